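#!/usr/bin/env Rscript
# Stage 4: genome-wide empirical null and chi-square comparisons.
#
# The null is the background frequency of up/down-regulated genes within
# 500 kb of every down-regulated (gene, library) instance across the whole
# annotation. Observed per-target flanking frequencies per allele class are
# then compared against it with Pearson goodness-of-fit tests, and the two
# allele classes against each other with a 2x2 homogeneity test.

suppressMessages(library(flankfx))
suppressMessages(library(readr))
suppressMessages(library(dplyr))

gm <- read_gene_models("results/synthetic/gene_models.tsv", format = "tsv")
calls <- read_tsv("results/differential_calls.tsv", show_col_types = FALSE)
targets <- read_tsv("results/neighborhood_targets.tsv", show_col_types = FALSE)

nl <- genome_wide_null(calls, gm, window = 500000)
message(sprintf("empirical null from %d focal down-calls over %d neighbor instances: f_up = %.2f%%, f_down = %.2f%%",
                nl$n_focal, nl$n_neighbor_instances,
                100 * nl$f_up, 100 * nl$f_down))

rows <- list()
for (cl in c("DEL", "TRAP")) {
  sub <- targets[targets$allele_class == cl, ]
  for (dir in c("up", "down")) {
    hits <- sum(if (dir == "up") sub$has_up else sub$has_down)
    f0 <- if (dir == "up") nl$f_up else nl$f_down
    gof <- chisq_gof(c(hits, nrow(sub) - hits), f0)
    rows[[paste(cl, dir)]] <- tibble::tibble(
      allele_class = cl, direction = dir,
      observed_pct = 100 * hits / nrow(sub), expected_pct = 100 * f0,
      statistic = gof$statistic, p = gof$p)
  }
}
comp <- bind_rows(rows)
write_tsv(comp, "results/null_comparisons.tsv")
print(as.data.frame(comp))

tab <- rbind(DEL = c(sum(targets$has_down[targets$allele_class == "DEL"]),
                     sum(!targets$has_down[targets$allele_class == "DEL"])),
             TRAP = c(sum(targets$has_down[targets$allele_class == "TRAP"]),
                      sum(!targets$has_down[targets$allele_class == "TRAP"])))
print(chisq_homogeneity(tab))
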