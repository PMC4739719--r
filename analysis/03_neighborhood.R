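#!/usr/bin/env Rscript
# Stage 3: the +/-500 kb flanking-gene survey.
#
# For every target: all genes and miRNAs whose centrum lies within 500 kb,
# with signed strand-adjusted distances (negative = 5'); per-target and
# per-library dysregulation frequencies by allele class; the 50-kb spatial
# topography with its medians; and the gene-density contrast between
# targets with and without local effects.

suppressMessages(library(flankfx))
suppressMessages(library(readr))
suppressMessages(library(dplyr))

gm <- read_gene_models("results/synthetic/gene_models.tsv", format = "tsv")
alleles <- read_alleles("results/synthetic/alleles.tsv", gm)
calls <- read_tsv("results/differential_calls.tsv", show_col_types = FALSE)

survey <- survey_neighborhoods(alleles, gm, calls, window = 500000)
write_tsv(survey$targets, "results/neighborhood_targets.tsv")
write_tsv(survey$dysregulated, "results/neighborhood_dysregulated.tsv")

freq <- bind_rows(lapply(c("DEL", "TRAP"), function(cl) {
  bind_rows(cohort_frequencies(survey, "target", cl),
            cohort_frequencies(survey, "library", cl))
}))
write_tsv(freq, "results/cohort_frequencies.tsv")

for (cl in c("DEL", "TRAP")) {
  d <- survey$dysregulated
  topo <- topography(d[d$allele_class == cl, ], dedupe = "pair")
  write_tsv(topo$bins, sprintf("results/topography_bins_%s.tsv", tolower(cl)))
  message(sprintf(
    "%s topography (%d unique pairs): median |d| down = %.0f kb; median d 3'-up = %.0f kb; up split %.1f%% 3' / %.1f%% 5'",
    cl, topo$n_dysregulated, topo$medians$abs_down_kb,
    topo$medians$up_3prime_kb, topo$pct_up_3prime, topo$pct_up_5prime))
}

dens <- gene_density_contrast(survey)
write_tsv(dens, "results/gene_density.tsv")
message(sprintf("targets with local effects: %d (mean %.1f genes in window); without: %d",
                dens$n_targets[1], dens$mean_genes_in_window[1], dens$n_targets[2]))
print(as.data.frame(freq))
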