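#!/usr/bin/env Rscript
# Stage 6: regulatory-element disruption scoring.
#
# TRAP rule: >= 2 high-confidence TFBS in the gene body 3' of the insertion
# intron. DEL rule: >= 2 TFBS in the deleted span corroborated by >= 1
# overlapping ChIP peak. Interval fixtures with planted disruption status
# stand in for externally curated TFBS/ChIP tracks.

suppressMessages(library(flankfx))
suppressMessages(library(readr))
suppressMessages(library(dplyr))

gm <- read_gene_models("results/synthetic/gene_models.tsv", format = "tsv")
alleles <- read_alleles("results/synthetic/alleles.tsv", gm)
cfg <- synthetic_config(seed = 1)
ann <- list(gene_models = gm, alleles = alleles)
reg <- generate_reg_annotation(cfg, ann)

calls <- score_cohort(alleles, gm, reg$tfbs, reg$chip)
write_tsv(calls, "results/reg_disruption.tsv")

s <- cohort_disruption_frequency(calls)
write_tsv(s$by_class, "results/reg_summary.tsv")
for (i in seq_len(nrow(s$by_class))) {
  message(sprintf("%s: %d / %d targets scored as disrupting regulatory elements (%.1f%%)",
                  s$by_class$allele_class[i], s$by_class$n_disrupted[i],
                  s$by_class$n[i], s$by_class$pct_disrupted[i]))
}
if (!is.null(s$test)) print(s$test)

agree <- inner_join(calls, reg$truth, by = c("gene_id", "allele_class"),
                    suffix = c("_called", "_planted"))
message(sprintf("calls matching planted status: %d / %d",
                sum(agree$disrupted_called == agree$disrupted_planted),
                nrow(agree)))
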