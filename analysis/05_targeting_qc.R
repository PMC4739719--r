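#!/usr/bin/env Rscript
# Stage 5: targeting-confirmation QC.
#
# Two layers: (a) the read-count flag over the cohort's target genes --
# a mutant is flagged for inspection when any library shows >= 100 reads in
# either genotype AND the mutant retains >= 20% of WT reads; (b) the
# exon-pattern classifier, demonstrated on one generated profile pair per
# verdict scenario (the count simulator works at gene level, so exon
# profiles come from the scenario generator).

suppressMessages(library(flankfx))
suppressMessages(library(readr))
suppressMessages(library(dplyr))

gm <- read_gene_models("results/synthetic/gene_models.tsv", format = "tsv")
alleles <- read_alleles("results/synthetic/alleles.tsv", gm)
cnt <- read_counts("results/synthetic/counts.tsv",
                   meta_path = "results/synthetic/libraries.tsv")
pairs <- read_tsv("results/synthetic/pairs.tsv", show_col_types = FALSE)

sf <- compute_size_factors(cnt$counts)
norm <- sweep(cnt$counts, 2, sf, "/")
rows <- pairs[pairs$line %in% alleles$gene_id, ]
flags <- tibble::tibble(
  target = rows$line,
  allele_class = alleles$allele_class[match(rows$line, alleles$gene_id)],
  library = rows$hom_library,
  hom_total = norm[cbind(rows$line, rows$hom_library)],
  wt_total = norm[cbind(rows$line, rows$wt_library)]
)
write_tsv(flags, "results/qc_flags.tsv")

cfg <- synthetic_config(seed = 1)
verdicts <- c("confirmed_null", "trap_complete", "splice_around",
              "uniform_hypomorph", "distal_retention", "intronic_only",
              "failed_targeting", "indeterminate")
cls <- bind_rows(lapply(verdicts, function(v) {
  p <- generate_exon_profiles(cfg, v, n = 1)[[1]]
  got <- classify_exon_pattern(p$hom, p$wt, p$allele, p$model)
  tibble::tibble(target = p$model$gene_id,
                 allele_class = p$allele$allele_class,
                 scenario = v, verdict = got$verdict)
}))
write_tsv(cls, "results/qc_classifications.tsv")

qc <- cohort_qc(flags,
                cls |> rename(verdict = verdict) |> select(target, allele_class, verdict))
write_tsv(qc$by_class, "results/qc_summary.tsv")
message(sprintf("flagged for inspection: DEL %.0f%%, TRAP %.0f%% of mutants",
                qc$by_class$pct_flagged[qc$by_class$allele_class == "DEL"],
                qc$by_class$pct_flagged[qc$by_class$allele_class == "TRAP"]))
message(sprintf("scenario classifications correct: %d / %d",
                sum(cls$scenario == cls$verdict), nrow(cls)))
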