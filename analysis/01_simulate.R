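#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# The cohort mirrors the design of the mutant-transcriptome screen this
# workflow implements: 29 deletion (DEL) and 15 gene-trap (TRAP) targets,
# one pooled HOM library per target and tissue plus shared WT controls over
# 4 tissues, an 8-fold knockdown of each target, and planted local effects
# around the targets (up-regulation biased 3', down-regulation symmetric
# and proximal). Everything downstream reads the TSVs written here.

suppressMessages(library(flankfx))
suppressMessages(library(readr))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = 1)
ann <- generate_annotation(cfg)
cnt <- generate_counts(cfg, ann)

write_gene_models(ann$gene_models, file.path(out, "gene_models.tsv"))
write_alleles(ann$alleles, file.path(out, "alleles.tsv"))
write_counts(cnt$counts, file.path(out, "counts.tsv"),
             meta = cnt$meta, meta_path = file.path(out, "libraries.tsv"))
write_tsv(cnt$pairs, file.path(out, "pairs.tsv"))
write_tsv(cnt$truth, file.path(out, "planted_truth.tsv"))

message(sprintf("simulated %d genes on %d chromosomes; %d targets (%d DEL, %d TRAP)",
                nrow(ann$gene_models), cfg$n_chromosomes, nrow(ann$alleles),
                sum(ann$alleles$allele_class == "DEL"),
                sum(ann$alleles$allele_class == "TRAP")))
message(sprintf("%d libraries (%d HOM, %d shared WT), %d planted local effects (%d unique pairs)",
                ncol(cnt$counts), sum(cnt$meta$genotype == "HOM"),
                sum(cnt$meta$genotype == "WT"), nrow(cnt$truth),
                nrow(unique(cnt$truth[c("line", "gene_id", "direction")]))))
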