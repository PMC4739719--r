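#!/usr/bin/env Rscript
# Stage 2: HOM-vs-WT differential calls for every library pair.
#
# Median-of-ratios normalization, a cross-gene dispersion trend (the pooled
# no-replicate design leaves no within-group replication), and an exact
# conditional NB test per gene and pair. Direction uses the unadjusted
# p < 0.05 criterion; BH-adjusted p-values are carried along.

suppressMessages(library(flankfx))
suppressMessages(library(readr))

src <- "results/synthetic"
cnt <- read_counts(file.path(src, "counts.tsv"),
                   meta_path = file.path(src, "libraries.tsv"))
pairs <- read_tsv(file.path(src, "pairs.tsv"), show_col_types = FALSE)

calls <- call_differential(cnt$counts, pairs, alpha = 0.05)
write_tsv(calls, "results/differential_calls.tsv")

n_sig <- sum(calls$p_unadjusted < 0.05)
message(sprintf("%d calls over %d pairs; %d significant at unadjusted p < 0.05 (%.1f%%), %d up / %d down",
                nrow(calls), nrow(pairs), n_sig, 100 * n_sig / nrow(calls),
                sum(calls$direction == "up"), sum(calls$direction == "down")))
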