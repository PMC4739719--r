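# Small fixtures built in code.

toy_gene_models <- function() {
  gene_models(
    gene_id = c("gA", "gB", "gC"),
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(1000, 60000, 5000),
    end = c(9000, 75000, 9000),
    strand = c("+", "-", "+"),
    exons = list(
      data.frame(start = c(1000, 4000, 8000), end = c(1500, 4500, 9000)),
      data.frame(start = c(60000, 70000), end = c(61000, 75000)),
      data.frame(start = c(5000, 7000), end = c(5600, 9000))
    ),
    biotype = c("protein_coding", "protein_coding", "miRNA")
  )
}

write_toy_gtf <- function(gm, path) {
  lines <- character(0)
  for (i in seq_len(nrow(gm))) {
    attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";',
                      gm$gene_id[i], gm$biotype[i])
    lines <- c(lines, paste(gm$chromosome[i], "test", "gene",
                            gm$start[i], gm$end[i], ".", gm$strand[i], ".",
                            attr_g, sep = "\t"))
    e <- gm$exons[[i]]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, paste(gm$chromosome[i], "test", "exon",
                              e$start[j], e$end[j], ".", gm$strand[i], ".",
                              attr_g, sep = "\t"))
    }
  }
  writeLines(lines, path)
  path
}

# random annotations for property tests (overlap allowed; extract/scan
# operations must not care)
random_gene_models <- function(n, n_chrom = 2, span = 3e6) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(200:50000, n, replace = TRUE)
  gene_models(
    gene_id = sprintf("r%03d", seq_len(n)),
    chromosome = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start,
    end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    exons = lapply(seq_len(n), function(i) {
      data.frame(start = start[i], end = start[i] + len[i])
    })
  )
}

# tiny hand-countable supplementary-table fixture: two lines, two tissues
toy_s1 <- function() {
  row <- function(line, tissue, gene, d, hom, wt, p) {
    tibble::tibble(line = line, synonym = NA_character_, tissue = tissue,
                   chromosome = "chr1", gene = gene,
                   start = 1e6 + d, end = 1e6 + d + 1000,
                   centrum_distance = d, strand = "+",
                   hom = hom, wt = wt, p_value = p,
                   hom_wt_ratio = hom / wt,
                   log2 = log2(hom / wt))
  }
  dplyr::bind_rows(
    # line L1 (DEL): target knocked down; n1 up 3' in liver only; n2 down 5' both tissues
    row("L1", "liver", "L1", 0, 50, 800, 0.001),
    row("L1", "liver", "n1", 67000, 400, 100, 0.01),
    row("L1", "liver", "n2", -34000, 50, 300, 0.02),
    row("L1", "kidney", "L1", 0, 60, 900, 0.001),
    row("L1", "kidney", "n1", 67000, 150, 120, 0.4),
    row("L1", "kidney", "n2", -34000, 60, 310, 0.03),
    # line L2 (TRAP): target retains 30% of WT (flagged); no dysregulated neighbors
    row("L2", "liver", "L2", 0, 300, 1000, 0.04),
    row("L2", "liver", "n3", 120000, 200, 210, 0.9),
    row("L2", "kidney", "L2", 0, 280, 950, 0.05),
    row("L2", "kidney", "n3", 120000, 190, 200, NA)
  )
}

toy_s1_classes <- function() {
  tibble::tibble(line = c("L1", "L2"), allele_class = c("DEL", "TRAP"))
}
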