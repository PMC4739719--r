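test_that("GTF parsing copies spans and sorts exons", {
  gm <- toy_gene_models()
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_toy_gtf(gm, gtf)
  got <- read_gene_models(gtf, format = "gtf")
  got <- got[match(gm$gene_id, got$gene_id), ]
  expect_equal(got$start, gm$start)
  expect_equal(got$end, gm$end)
  expect_equal(got$strand, gm$strand)
  expect_equal(got$biotype, gm$biotype)
  expect_equal(got$exons[[1]]$start, gm$exons[[1]]$start)

  # exons deliberately written out of order still come back sorted
  shuffled <- gm
  shuffled$exons[[1]] <- gm$exons[[1]][c(3, 1, 2), ]
  gtf2 <- withr::local_tempfile(fileext = ".gtf")
  write_toy_gtf(shuffled, gtf2)
  got2 <- read_gene_models(gtf2, format = "gtf")
  expect_false(is.unsorted(got2$exons[[which(got2$gene_id == "gA")]]$start))
})

test_that("GTF and TSV dialects yield identical gene models", {
  gm <- toy_gene_models()
  gtf <- withr::local_tempfile(fileext = ".gtf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_toy_gtf(gm, gtf)
  write_gene_models(gm, tsv)
  from_gtf <- read_gene_models(gtf, "gtf")
  from_tsv <- read_gene_models(tsv, "tsv")
  from_gtf <- from_gtf[match(from_tsv$gene_id, from_gtf$gene_id), ]
  for (col in c("gene_id", "chromosome", "start", "end", "strand", "biotype")) {
    expect_equal(from_gtf[[col]], from_tsv[[col]], info = col)
  }
  for (i in seq_len(nrow(from_tsv))) {
    expect_equal(unname(as.matrix(from_gtf$exons[[i]])),
                 unname(as.matrix(from_tsv$exons[[i]])))
  }
})

test_that("gene-model validation rejects malformed structures", {
  gm <- toy_gene_models()
  bad <- gm; bad$exons[[1]] <- bad$exons[[1]][0, ]
  expect_error(validate_gene_models(bad), "zero exons")
  bad <- gm; bad$exons[[1]]$end[3] <- gm$end[1] + 10
  expect_error(validate_gene_models(bad), "outside gene span")
  bad <- gm; bad$strand[2] <- "."
  expect_error(validate_gene_models(bad), "strand")
  bad <- gm; bad$gene_id[2] <- "gA"
  expect_error(validate_gene_models(bad), "duplicate")
})

test_that("count tables round-trip and reject bad input", {
  m <- matrix(rpois(20, 50), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("lib", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(m, path)
  got <- read_counts(path)
  expect_equal(got$counts, m)

  neg <- m; neg[2, 2] <- -1
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(neg, path2)
  expect_error(read_counts(path2), "negative")

  dup <- m; rownames(dup)[2] <- "g1"
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(dup, path3)
  expect_error(read_counts(path3), "duplicate")
})

test_that("supplementary-table dialect round-trips with signs and blanks intact", {
  s1 <- toy_s1()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_s1_table(s1, path)
  got <- read_s1_table(path)
  expect_equal(nrow(got), nrow(s1))
  # 5' convention: negative centrum distance preserved
  expect_equal(got$centrum_distance[got$gene == "n2" & got$tissue == "liver"],
               -34000)
  # blank p-values stay absent
  expect_true(is.na(got$p_value[got$gene == "n3" & got$tissue == "kidney"]))
  expect_equal(got$hom, s1$hom)
  expect_equal(got$p_value, s1$p_value)

  incomplete <- s1[, setdiff(names(s1), "strand")]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(incomplete, path2)
  expect_error(read_s1_table(path2), "strand")
})

test_that("centrum is the floored midpoint", {
  expect_equal(unname(gene_centrum(data.frame(start = 100, end = 200))), 150)
  expect_equal(unname(gene_centrum(data.frame(start = 1, end = 2))), 1)
  set.seed(42)
  s <- sample.int(1e6, 200)
  e <- s + sample.int(1e5, 200)
  expect_equal(unname(gene_centrum(data.frame(start = s, end = e))),
               vapply(seq_along(s), function(i) floor((s[i] + e[i]) / 2),
                      numeric(1)))
})

test_that("BED intervals convert from 0-based half-open to 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t112\ts1\thigh", "chr1\t0\t12\ts2\tlow"), path)
  tf <- read_tfbs_bed(path)
  expect_equal(tf$start, c(101, 1))
  expect_equal(tf$end, c(112, 12))
  expect_equal(tf$end - tf$start + 1, c(12, 12))
})

test_that("allele tables validate class-specific fields and ordinals", {
  gm <- toy_gene_models()
  ok <- tibble::tibble(
    gene_id = c("gA", "gB"), allele_class = c("TRAP", "DEL"),
    trap_insertion_intron = c(1, NA), deleted_exon_first = c(NA, 1),
    deleted_exon_last = c(NA, 2), neo_promoter = c("hACTB", "hUBC")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_alleles(ok, path)
  expect_equal(read_alleles(path, gm)$gene_id, ok$gene_id)

  bad <- ok; bad$trap_insertion_intron[1] <- 3  # gA has 3 exons, 2 introns
  expect_error(validate_alleles(bad, gm), "intron")
  bad <- ok; bad$deleted_exon_last[2] <- 5
  expect_error(validate_alleles(bad, gm), "exon")
  bad <- ok; bad$trap_insertion_intron[2] <- 1
  expect_error(validate_alleles(bad), "DEL allele with trap")
})

test_that("1-based inclusive and half-open conversions are lossless", {
  set.seed(7)
  start0 <- sample.int(1e6, 500) - 1  # BED-style 0-based starts
  end0 <- start0 + sample.int(1000, 500)
  start1 <- start0 + 1  # the conversion read_*_bed applies
  end1 <- end0
  expect_equal(start1 - 1, start0)
  expect_equal(end1 - start1 + 1, end0 - start0)
})
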