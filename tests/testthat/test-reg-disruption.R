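make_reg_gene <- function(strand = "+") {
  # 5 exons of 100 bp spaced by 900 bp introns, gene span 1000-5500
  starts <- seq(1000, 5000, by = 1000)
  gene_models("g", "chr1", 1000, 5100, strand,
              list(data.frame(start = starts, end = starts + 100)))
}

trap_allele <- function(intron = 2) {
  tibble::tibble(gene_id = "g", allele_class = "TRAP",
                 trap_insertion_intron = intron,
                 deleted_exon_first = NA_real_, deleted_exon_last = NA_real_,
                 neo_promoter = "hACTB")
}

del_allele <- function(first = 1, last = 5) {
  tibble::tibble(gene_id = "g", allele_class = "DEL",
                 trap_insertion_intron = NA_real_,
                 deleted_exon_first = first, deleted_exon_last = last,
                 neo_promoter = "hUBC")
}

tfbs_at <- function(starts, confidence = "high") {
  tibble::tibble(chromosome = "chr1", start = starts, end = starts + 11,
                 tfbs_id = paste0("s", seq_along(starts)),
                 confidence = confidence)
}

chip_at <- function(starts) {
  tibble::tibble(chromosome = "chr1", start = starts, end = starts + 299,
                 peak_id = paste0("p", seq_along(starts)),
                 factor = "Pol2", tissue = "liver")
}

test_that("TRAP scoring needs two high-confidence distal sites", {
  model <- make_reg_gene()
  allele <- trap_allele(2)  # post-trap region starts at exon 3 (3000)
  none <- tfbs_at(numeric(0))
  expect_false(score_trap(allele, model, none)$disrupted)
  one <- tfbs_at(3500)
  expect_false(score_trap(allele, model, one)$disrupted)
  two <- tfbs_at(c(3500, 4500))
  expect_true(score_trap(allele, model, two)$disrupted)
  # low-confidence sites never count for TRAP
  low <- tfbs_at(c(3500, 4500), confidence = "low")
  expect_false(score_trap(allele, model, low)$disrupted)
  # sites 5' of the trap do not count
  proximal <- tfbs_at(c(1200, 2200))
  expect_false(score_trap(allele, model, proximal)$disrupted)
  expect_error(score_trap(del_allele(), model, two), "TRAP")
})

test_that("DEL scoring requires two deleted sites plus ChIP corroboration", {
  model <- make_reg_gene()
  allele <- del_allele(1, 5)
  two_tfbs <- tfbs_at(c(1500, 2500), confidence = c("high", "low"))
  no_chip <- chip_at(numeric(0))
  expect_false(score_del(allele, model, two_tfbs, no_chip)$disrupted)
  with_chip <- chip_at(2000)
  expect_true(score_del(allele, model, two_tfbs, with_chip)$disrupted)
  one_tfbs <- tfbs_at(1500)
  expect_false(score_del(allele, model, one_tfbs, with_chip)$disrupted)
  expect_error(score_del(trap_allele(), model, two_tfbs, with_chip), "DEL")
})

test_that("minus-strand geometry flips the post-trap region", {
  model <- make_reg_gene(strand = "-")
  # transcription starts at the genomically last exon; intron 1 is between
  # exons 5 and 4 (genomic), so the post-trap region is the genomic 5' side
  allele <- trap_allele(1)
  region <- post_trap_region(allele, model)
  expect_equal(region, c(1000, 4100))
  distal <- tfbs_at(c(1200, 2200))
  expect_true(score_trap(allele, model, distal)$disrupted)
})

test_that("both scoring rules match brute-force interval checks on random fixtures", {
  set.seed(81)
  model_plus <- make_reg_gene("+")
  model_minus <- make_reg_gene("-")
  for (rep in 1:300) {
    model <- if (runif(1) < 0.5) model_plus else model_minus
    n_tf <- sample(0:5, 1)
    tfbs <- tfbs_at(sample(500:6000, n_tf, replace = TRUE),
                    confidence = sample(c("high", "low"), max(n_tf, 1),
                                        replace = TRUE)[seq_len(n_tf)])
    n_pk <- sample(0:2, 1)
    chip <- chip_at(sample(500:6000, n_pk, replace = TRUE))

    trap <- trap_allele(sample(1:4, 1))
    region <- post_trap_region(trap, model)
    expect_equal(score_trap(trap, model, tfbs)$disrupted,
                 oracle_score_trap(region, "chr1", tfbs))

    dfirst <- sample(1:4, 1)
    del <- del_allele(dfirst, sample(dfirst:5, 1))
    span <- deleted_span(del, model)
    expect_equal(score_del(del, model, tfbs, chip)$disrupted,
                 oracle_score_del(span, "chr1", tfbs, chip))
  }
})

test_that("adding sites or peaks never un-disrupts a call (monotonicity)", {
  set.seed(91)
  model <- make_reg_gene()
  del <- del_allele(1, 5)
  for (rep in 1:50) {
    tfbs <- tfbs_at(sample(500:6000, sample(1:4, 1), replace = TRUE))
    chip <- chip_at(sample(500:6000, sample(0:2, 1), replace = TRUE))
    base <- score_del(del, model, tfbs, chip)$disrupted
    more <- score_del(del, model,
                      dplyr::bind_rows(tfbs, tfbs_at(3000)),
                      dplyr::bind_rows(chip, chip_at(3000)))$disrupted
    expect_true(!base || more)
  }
})

test_that("cohort disruption frequencies reproduce a constructed contrast", {
  calls <- tibble::tibble(
    gene_id = paste0("g", 1:44),
    allele_class = c(rep("TRAP", 15), rep("DEL", 29)),
    disrupted = c(rep(TRUE, 1), rep(FALSE, 14), rep(TRUE, 17), rep(FALSE, 12)),
    n_tfbs_affected = 2, n_chip_corroborating = 1
  )
  s <- cohort_disruption_frequency(calls)
  trap <- s$by_class[s$by_class$allele_class == "TRAP", ]
  del <- s$by_class[s$by_class$allele_class == "DEL", ]
  expect_equal(trap$pct_disrupted, 100 / 15, tolerance = 1e-10)
  expect_equal(del$pct_disrupted, 100 * 17 / 29, tolerance = 1e-10)
  expect_lt(s$test$p, 0.001)

  nothing <- calls
  nothing$disrupted <- FALSE
  s0 <- cohort_disruption_frequency(nothing)
  expect_equal(s0$by_class$pct_disrupted, c(0, 0))
  expect_null(s0$test)  # degenerate table has a zero marginal
})
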