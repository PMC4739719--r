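small_cfg <- function(seed = 17, ...) {
  synthetic_config(seed = seed, n_chromosomes = 2, chromosome_length_mb = 8,
                   n_targets_del = 5, n_targets_trap = 3, n_tissues = 2, ...)
}

test_that("annotation generation is deterministic and non-overlapping", {
  cfg <- small_cfg()
  a <- generate_annotation(cfg)
  b <- generate_annotation(cfg)
  expect_identical(a, b)

  gm <- a$gene_models
  for (chr in unique(gm$chromosome)) {
    sub <- gm[gm$chromosome == chr, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]), info = chr)
    }
  }
  expect_true(all(gm$end <= cfg$chromosome_length_mb * 1e6))
})

test_that("gene counts follow the configured density", {
  cfg <- synthetic_config(seed = 23, n_chromosomes = 1,
                          chromosome_length_mb = 30, genes_per_mb = 30,
                          n_targets_del = 2, n_targets_trap = 1)
  gm <- generate_annotation(cfg)$gene_models
  lambda <- 30 * 30
  expect_gt(nrow(gm), lambda - 4 * sqrt(lambda))
  expect_lt(nrow(gm), lambda + 4 * sqrt(lambda))
})

test_that("targets satisfy the neighbor and exon requirements", {
  ann <- generate_annotation(small_cfg())
  for (i in seq_len(nrow(ann$alleles))) {
    tid <- ann$alleles$gene_id[i]
    nb <- extract_neighborhood(tid, ann$gene_models, 500000)
    expect_gte(nrow(nb), 5)
    n_ex <- nrow(ann$gene_models$exons[[which(ann$gene_models$gene_id == tid)]])
    expect_gte(n_ex, 4)
  }
  expect_error(
    generate_annotation(synthetic_config(seed = 1, n_chromosomes = 1,
                                         chromosome_length_mb = 2,
                                         genes_per_mb = 2,
                                         n_targets_del = 10,
                                         n_targets_trap = 5)),
    "density too low"
  )
})

test_that("null configuration leaves HOM and WT exchangeable", {
  cfg <- small_cfg(seed = 29, knockdown_factor = 1, p_local_up = 0,
                   p_local_down = 0)
  ann <- generate_annotation(cfg)
  cnt <- generate_counts(cfg, ann)
  expect_equal(nrow(cnt$truth), 0)
  # same marginal behavior after depth normalization: mean log-ratio near zero
  sf <- compute_size_factors(cnt$counts)
  norm <- sweep(cnt$counts, 2, sf, "/")
  pair1 <- cnt$pairs[1, ]
  lr <- log2((norm[, pair1$hom_library] + 0.5) /
               (norm[, pair1$wt_library] + 0.5))
  expect_lt(abs(mean(lr)), 0.15)
})

test_that("planted effects and knockdown are recoverable from the truth record", {
  cfg <- small_cfg(seed = 31)
  ann <- generate_annotation(cfg)
  cnt <- generate_counts(cfg, ann)
  expect_gt(nrow(cnt$truth), 0)
  expect_true(all(cnt$truth$direction %in% c("up", "down")))
  expect_true(all(abs(cnt$truth$centrum_distance) <= 500000))
  # a planted pair appears once per tissue
  per_pair <- dplyr::count(cnt$truth, line, gene_id)
  expect_true(all(per_pair$n == cfg$n_tissues))

  # the knockdown is visible in raw counts for expressed targets
  tgt <- ann$alleles$gene_id
  first_pair <- match(tgt, cnt$pairs$line)
  hom1 <- cnt$counts[cbind(tgt, cnt$pairs$hom_library[first_pair])]
  wt1 <- cnt$counts[cbind(tgt, cnt$pairs$wt_library[first_pair])]
  expressed <- wt1 >= 200
  expect_true(mean(hom1[expressed] < 0.5 * wt1[expressed]) > 0.8)
})

test_that("marginal distributions are seed-stable (same law, different draws)", {
  cfg1 <- small_cfg(seed = 101)
  cfg2 <- small_cfg(seed = 202)
  g1 <- generate_annotation(cfg1)$gene_models
  g2 <- generate_annotation(cfg2)$gene_models
  expect_false(identical(g1$start, g2$start))
  len1 <- log(g1$end - g1$start + 1)
  len2 <- log(g2$end - g2$start + 1)
  ks <- suppressWarnings(ks.test(len1, len2))
  expect_gt(ks$p.value, 0.001)
})

test_that("planted 3'-bias matches its configured probability over many draws", {
  # pool planted up-events across replicate cohorts until the binomial CI
  # around the default bias is informative
  ups <- list()
  for (s in 1:12) {
    cfg <- synthetic_config(seed = 300 + s, n_chromosomes = 3,
                            chromosome_length_mb = 10, n_targets_del = 24,
                            n_targets_trap = 12, n_tissues = 2)
    ann <- generate_annotation(cfg)
    cnt <- generate_counts(cfg, ann)
    tr <- dplyr::distinct(cnt$truth, line, gene_id,
                          .keep_all = TRUE)
    ups[[s]] <- tr[tr$direction == "up", ]
  }
  up <- dplyr::bind_rows(ups)
  expect_gte(nrow(up), 200)
  p_hat <- mean(up$centrum_distance > 0)
  ci_half <- 1.96 * sqrt(0.774 * 0.226 / nrow(up))
  expect_lt(abs(p_hat - 0.774), ci_half + 1e-12)
})

test_that("regulatory fixtures realize their planted disruption status", {
  cfg <- small_cfg(seed = 37)
  ann <- generate_annotation(cfg)
  reg <- generate_reg_annotation(cfg, ann)
  calls <- score_cohort(ann$alleles, ann$gene_models, reg$tfbs, reg$chip)
  merged <- dplyr::inner_join(calls, reg$truth, by = c("gene_id", "allele_class"),
                              suffix = c("_called", "_planted"))
  expect_equal(merged$disrupted_called, merged$disrupted_planted)
})
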