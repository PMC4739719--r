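test_that("strand-adjusted distance follows the 5'/3' sign convention", {
  target_plus <- gene_models("t", "chr1", 999000, 1001000, "+",
                             list(data.frame(start = 999000, end = 1001000)))
  target_minus <- target_plus
  target_minus$strand <- "-"
  nb <- gene_models("n", "chr1", 1049000, 1051000, "+",
                    list(data.frame(start = 1049000, end = 1051000)))
  expect_equal(unname(strand_adjusted_distance(target_plus, nb)), 50000)
  expect_equal(unname(strand_adjusted_distance(target_minus, nb)), -50000)

  other <- nb
  other$chromosome <- "chr2"
  expect_error(strand_adjusted_distance(target_plus, other), "chromosome")

  # random configurations vs independent sign-by-cases computation
  set.seed(31)
  for (i in 1:200) {
    ts <- sample.int(2e6, 1); te <- ts + sample.int(5e4, 1)
    ns <- sample.int(2e6, 1); ne <- ns + sample.int(5e4, 1)
    st <- sample(c("+", "-"), 1)
    t1 <- gene_models("t", "chr1", ts, te, st,
                      list(data.frame(start = ts, end = te)))
    n1 <- gene_models("n", "chr1", ns, ne, "+",
                      list(data.frame(start = ns, end = ne)))
    expect_equal(unname(strand_adjusted_distance(t1, n1)),
                 oracle_signed_distance(ts, te, st, ns, ne))
  }
})

test_that("neighborhood extraction matches a brute-force scan", {
  set.seed(41)
  for (rep in 1:20) {
    gm <- random_gene_models(40)
    target <- sample(gm$gene_id, 1)
    got <- extract_neighborhood(target, gm, window = 500000)
    expect_equal(sort(got$gene_id), oracle_neighborhood(target, gm, 500000))
    expect_false(target %in% got$gene_id)
    expect_true(all(abs(got$centrum_distance) <= 500000))
  }
  gm1 <- random_gene_models(5, n_chrom = 1)
  expect_error(extract_neighborhood("absent", gm1, 500000), "absent")
})

test_that("a published-style neighborhood keeps its 5'/3' geometry", {
  # Tst-like locus: target plus two 5' down-regulated and one 3' up-regulated
  # flanking genes, all within 500 kb
  mk <- function(id, s, e, strand = "+") {
    list(gene_id = id, start = s, end = e, strand = strand,
         exons = data.frame(start = s, end = e))
  }
  gm <- gene_models(
    gene_id = c("Tst", "Mpst", "Kctd17", "Tex33"),
    chromosome = "chr17",
    start = c(999000, 949000, 899000, 1199000),
    end = c(1001000, 951000, 901000, 1201000),
    strand = c("+", "+", "-", "+"),
    exons = lapply(c(999000, 949000, 899000, 1199000), function(s) {
      data.frame(start = s, end = s + 2000)
    })
  )
  nb <- extract_neighborhood("Tst", gm, window = 500000)
  expect_setequal(nb$gene_id, c("Mpst", "Kctd17", "Tex33"))
  expect_lt(nb$centrum_distance[nb$gene_id == "Mpst"], 0)
  expect_lt(nb$centrum_distance[nb$gene_id == "Kctd17"], 0)
  expect_gt(nb$centrum_distance[nb$gene_id == "Tex33"], 0)
})

test_that("target summaries use OR aggregation over libraries", {
  gm <- gene_models(
    gene_id = c("t", "n1", "n2"),
    chromosome = "chr1",
    start = c(1e6, 1.1e6, 1.2e6), end = c(1e6, 1.1e6, 1.2e6) + 1000,
    strand = "+",
    exons = lapply(c(1e6, 1.1e6, 1.2e6), function(s) {
      data.frame(start = s, end = s + 1000)
    })
  )
  calls <- tibble::tibble(
    gene_id = rep(c("t", "n1", "n2"), 4),
    hom_library = rep(paste0("lib", 1:4), each = 3),
    direction = "ns", line = "t"
  )
  s0 <- summarize_target("t", gm, calls)
  expect_false(s0$summary$has_up)
  expect_false(s0$summary$has_down)
  expect_equal(s0$summary$n_genes_in_window, 2)

  calls$direction[calls$gene_id == "n1" & calls$hom_library == "lib3"] <- "down"
  s1 <- summarize_target("t", gm, calls)
  expect_true(s1$summary$has_down)
  expect_false(s1$summary$has_up)
  expect_equal(sum(s1$libraries$has_down), 1)
  # the target's own call never counts
  calls$direction[calls$gene_id == "t"] <- "down"
  s2 <- summarize_target("t", gm, calls)
  expect_equal(nrow(s2$dysregulated), 1)
})

test_that("cohort frequencies count targets with at least one effect", {
  survey <- list(
    targets = tibble::tibble(
      target = paste0("t", 1:10),
      n_genes_in_window = 10,
      has_up = c(rep(TRUE, 3), rep(FALSE, 7)),
      has_down = FALSE,
      allele_class = "DEL"
    ),
    libraries = tibble::tibble(
      target = paste0("t", 1:10), hom_library = "l1",
      has_up = c(rep(TRUE, 3), rep(FALSE, 7)), has_down = FALSE,
      allele_class = "DEL"
    )
  )
  f <- cohort_frequencies(survey, by = "target", class = "DEL")
  expect_equal(f$pct_up, 30)
  expect_equal(f$pct_down, 0)
  expect_error(cohort_frequencies(survey, by = "target", class = "TRAP"),
               "no target")
})

test_that("topography bins tile the window and medians follow their subsets", {
  one <- tibble::tibble(target = "t", gene_id = "n", centrum_distance = -34000,
                        direction = "down", hom_library = "l1")
  topo <- topography(one)
  expect_equal(sum(topo$bins$count_down), 1)
  expect_equal(topo$bins$count_down[topo$bins$lo == -50 & topo$bins$hi == 0], 1)
  expect_equal(topo$medians$abs_down_kb, 34)
  expect_equal(nrow(topo$bins), 20)
  expect_equal(topo$bins$lo[1], -500)
  expect_equal(topo$bins$hi[20], 500)

  # random planted distances vs brute-force binning
  set.seed(51)
  d <- sample(seq(-500000, 499999), 300)
  dys <- tibble::tibble(target = "t", gene_id = paste0("n", seq_along(d)),
                        centrum_distance = d,
                        direction = sample(c("up", "down"), 300, replace = TRUE),
                        hom_library = "l1")
  topo2 <- topography(dys)
  expect_equal(topo2$bins$count_up,
               oracle_bin_histogram(d[dys$direction == "up"], 50000, 500000))
  expect_equal(topo2$bins$count_down,
               oracle_bin_histogram(d[dys$direction == "down"], 50000, 500000))
  expect_equal(sum(topo2$bins$count_up) + sum(topo2$bins$count_down),
               nrow(dys))
})

test_that("dedupe conventions count pairs vs instances", {
  dys <- tibble::tibble(
    target = "t", gene_id = c("n1", "n1", "n2"),
    centrum_distance = c(10000, 10000, -60000),
    direction = c("up", "up", "down"),
    hom_library = c("l1", "l2", "l1")
  )
  expect_equal(topography(dys, dedupe = "pair")$n_dysregulated, 2)
  expect_equal(topography(dys, dedupe = "instance")$n_dysregulated, 3)
})

test_that("flipping every strand mirrors the topography exactly", {
  set.seed(61)
  gm <- random_gene_models(50, n_chrom = 1)
  flipped <- gm
  flipped$strand <- ifelse(gm$strand == "+", "-", "+")
  target <- gm$gene_id[25]
  a <- extract_neighborhood(target, gm, 500000)
  b <- extract_neighborhood(target, flipped, 500000)
  b <- b[match(a$gene_id, b$gene_id), ]
  expect_equal(a$centrum_distance, -b$centrum_distance)
})

test_that("gene density contrast reports group means", {
  tab <- tibble::tibble(
    target = c("a", "b"), n_genes_in_window = c(10, 20),
    has_up = c(TRUE, FALSE), has_down = FALSE
  )
  d <- gene_density_contrast(tab)
  expect_equal(d$mean_genes_in_window[d$group == "with_effects"], 10)
  expect_equal(d$mean_genes_in_window[d$group == "without_effects"], 20)
  tab$has_up <- TRUE
  d2 <- gene_density_contrast(tab)
  expect_true(is.na(d2$mean_genes_in_window[d2$group == "without_effects"]))
})
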