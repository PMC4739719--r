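# Genome-wide empirical null and chi-square comparisons.
#
# The null is the background frequency of finding up- or down-regulated
# genes within the window of *any* down-regulated gene, over every library:
# each (gene, library) down-call is a focal instance, every other gene
# within the window is a neighbor instance scored by its call in the same
# library.

#' Genome-wide empirical null frequency
#'
#' Focal set: every (gene, library) pair down-regulated at unadjusted
#' p < alpha. For each focal instance, every other gene whose centrum lies
#' within `window` bp on the same chromosome is one neighbor instance;
#' `f_up` / `f_down` are the fractions of neighbor instances up- /
#' down-regulated in the same library. The focal gene's own record is
#' excluded from its neighbor set.
#'
#' @param calls Differential-call tibble covering the full annotation for
#'   each library (columns `gene_id`, `hom_library`, `direction`).
#' @param gm Gene-model tibble.
#' @param window Half-width in bp (default 500000).
#' @return List: `f_up`, `f_down`, `n_focal`, `n_neighbor_instances`.
#' @export
genome_wide_null <- function(calls, gm, window = 500000) {
  cen <- gene_centrum(gm)
  chrom <- stats::setNames(gm$chromosome, gm$gene_id)
  absent <- setdiff(calls$gene_id, gm$gene_id)
  if (length(absent) > 0) {
    stop("calls for genes absent from annotation: ",
         paste(utils::head(absent, 3), collapse = ", "))
  }
  n_focal <- 0L
  n_inst <- 0L
  n_up <- 0L
  n_down <- 0L
  for (lib in unique(calls$hom_library)) {
    cl <- calls[calls$hom_library == lib, ]
    dir_by_gene <- stats::setNames(cl$direction, cl$gene_id)
    focal <- cl$gene_id[cl$direction == "down"]
    n_focal <- n_focal + length(focal)
    if (length(focal) == 0) next
    for (chr in unique(chrom[focal])) {
      on_chr <- gm$gene_id[gm$chromosome == chr]
      on_chr <- intersect(on_chr, cl$gene_id)
      pos <- sort(cen[on_chr])
      ids <- names(pos)
      for (fg in focal[chrom[focal] == chr]) {
        c0 <- cen[[fg]]
        i_lo <- findInterval(c0 - window, pos, left.open = TRUE) + 1L
        i_hi <- findInterval(c0 + window, pos)
        if (i_hi < i_lo) next
        nb <- setdiff(ids[i_lo:i_hi], fg)
        n_inst <- n_inst + length(nb)
        dirs <- dir_by_gene[nb]
        n_up <- n_up + sum(dirs == "up")
        n_down <- n_down + sum(dirs == "down")
      }
    }
  }
  if (n_focal == 0) stop("empty focal set: no down-regulated (gene, library) calls")
  list(
    f_up = if (n_inst > 0) n_up / n_inst else NA_real_,
    f_down = if (n_inst > 0) n_down / n_inst else NA_real_,
    n_focal = n_focal,
    n_neighbor_instances = n_inst
  )
}

#' Chi-square goodness of fit against an expected fraction
#'
#' Pearson goodness-of-fit on two categories with df = 1 and no continuity
#' correction; expected counts are `total * c(f, 1 - f)`.
#'
#' @param observed Two non-negative category counts (hits, misses).
#' @param expected_fraction Expected fraction of the first category,
#'   strictly inside (0, 1).
#' @return A `chisq_result` list: `statistic`, `df`, `p`, `observed`,
#'   `expected`.
#' @export
chisq_gof <- function(observed, expected_fraction) {
  if (length(observed) != 2 || any(observed < 0)) {
    stop("observed must be two non-negative counts")
  }
  total <- sum(observed)
  if (total <= 0) stop("total observed must be positive")
  if (expected_fraction <= 0 || expected_fraction >= 1) {
    stop("expected_fraction must be strictly inside (0, 1)")
  }
  expected <- total * c(expected_fraction, 1 - expected_fraction)
  if (any(expected == 0)) stop("expected cell is zero")
  stat <- sum((observed - expected)^2 / expected)
  res <- list(
    statistic = stat,
    df = 1L,
    p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    observed = observed,
    expected = expected
  )
  class(res) <- "chisq_result"
  res
}

#' Chi-square test of homogeneity for a 2x2 table
#'
#' Pearson test, df = 1, no continuity correction (wraps
#' `stats::chisq.test(correct = FALSE)`).
#'
#' @param table 2x2 matrix of counts with positive row and column totals.
#' @return A `chisq_result` list.
#' @export
chisq_homogeneity <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in 2x2 table")
  }
  # small expected cells are routine here (cohorts of tens of targets); the
  # plain Pearson statistic is reported regardless
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  res <- list(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p = ct$p.value,
    observed = table,
    expected = ct$expected
  )
  class(res) <- "chisq_result"
  res
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}
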