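# Differential calls for pooled, no-replicate HOM/WT library pairs.
#
# Each mutant line contributes one pooled HOM library and one WT control
# library per tissue, so there is no within-group replication. Dispersion is
# therefore borrowed across genes: a method-of-moments estimate per gene from
# the paired normalized counts, pooled across pairs, followed by a trend fit
# alpha(mu) = a0 + a1/mu. The pair test itself is an exact conditional
# negative-binomial test on the observed total.

#' Median-of-ratios size factors
#'
#' The DESeq-family normalization: for each library, the median across genes
#' of the ratio of its count to the per-gene geometric mean, using only genes
#' with nonzero counts in every library. Normalized count = raw / factor.
#'
#' @param counts Numeric matrix, genes x libraries, raw counts.
#' @return Named positive numeric vector of size factors (one per library).
#' @export
compute_size_factors <- function(counts) {
  if (ncol(counts) < 2) stop("need at least two libraries")
  log_gm <- rowMeans(log(counts))
  usable <- is.finite(log_gm)
  if (!any(usable)) stop("no gene has nonzero counts in all libraries")
  sf <- apply(counts, 2, function(col) {
    exp(stats::median(log(col[usable]) - log_gm[usable]))
  })
  names(sf) <- colnames(counts)
  sf
}

#' Fit a cross-gene dispersion trend from HOM/WT pairs
#'
#' Per gene, a method-of-moments raw dispersion is formed from the paired
#' normalized counts, pooled across pairs: with x_h = k_h/s_h, x_w = k_w/s_w,
#' the half squared difference (x_h - x_w)^2 / 2 estimates
#' mu * (1/s_h + 1/s_w)/2 + alpha * mu^2 under a common pair mean, giving
#' alpha_hat = (v - c * mu) / mu^2. Raw estimates (which may be negative) are
#' averaged within mean-expression bins and the trend alpha(mu) = a0 + a1/mu
#' is fit to the bin means by weighted least squares; the fitted curve is
#' floored at `alpha_min`.
#'
#' @param counts Raw count matrix, genes x libraries.
#' @param pairs Tibble with columns `hom_library`, `wt_library`.
#' @param size_factors Optional named size factors; computed if missing.
#' @param alpha_min Dispersion floor (default 0.01).
#' @param n_bins Number of mean-expression bins for the trend fit.
#' @return A `dispersion_model` list with `a0`, `a1`, `alpha_min`.
#' @export
fit_dispersion_trend <- function(counts, pairs, size_factors = NULL,
                                 alpha_min = 0.01, n_bins = 20) {
  check_pairs(pairs, counts)
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  s_h <- size_factors[pairs$hom_library]
  s_w <- size_factors[pairs$wt_library]
  xh <- sweep(counts[, pairs$hom_library, drop = FALSE], 2, s_h, "/")
  xw <- sweep(counts[, pairs$wt_library, drop = FALSE], 2, s_w, "/")
  mu <- rowMeans((xh + xw) / 2)
  v <- rowMeans((xh - xw)^2 / 2)
  cbar <- mean((1 / s_h + 1 / s_w) / 2)
  use <- mu > 0
  if (sum(use) < 20) stop("fewer than 20 genes with nonzero mean")
  mu <- mu[use]
  alpha_raw <- (v[use] - cbar * mu) / mu^2

  # bin by mean expression; bin means keep the raw estimates mean-unbiased
  # (a robust fit on the heavily skewed per-gene values would not be)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  bm_alpha <- tapply(alpha_raw, bin, mean)
  bm_invmu <- tapply(1 / mu, bin, mean)
  bw <- tapply(alpha_raw, bin, length)
  keep <- !is.na(bm_alpha)
  if (sum(keep) >= 2) {
    fit <- stats::lm(y ~ x, data = data.frame(y = bm_alpha[keep],
                                              x = bm_invmu[keep]),
                     weights = bw[keep])
    a0 <- unname(stats::coef(fit)[1])
    a1 <- unname(stats::coef(fit)[2])
  } else {
    # degenerate mean range (e.g. constant counts): flat trend
    a0 <- mean(alpha_raw)
    a1 <- 0
  }
  if (is.na(a1)) a1 <- 0
  model <- list(a0 = a0, a1 = a1, alpha_min = alpha_min)
  class(model) <- "dispersion_model"
  model
}

#' Evaluate a dispersion trend at given means
#'
#' @param model A `dispersion_model`.
#' @param mu Positive normalized means.
#' @return Dispersions `pmax(a0 + a1/mu, alpha_min)`.
#' @export
dispersion_at <- function(model, mu) {
  stopifnot(inherits(model, "dispersion_model"))
  pmax(model$a0 + model$a1 / mu, model$alpha_min)
}

#' Exact conditional NB test for one HOM/WT gene pair
#'
#' Under the null the two libraries share a common mean, estimated as
#' mu = (k_hom + k_wt) / (s_hom + s_wt). Conditioning on the observed total
#' N = k_hom + k_wt, the null distribution of the HOM count is proportional
#' to dnbinom(a; mu = s_hom * mu, size = 1/alpha) * dnbinom(N - a; ...) over
#' a = 0..N. The two-sided p-value doubles the smaller tail (observed point
#' included in both tails), capped at 1.
#'
#' @param k_hom,k_wt Raw counts.
#' @param s_hom,s_wt Size factors.
#' @param disp A `dispersion_model` (or a single numeric dispersion).
#' @return Two-sided p-value in (0, 1].
#' @export
nb_pair_test <- function(k_hom, k_wt, s_hom, s_wt, disp) {
  n_tot <- k_hom + k_wt
  if (n_tot == 0) return(1)
  mu <- n_tot / (s_hom + s_wt)
  alpha <- if (inherits(disp, "dispersion_model")) {
    dispersion_at(disp, mu)
  } else {
    as.numeric(disp)
  }
  size <- 1 / alpha
  a <- 0:n_tot
  logw <- stats::dnbinom(a, size = size, mu = s_hom * mu, log = TRUE) +
    stats::dnbinom(n_tot - a, size = size, mu = s_wt * mu, log = TRUE)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  lower <- sum(w[a <= k_hom])
  upper <- sum(w[a >= k_hom])
  min(1, 2 * min(lower, upper))
}

check_pairs <- function(pairs, counts) {
  needed <- c("hom_library", "wt_library")
  if (!all(needed %in% names(pairs))) {
    stop("pairs must have columns hom_library and wt_library")
  }
  libs <- colnames(counts)
  absent <- setdiff(c(pairs$hom_library, pairs$wt_library), libs)
  if (length(absent) > 0) {
    stop("unknown library in pairs: ", paste(absent, collapse = ", "))
  }
  invisible(pairs)
}

#' Build HOM/WT library pairs from metadata
#'
#' One pair per (line, tissue) with a HOM library; the WT member is the WT
#' library of the same line and tissue if present, otherwise the shared WT
#' control of that tissue (line `"WT"`).
#'
#' @param meta Library-metadata tibble.
#' @return Tibble with `line`, `tissue`, `hom_library`, `wt_library`.
#' @export
make_pairs <- function(meta) {
  hom <- meta[meta$genotype == "HOM", ]
  wt <- meta[meta$genotype == "WT", ]
  if (nrow(hom) == 0 || nrow(wt) == 0) stop("need both HOM and WT libraries")
  wt_key <- stats::setNames(wt$library_id, paste(wt$line, wt$tissue))
  wt_shared <- stats::setNames(wt$library_id[wt$line == "WT"],
                               wt$tissue[wt$line == "WT"])
  wt_lib <- ifelse(!is.na(wt_key[paste(hom$line, hom$tissue)]),
                   wt_key[paste(hom$line, hom$tissue)],
                   wt_shared[hom$tissue])
  if (anyNA(wt_lib)) {
    stop("no WT control library for: ",
         paste(paste(hom$line, hom$tissue)[is.na(wt_lib)], collapse = ", "))
  }
  tibble::tibble(line = hom$line, tissue = hom$tissue,
                 hom_library = hom$library_id, wt_library = unname(wt_lib))
}

#' Per-gene differential calls for HOM/WT pairs
#'
#' Normalizes with median-of-ratios size factors, fits (or reuses) the
#' dispersion trend, runs the exact conditional NB test for every gene in
#' every pair, adjusts p-values by Benjamini-Hochberg within each pair
#' (reported, not used for direction), and assigns direction: `up` if
#' p_unadjusted < alpha and hom_norm > wt_norm, `down` if p_unadjusted <
#' alpha and hom_norm < wt_norm, otherwise `ns`.
#'
#' @param counts Raw count matrix, genes x libraries.
#' @param pairs Tibble with `hom_library`, `wt_library` (extra columns such
#'   as `line`/`tissue` are carried through).
#' @param alpha Significance level on the unadjusted p-value (default 0.05).
#' @param disp Optional `dispersion_model`; fitted from `counts` if NULL.
#' @param pseudocount Pseudocount for the log2 ratio (default 0.5).
#' @return Tibble of calls: one row per (gene, pair) with normalized counts,
#'   `log2_ratio`, `p_unadjusted`, `p_adjusted`, `direction`.
#' @export
call_differential <- function(counts, pairs, alpha = 0.05, disp = NULL,
                              pseudocount = 0.5) {
  check_pairs(pairs, counts)
  sf <- compute_size_factors(counts)
  if (is.null(disp)) disp <- fit_dispersion_trend(counts, pairs, sf)
  out <- vector("list", nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    hlib <- pairs$hom_library[j]
    wlib <- pairs$wt_library[j]
    kh <- unname(counts[, hlib])
    kw <- unname(counts[, wlib])
    sh <- sf[[hlib]]
    sw <- sf[[wlib]]
    p <- vapply(seq_along(kh), function(i) {
      nb_pair_test(kh[i], kw[i], sh, sw, disp)
    }, numeric(1))
    hn <- kh / sh
    wn <- kw / sw
    res <- tibble::tibble(
      gene_id = rownames(counts),
      hom_library = hlib,
      wt_library = wlib,
      hom_norm = hn,
      wt_norm = wn,
      log2_ratio = log2((hn + pseudocount) / (wn + pseudocount)),
      p_unadjusted = p,
      p_adjusted = stats::p.adjust(p, method = "BH"),
      direction = ifelse(p < alpha & hn > wn, "up",
                         ifelse(p < alpha & hn < wn, "down", "ns"))
    )
    extra <- setdiff(names(pairs), c("hom_library", "wt_library"))
    for (col in extra) res[[col]] <- pairs[[col]][j]
    out[[j]] <- res
  }
  dplyr::bind_rows(out)
}
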