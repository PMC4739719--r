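# Strand-aware +/-500 kb flanking-gene survey around targeted genes.
#
# Distances are centrum-to-centrum and strand-adjusted: negative = 5' of the
# target's transcription direction, positive = 3'. The targeted gene itself
# is never counted among its neighbors.

#' Signed, strand-adjusted centrum distance
#'
#' `d = centrum(neighbor) - centrum(target)`, negated when the target is on
#' the minus strand, so that negative distances are 5' of the target in its
#' transcription direction and positive distances 3'.
#'
#' @param target One-row gene-model tibble (the targeted gene).
#' @param neighbors Gene-model tibble of neighbors on the same chromosome.
#' @return Numeric vector of signed distances in bp, named by neighbor id.
#' @export
strand_adjusted_distance <- function(target, neighbors) {
  if (nrow(target) != 1) stop("target must be a single gene")
  if (!all(neighbors$chromosome == target$chromosome)) {
    stop("neighbor on a different chromosome than target ", target$gene_id)
  }
  d <- gene_centrum(neighbors) - unname(gene_centrum(target))
  if (target$strand == "-") d <- -d
  d
}

#' Extract the flanking-gene neighborhood of a target
#'
#' All genes (and miRNAs; every annotated gene model counts) other than the
#' target itself whose centrum lies within `window` bp of the target's
#' centrum on the same chromosome. The window boundary is inclusive.
#'
#' @param target_id Gene id of the target.
#' @param gm Gene-model tibble.
#' @param window Half-width in bp (default 500000).
#' @return Tibble with `gene_id` and signed `centrum_distance`, sorted by
#'   distance.
#' @export
extract_neighborhood <- function(target_id, gm, window = 500000) {
  ti <- which(gm$gene_id == target_id)
  if (length(ti) != 1) stop("target absent from annotation: ", target_id)
  target <- gm[ti, ]
  cand <- gm[gm$chromosome == target$chromosome &
               gm$gene_id != target_id, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::tibble(gene_id = character(0), centrum_distance = numeric(0)))
  }
  d <- strand_adjusted_distance(target, cand)
  keep <- abs(d) <= window
  out <- tibble::tibble(gene_id = cand$gene_id[keep], centrum_distance = d[keep])
  out[order(out$centrum_distance), ]
}

#' Summarize the differential calls around one target
#'
#' Joins a target's neighborhood to the differential calls of that target's
#' library pairs and reports per-library and target-level dysregulation
#' flags (`has_up`/`has_down`; target level = OR over libraries), plus the
#' dysregulated neighbor list. The targeted gene is excluded.
#'
#' @param target_id Gene id of the target.
#' @param gm Gene-model tibble.
#' @param calls Differential-call tibble for this target's pairs (rows for
#'   other genes are ignored via the neighborhood join).
#' @param window Half-width in bp.
#' @return List with `summary` (one row), `libraries` (one row per pair) and
#'   `dysregulated` (one row per dysregulated neighbor x library).
#' @export
summarize_target <- function(target_id, gm, calls, window = 500000) {
  nb <- extract_neighborhood(target_id, gm, window)
  calls_nb <- dplyr::inner_join(nb, calls, by = "gene_id")
  pair_ids <- unique(calls$hom_library)
  per_lib <- dplyr::summarise(
    dplyr::group_by(calls_nb, .data$hom_library),
    has_up = any(.data$direction == "up"),
    has_down = any(.data$direction == "down"),
    .groups = "drop"
  )
  # pairs with no neighbor rows still count as libraries without effects
  missing_libs <- setdiff(pair_ids, per_lib$hom_library)
  if (length(missing_libs) > 0) {
    per_lib <- dplyr::bind_rows(
      per_lib,
      tibble::tibble(hom_library = missing_libs, has_up = FALSE, has_down = FALSE)
    )
  }
  per_lib <- dplyr::mutate(per_lib, target = target_id, .before = 1)
  dys <- calls_nb[calls_nb$direction %in% c("up", "down"),
                  c("gene_id", "centrum_distance", "direction", "hom_library")]
  dys <- dplyr::mutate(dys, target = target_id, .before = 1)
  list(
    summary = tibble::tibble(
      target = target_id,
      n_genes_in_window = nrow(nb),
      has_up = any(per_lib$has_up),
      has_down = any(per_lib$has_down)
    ),
    libraries = per_lib,
    dysregulated = dys
  )
}

#' Survey the neighborhoods of a cohort of targets
#'
#' Runs [summarize_target()] for every allele, selecting each target's
#' library pairs by the `line` column of `calls`.
#'
#' @param alleles Allele tibble (`gene_id`, `allele_class`, ...).
#' @param gm Gene-model tibble.
#' @param calls Differential-call tibble with a `line` column naming the
#'   mutant line each pair belongs to.
#' @param window Half-width in bp.
#' @return A `neighborhood_survey` list with `targets`, `libraries` and
#'   `dysregulated` tibbles (all carrying `allele_class`).
#' @export
survey_neighborhoods <- function(alleles, gm, calls, window = 500000) {
  if (!"line" %in% names(calls)) {
    stop("calls must carry a 'line' column naming the mutant line")
  }
  res <- lapply(seq_len(nrow(alleles)), function(i) {
    tid <- alleles$gene_id[i]
    calls_i <- calls[calls$line == tid, , drop = FALSE]
    s <- summarize_target(tid, gm, calls_i, window)
    s$summary$allele_class <- alleles$allele_class[i]
    if (nrow(s$dysregulated) > 0) {
      s$dysregulated$allele_class <- alleles$allele_class[i]
    }
    s$libraries$allele_class <- alleles$allele_class[i]
    s
  })
  out <- list(
    targets = dplyr::bind_rows(lapply(res, `[[`, "summary")),
    libraries = dplyr::bind_rows(lapply(res, `[[`, "libraries")),
    dysregulated = dplyr::bind_rows(lapply(res, `[[`, "dysregulated"))
  )
  if (nrow(out$dysregulated) == 0) {
    out$dysregulated <- tibble::tibble(
      target = character(0), gene_id = character(0),
      centrum_distance = numeric(0), direction = character(0),
      hom_library = character(0), allele_class = character(0)
    )
  }
  class(out) <- c("neighborhood_survey", class(out))
  out
}

#' Cohort frequencies of local dysregulation
#'
#' Percentage of targets (or libraries) of one allele class with at least
#' one up- (down-) regulated gene within the window.
#'
#' @param survey A `neighborhood_survey`.
#' @param by `"target"` or `"library"`.
#' @param class `"DEL"`, `"TRAP"`, or NULL for all.
#' @return One-row tibble: `n`, `pct_up`, `pct_down`.
#' @export
cohort_frequencies <- function(survey, by = c("target", "library"),
                               class = NULL) {
  by <- match.arg(by)
  tab <- if (by == "target") survey$targets else survey$libraries
  if (!is.null(class)) tab <- tab[tab$allele_class == class, , drop = FALSE]
  if (nrow(tab) == 0) stop("no ", by, " rows in class ", class %||% "(all)")
  tibble::tibble(
    by = by,
    allele_class = class %||% "all",
    n = nrow(tab),
    pct_up = 100 * mean(tab$has_up),
    pct_down = 100 * mean(tab$has_down)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spatial topography of dysregulated neighbors
#'
#' Bins dysregulated neighbors by signed strand-adjusted distance into
#' fixed-width intervals tiling [-window, +window) and reports the medians
#' the survey cares about: median |d| of down-regulated neighbors, median d
#' of 3'-up-regulated neighbors, median |d| of 5'-up-regulated neighbors,
#' and the 5'/3' split of up-regulated neighbors.
#'
#' @param dysregulated Dysregulated tibble from a survey (columns `target`,
#'   `gene_id`, `centrum_distance`, `direction`, `hom_library`).
#' @param bin_width Bin width in bp (default 50000).
#' @param window Half-width in bp (default 500000).
#' @param dedupe `"pair"` counts each unique (target, neighbor, direction)
#'   once across libraries; `"instance"` counts every library occurrence.
#' @return List with `bins` (tibble `lo`, `hi` in kb, `count_up`,
#'   `count_down`), `medians` (named list, kb; NA when a subset is empty),
#'   `pct_up_3prime`, `pct_up_5prime`, and `n_dysregulated`.
#' @export
topography <- function(dysregulated, bin_width = 50000, window = 500000,
                       dedupe = c("pair", "instance")) {
  dedupe <- match.arg(dedupe)
  d <- dysregulated
  if (dedupe == "pair") {
    d <- dplyr::distinct(d, .data$target, .data$gene_id, .data$direction,
                         .keep_all = TRUE)
  }
  edges <- seq(-window, window, by = bin_width)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  assign_bin <- function(x) {
    # half-open tiling [lo, hi); the closing boundary +window folds into the
    # last bin so the inclusive window edge is representable
    b <- findInterval(x, edges, rightmost.closed = TRUE)
    pmin(pmax(b, 1L), length(lo))
  }
  up <- d[d$direction == "up", , drop = FALSE]
  down <- d[d$direction == "down", , drop = FALSE]
  count_in_bins <- function(x) {
    tabulate(assign_bin(x), nbins = length(lo))
  }
  bins <- tibble::tibble(
    lo = lo / 1000, hi = hi / 1000,
    count_up = count_in_bins(up$centrum_distance),
    count_down = count_in_bins(down$centrum_distance)
  )
  med <- function(x) if (length(x) == 0) NA_real_ else stats::median(x)
  up3 <- up$centrum_distance[up$centrum_distance > 0]
  up5 <- up$centrum_distance[up$centrum_distance < 0]
  list(
    bins = bins,
    medians = list(
      abs_down_kb = med(abs(down$centrum_distance)) / 1000,
      up_3prime_kb = med(up3) / 1000,
      abs_up_5prime_kb = med(abs(up5)) / 1000
    ),
    pct_up_3prime = if (nrow(up) == 0) NA_real_ else 100 * length(up3) / nrow(up),
    pct_up_5prime = if (nrow(up) == 0) NA_real_ else 100 * length(up5) / nrow(up),
    n_dysregulated = nrow(d)
  )
}

#' Gene density around targets with vs without local effects
#'
#' Mean number of genes in the window for targets with at least one up- or
#' down-regulated neighbor, versus targets with none.
#'
#' @param survey A `neighborhood_survey` (or its `targets` tibble).
#' @return Tibble with one row per group (`with_effects`, `without_effects`):
#'   `n_targets`, `mean_genes_in_window` (NA for an empty group).
#' @export
gene_density_contrast <- function(survey) {
  tab <- if (is.data.frame(survey)) survey else survey$targets
  any_eff <- tab$has_up | tab$has_down
  grp <- function(sel, label) {
    tibble::tibble(
      group = label,
      n_targets = sum(sel),
      mean_genes_in_window = if (any(sel)) mean(tab$n_genes_in_window[sel]) else NA_real_
    )
  }
  dplyr::bind_rows(grp(any_eff, "with_effects"), grp(!any_eff, "without_effects"))
}
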