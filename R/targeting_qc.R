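# Targeting-confirmation screen: read-count flag criteria plus an
# exon-coverage pattern classifier (confirmed null, complete trap,
# splice-around, uniform hypomorph, distal retention, intronic-only, failed
# targeting, indeterminate).

qc_verdicts <- c("confirmed_null", "trap_complete", "splice_around",
                 "uniform_hypomorph", "distal_retention", "intronic_only",
                 "failed_targeting", "indeterminate")

#' Construct an exon profile
#'
#' Per-exon normalized read counts ordered 5' to 3' in transcription
#' direction, plus the gene's intronic read total.
#'
#' @param gene_id,library_id Identifiers.
#' @param exon_counts Non-negative numeric vector, transcription order.
#' @param intronic_reads Non-negative scalar (default 0).
#' @return An `exon_profile` list.
#' @export
exon_profile <- function(gene_id, library_id, exon_counts, intronic_reads = 0) {
  if (any(exon_counts < 0) || intronic_reads < 0) {
    stop("exon profile counts must be non-negative")
  }
  structure(list(gene_id = gene_id, library_id = library_id,
                 exon_counts = as.numeric(exon_counts),
                 intronic_reads = as.numeric(intronic_reads)),
            class = "exon_profile")
}

#' Flag a mutant library for targeting inspection
#'
#' TRUE when the gene is expressed enough to judge (at least 100 normalized
#' reads in either library) and the mutant retains at least 20% of wild-type
#' reads -- i.e. total read counts alone cannot confirm the knockout and the
#' exon pattern needs inspection. Boundary-inclusive on both thresholds.
#'
#' @param hom_total,wt_total Normalized read totals for the targeted gene
#'   (vectorized).
#' @param min_reads Expression floor (default 100).
#' @param ratio Retained-expression threshold (default 0.20).
#' @return Logical vector.
#' @export
flag_for_inspection <- function(hom_total, wt_total, min_reads = 100,
                                ratio = 0.20) {
  if (any(hom_total < 0) || any(wt_total < 0)) stop("counts must be non-negative")
  pmax(hom_total, wt_total) >= min_reads & hom_total >= ratio * wt_total
}

#' Classify the exon-coverage pattern of a mutant gene
#'
#' Decision cascade over a HOM/WT exon-profile pair, most specific
#' structural evidence first (F = expression floor, r = presence ratio;
#' profile totals include intronic reads):
#' \enumerate{
#'   \item both totals < F: \code{indeterminate};
#'   \item DEL with mutant reads on the deleted exons at >= r of WT (and
#'     nonzero): \code{failed_targeting};
#'   \item DEL with mutant reads predominantly intronic: \code{intronic_only};
#'   \item partial DEL with deleted-exon reads < r of WT and retained exons
#'     at or above WT level: \code{distal_retention};
#'   \item TRAP with every post-trap exon below F: \code{trap_complete};
#'   \item TRAP with an initial run of post-trap exons below F followed by
#'     exons at >= r of WT: \code{splice_around};
#'   \item every exon at a uniformly reduced level (per-exon HOM/WT ratio
#'     within 2-fold of the gene-level ratio, gene ratio < 1):
#'     \code{uniform_hypomorph};
#'   \item otherwise \code{confirmed_null} if the mutant total is below r of
#'     WT, else \code{failed_targeting}.
#' }
#'
#' @param hom,wt `exon_profile` objects (HOM mutant and WT control).
#' @param allele One row of an allele tibble (see [read_alleles()]).
#' @param model One row of a gene-model tibble.
#' @param floor Expression floor F in normalized reads (default 100).
#' @param ratio Presence ratio r (default 0.20).
#' @param pseudocount Pseudocount for per-exon ratios (default 0.5).
#' @return A `qc_classification` list: `verdict`, `evidence` (per-exon
#'   tibble), `gene_id`.
#' @export
classify_exon_pattern <- function(hom, wt, allele, model, floor = 100,
                                  ratio = 0.20, pseudocount = 0.5) {
  n_exons <- nrow(model$exons[[1]])
  if (length(hom$exon_counts) != n_exons || length(wt$exon_counts) != n_exons) {
    stop("exon profile length does not match the gene model (",
         model$gene_id, ": ", n_exons, " exons)")
  }
  if (allele$gene_id != model$gene_id) {
    stop("allele and gene model describe different genes")
  }
  validate_alleles(tibble::as_tibble(allele), model)
  h <- hom$exon_counts
  w <- wt$exon_counts
  hom_total <- sum(h) + hom$intronic_reads
  wt_total <- sum(w) + wt$intronic_reads
  is_del <- allele$allele_class == "DEL"
  evidence <- tibble::tibble(
    exon = seq_len(n_exons),
    hom = h, wt = w,
    ratio = (h + pseudocount) / (w + pseudocount)
  )
  done <- function(v) {
    structure(list(verdict = v, evidence = evidence, gene_id = model$gene_id),
              class = "qc_classification")
  }

  # 1. neither library expresses the gene: nothing to judge
  if (hom_total < floor && wt_total < floor) return(done("indeterminate"))

  if (is_del) {
    del_idx <- seq(allele$deleted_exon_first, allele$deleted_exon_last)
    h_del <- sum(h[del_idx])
    w_del <- sum(w[del_idx])
    # 2. reads persist on exons targeted for deletion
    if (h_del > 0 && h_del >= ratio * w_del) return(done("failed_targeting"))
    # 3. mutant reads predominantly intronic
    if (hom$intronic_reads > sum(h)) return(done("intronic_only"))
    # 4. partial deletion with the retained exons at or above WT
    retained <- setdiff(seq_len(n_exons), del_idx)
    if (length(retained) > 0 && h_del < ratio * w_del &&
        sum(h[retained]) >= sum(w[retained])) {
      return(done("distal_retention"))
    }
  } else {
    post <- seq(allele$trap_insertion_intron + 1, n_exons)
    # 5. trap terminates transcription: nothing beyond the trap intron
    if (all(h[post] < floor)) return(done("trap_complete"))
    # 6. exons skipped right after the trap, then distal resumption
    below <- h[post] < floor
    run <- if (below[1]) which.min(c(below, FALSE)) - 1L else 0L
    if (run >= 1 && run < length(post)) {
      rest <- post[(run + 1):length(post)]
      if (all((h[rest] + pseudocount) >= ratio * (w[rest] + pseudocount))) {
        return(done("splice_around"))
      }
    }
  }

  # 7. all exons present at a uniformly reduced level
  gene_ratio <- (sum(h) + pseudocount) / (sum(w) + pseudocount)
  if (gene_ratio < 1 &&
      all(evidence$ratio >= gene_ratio / 2 & evidence$ratio <= gene_ratio * 2)) {
    return(done("uniform_hypomorph"))
  }

  # 8. fall back to the total-count criterion
  if (hom_total < ratio * wt_total) done("confirmed_null") else done("failed_targeting")
}

#' @export
print.qc_classification <- function(x, ...) {
  cat(sprintf("targeting QC for %s: %s\n", x$gene_id, x$verdict))
  invisible(x)
}

#' Cohort targeting-QC summary
#'
#' Aggregates flag and classification results per allele class. A mutant is
#' flagged when any of its libraries triggers [flag_for_inspection()];
#' targeting is considered confirmed for every verdict except
#' `failed_targeting` and `indeterminate`.
#'
#' @param flags Tibble with `target`, `allele_class`, `library`, `hom_total`,
#'   `wt_total` (one row per mutant x library).
#' @param classifications Tibble with `target`, `allele_class`, `verdict`
#'   (one row per mutant).
#' @return List with `by_class` (per-class `n`, `pct_flagged`,
#'   `pct_confirmed`) and `verdicts` (per-class verdict percentages).
#' @export
cohort_qc <- function(flags, classifications) {
  if (nrow(classifications) == 0) stop("no mutants to summarize")
  fl <- dplyr::mutate(flags,
                      flagged = flag_for_inspection(.data$hom_total, .data$wt_total))
  fl_target <- dplyr::summarise(
    dplyr::group_by(fl, .data$allele_class, .data$target),
    flagged = any(.data$flagged), .groups = "drop"
  )
  by_flag <- dplyr::summarise(
    dplyr::group_by(fl_target, .data$allele_class),
    n = dplyr::n(),
    pct_flagged = 100 * mean(.data$flagged),
    .groups = "drop"
  )
  cls <- dplyr::mutate(
    classifications,
    confirmed = !.data$verdict %in% c("failed_targeting", "indeterminate")
  )
  by_conf <- dplyr::summarise(
    dplyr::group_by(cls, .data$allele_class),
    pct_confirmed = 100 * mean(.data$confirmed),
    .groups = "drop"
  )
  verdicts <- dplyr::summarise(
    dplyr::group_by(cls, .data$allele_class, .data$verdict),
    n = dplyr::n(), .groups = "drop_last"
  )
  verdicts <- dplyr::mutate(verdicts, pct = 100 * .data$n / sum(.data$n))
  verdicts <- dplyr::ungroup(verdicts)
  list(
    by_class = dplyr::full_join(by_flag, by_conf, by = "allele_class"),
    verdicts = verdicts
  )
}
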