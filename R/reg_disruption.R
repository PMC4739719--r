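# Regulatory-element disruption scoring from TFBS and ChIP-peak intervals.
#
# TRAP rule: the cassette sits between the promoter and any TFBS lying 3'
# (transcription direction) of the insertion intron, so >= 2 high-confidence
# TFBS in that region score the event as likely disruptive. DEL rule: >= 2
# TFBS of any confidence inside the deleted span, corroborated by >= 1
# overlapping ChIP peak (Pol2/CTCF/p300).

#' Genomic span of a DEL allele's deleted exons
#'
#' @param allele One row of an allele tibble (DEL).
#' @param model Matching one-row gene-model tibble.
#' @return Numeric `c(start, end)`, 1-based inclusive.
#' @export
deleted_span <- function(allele, model) {
  if (allele$allele_class != "DEL") stop("deleted_span needs a DEL allele")
  tx <- exon_order_tx(model)
  idx <- tx[seq(allele$deleted_exon_first, allele$deleted_exon_last)]
  ex <- model$exons[[1]]
  c(min(ex$start[idx]), max(ex$end[idx]))
}

#' Gene-body region 3' of a TRAP insertion intron
#'
#' From the transcription-side start of the first post-trap exon to the 3'
#' end of the gene, in genomic coordinates.
#'
#' @param allele One row of an allele tibble (TRAP).
#' @param model Matching one-row gene-model tibble.
#' @return Numeric `c(start, end)`, 1-based inclusive.
#' @export
post_trap_region <- function(allele, model) {
  if (allele$allele_class != "TRAP") stop("post_trap_region needs a TRAP allele")
  tx <- exon_order_tx(model)
  first_post <- tx[allele$trap_insertion_intron + 1]
  ex <- model$exons[[1]]
  if (model$strand == "+") {
    c(ex$start[first_post], model$end)
  } else {
    c(model$start, ex$end[first_post])
  }
}

#' Score a TRAP targeting event for regulatory disruption
#'
#' Disrupted iff at least two high-confidence TFBS lie entirely within the
#' gene body 3' of the insertion intron (the region the cassette separates
#' from the promoter). ChIP peaks overlapping that region are counted as
#' side information but are not required.
#'
#' @param allele One row of an allele tibble (TRAP).
#' @param model Matching one-row gene-model tibble.
#' @param tfbs TFBS tibble (see [read_tfbs_bed()]).
#' @param chip ChIP-peak tibble (see [read_chip_bed()]); optional.
#' @return Tibble row: `gene_id`, `allele_class`, `disrupted`,
#'   `n_tfbs_affected`, `n_chip_corroborating`.
#' @export
score_trap <- function(allele, model, tfbs, chip = NULL) {
  if (allele$allele_class != "TRAP") stop("score_trap needs a TRAP allele")
  region <- post_trap_region(allele, model)
  hit <- tfbs$chromosome == model$chromosome &
    tfbs$confidence == "high" &
    tfbs$start >= region[1] & tfbs$end <= region[2]
  n_tfbs <- sum(hit)
  n_chip <- if (is.null(chip)) 0L else {
    sum(chip$chromosome == model$chromosome &
          chip$start <= region[2] & chip$end >= region[1])
  }
  tibble::tibble(
    gene_id = model$gene_id,
    allele_class = "TRAP",
    disrupted = n_tfbs >= 2,
    n_tfbs_affected = n_tfbs,
    n_chip_corroborating = n_chip
  )
}

#' Score a DEL targeting event for regulatory disruption
#'
#' Disrupted iff at least two TFBS (any confidence) lie entirely within the
#' deleted span and at least one ChIP peak overlaps the span.
#'
#' @inheritParams score_trap
#' @param allele One row of an allele tibble (DEL).
#' @param chip ChIP-peak tibble (required for corroboration).
#' @return Tibble row as in [score_trap()].
#' @export
score_del <- function(allele, model, tfbs, chip) {
  if (allele$allele_class != "DEL") stop("score_del needs a DEL allele")
  span <- deleted_span(allele, model)
  hit <- tfbs$chromosome == model$chromosome &
    tfbs$start >= span[1] & tfbs$end <= span[2]
  n_tfbs <- sum(hit)
  n_chip <- sum(chip$chromosome == model$chromosome &
                  chip$start <= span[2] & chip$end >= span[1])
  tibble::tibble(
    gene_id = model$gene_id,
    allele_class = "DEL",
    disrupted = n_tfbs >= 2 && n_chip >= 1,
    n_tfbs_affected = n_tfbs,
    n_chip_corroborating = n_chip
  )
}

#' Score a cohort of targeting events
#'
#' @param alleles Allele tibble.
#' @param gm Gene-model tibble.
#' @param tfbs,chip Interval tibbles.
#' @return Tibble of per-target calls.
#' @export
score_cohort <- function(alleles, gm, tfbs, chip) {
  rows <- lapply(seq_len(nrow(alleles)), function(i) {
    allele <- alleles[i, ]
    model <- gm[gm$gene_id == allele$gene_id, ]
    if (nrow(model) != 1) stop("allele target absent from annotation: ",
                               allele$gene_id)
    if (allele$allele_class == "TRAP") {
      score_trap(allele, model, tfbs, chip)
    } else {
      score_del(allele, model, tfbs, chip)
    }
  })
  dplyr::bind_rows(rows)
}

#' Cohort disruption frequency and DEL-vs-TRAP comparison
#'
#' @param calls Per-target call tibble from [score_cohort()].
#' @return List with `by_class` (fractions disrupted per class) and `test`
#'   (a `chisq_result` comparing DEL vs TRAP when both classes are present).
#' @export
cohort_disruption_frequency <- function(calls) {
  if (nrow(calls) == 0) stop("empty cohort")
  by_class <- dplyr::summarise(
    dplyr::group_by(calls, .data$allele_class),
    n = dplyr::n(),
    n_disrupted = sum(.data$disrupted),
    pct_disrupted = 100 * mean(.data$disrupted),
    .groups = "drop"
  )
  test <- NULL
  if (all(c("DEL", "TRAP") %in% by_class$allele_class)) {
    tab <- with(calls, table(factor(allele_class, c("DEL", "TRAP")),
                             factor(disrupted, c(TRUE, FALSE))))
    test <- tryCatch(chisq_homogeneity(tab), error = function(e) NULL)
  }
  list(by_class = by_class, test = test)
}
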