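# End-to-end orchestration and reproduction from a supplementary-table
# export of per-neighborhood normalized counts and p-values.

#' Run the synthetic end-to-end pipeline
#'
#' Generates a synthetic cohort, calls differential expression for every
#' HOM/WT pair, surveys the +/-window neighborhoods, builds the genome-wide
#' empirical null with chi-square comparisons, screens targets with the
#' read-count flag criteria, and scores regulatory disruption on the planted
#' TFBS/ChIP fixtures. Deterministic for a given config.
#'
#' @param cfg A `synthetic_config`.
#' @param alpha Unadjusted significance level for calls (default 0.05).
#' @param window Neighborhood half-width in bp (default 500000).
#' @param bin_width Topography bin width in bp (default 50000).
#' @param dedupe Topography counting convention (see [topography()]).
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there as TSV.
#' @param stages Character subset of
#'   `c("de", "neighborhood", "null", "qc", "reg")`; later stages that need
#'   a disabled one are skipped too.
#' @return List with the stage results: `annotation`, `counts`, `calls`,
#'   `survey`, `frequencies`, `topography`, `density`, `null`, `null_tests`,
#'   `qc_flags`, `reg`, and `table1` (the frequency table in the shape of a
#'   genome-wide / DEL / TRAP comparison), plus `params`.
#' @export
run_pipeline <- function(cfg = synthetic_config(), alpha = 0.05,
                         window = 500000, bin_width = 50000,
                         dedupe = c("pair", "instance"), out_dir = NULL,
                         stages = c("de", "neighborhood", "null", "qc", "reg")) {
  dedupe <- match.arg(dedupe)
  res <- list(params = list(seed = cfg$seed, alpha = alpha, window = window,
                            bin_width = bin_width, dedupe = dedupe,
                            stages = stages))
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res$annotation <- step("simulate", generate_annotation(cfg))
  res$counts <- step("simulate", generate_counts(cfg, res$annotation))
  if (!"de" %in% stages) return(finish_pipeline(res, out_dir))
  res$calls <- step("de", call_differential(res$counts$counts,
                                            res$counts$pairs, alpha = alpha))
  if ("neighborhood" %in% stages) {
    res$survey <- step("neighborhood", survey_neighborhoods(
      res$annotation$alleles, res$annotation$gene_models, res$calls, window))
    res$frequencies <- dplyr::bind_rows(lapply(c("DEL", "TRAP"), function(cl) {
      dplyr::bind_rows(
        cohort_frequencies(res$survey, by = "target", class = cl),
        cohort_frequencies(res$survey, by = "library", class = cl)
      )
    }))
    res$topography <- lapply(
      stats::setNames(c("DEL", "TRAP"), c("DEL", "TRAP")),
      function(cl) {
        d <- res$survey$dysregulated
        topography(d[d$allele_class == cl, , drop = FALSE],
                   bin_width = bin_width, window = window, dedupe = dedupe)
      })
    res$density <- gene_density_contrast(res$survey)
  }
  if ("null" %in% stages) {
    res$null <- step("null", genome_wide_null(res$calls,
                                              res$annotation$gene_models,
                                              window))
    if (!is.null(res$survey)) {
      tt <- res$survey$targets
      res$null_tests <- dplyr::bind_rows(lapply(c("DEL", "TRAP"), function(cl) {
        sub <- tt[tt$allele_class == cl, ]
        dplyr::bind_rows(
          null_gof_row(cl, "up", sum(sub$has_up), nrow(sub), res$null$f_up),
          null_gof_row(cl, "down", sum(sub$has_down), nrow(sub), res$null$f_down)
        )
      }))
      res$table1 <- tibble::tibble(
        direction = c("up", "down"),
        genome_wide_pct = 100 * c(res$null$f_up, res$null$f_down),
        del_pct = c(res$frequencies$pct_up[res$frequencies$allele_class == "DEL" &
                                             res$frequencies$by == "target"],
                    res$frequencies$pct_down[res$frequencies$allele_class == "DEL" &
                                               res$frequencies$by == "target"]),
        trap_pct = c(res$frequencies$pct_up[res$frequencies$allele_class == "TRAP" &
                                              res$frequencies$by == "target"],
                     res$frequencies$pct_down[res$frequencies$allele_class == "TRAP" &
                                                res$frequencies$by == "target"])
      )
    }
  }
  if ("qc" %in% stages) {
    res$qc_flags <- step("qc", pipeline_qc_flags(res$counts, res$annotation))
  }
  if ("reg" %in% stages) {
    reg_ann <- step("reg", generate_reg_annotation(cfg, res$annotation))
    calls <- step("reg", score_cohort(res$annotation$alleles,
                                      res$annotation$gene_models,
                                      reg_ann$tfbs, reg_ann$chip))
    res$reg <- list(annotation = reg_ann, calls = calls,
                    summary = cohort_disruption_frequency(calls))
  }
  finish_pipeline(res, out_dir)
}

null_gof_row <- function(class, direction, hits, n, f_expected) {
  gof <- tryCatch(chisq_gof(c(hits, n - hits), f_expected),
                  error = function(e) NULL)
  tibble::tibble(
    allele_class = class, direction = direction,
    observed_pct = 100 * hits / n,
    expected_pct = 100 * f_expected,
    statistic = if (is.null(gof)) NA_real_ else gof$statistic,
    p = if (is.null(gof)) NA_real_ else gof$p
  )
}

pipeline_qc_flags <- function(counts, annotation) {
  sf <- compute_size_factors(counts$counts)
  norm <- sweep(counts$counts, 2, sf, "/")
  pairs <- counts$pairs
  cls <- stats::setNames(annotation$alleles$allele_class,
                         annotation$alleles$gene_id)
  rows <- pairs[pairs$line %in% names(cls), ]
  tibble::tibble(
    target = rows$line,
    allele_class = unname(cls[rows$line]),
    library = rows$hom_library,
    hom_total = norm[cbind(rows$line, rows$hom_library)],
    wt_total = norm[cbind(rows$line, rows$wt_library)]
  )
}

finish_pipeline <- function(res, out_dir) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, name) {
      if (!is.null(x)) readr::write_tsv(x, file.path(out_dir, name),
                                        progress = FALSE)
    }
    wr(res$calls, "differential_calls.tsv")
    if (!is.null(res$survey)) {
      wr(res$survey$targets, "neighborhood_targets.tsv")
      wr(res$survey$dysregulated, "neighborhood_dysregulated.tsv")
    }
    wr(res$frequencies, "cohort_frequencies.tsv")
    if (!is.null(res$topography)) {
      wr(res$topography$DEL$bins, "topography_bins_del.tsv")
      wr(res$topography$TRAP$bins, "topography_bins_trap.tsv")
    }
    wr(res$density, "gene_density.tsv")
    wr(res$null_tests, "null_comparisons.tsv")
    wr(res$table1, "frequency_table.tsv")
    wr(res$qc_flags, "qc_flags.tsv")
    if (!is.null(res$reg)) wr(res$reg$calls, "reg_disruption.tsv")
  }
  res
}

#' Recompute printed summaries from a supplementary-table export
#'
#' Given the per-library normalized counts and unadjusted p-values stored in
#' the supplementary-table dialect (see [read_s1_table()]), recomputes every
#' summary the neighborhood survey produces: per-class per-target and
#' per-library dysregulation frequencies, topography medians and the 5'/3'
#' split of up-regulated neighbors, total dysregulated pairs under both
#' counting conventions, gene-density means for targets with vs without
#' local effects, and the targeting flag fractions. Rows whose `gene`
#' matches the `line` (or its synonym) are the target's own records: they
#' feed the flag criteria and are excluded from all neighbor statistics.
#'
#' @param s1 Path to the export, or the tibble from [read_s1_table()].
#' @param classes Tibble mapping `line` to `allele_class` (DEL/TRAP).
#' @param alpha Unadjusted significance level (default 0.05).
#' @param bin_width,window Topography parameters in bp.
#' @return List: `calls`, `frequencies`, `topography` (per class, each with
#'   both dedupe conventions), `n_dysregulated` (both conventions, all
#'   classes), `density`, `flags`.
#' @export
reproduce_from_s1 <- function(s1, classes, alpha = 0.05, bin_width = 50000,
                              window = 500000) {
  if (is.character(s1)) s1 <- read_s1_table(s1)
  missing_cls <- setdiff(unique(s1$line), classes$line)
  if (length(missing_cls) > 0) {
    stop("no allele_class for lines: ", paste(missing_cls, collapse = ", "))
  }
  cls <- stats::setNames(classes$allele_class, classes$line)
  is_target <- s1$gene == s1$line |
    (!is.na(s1$synonym) & s1$gene == s1$synonym)
  s1$library <- paste(s1$line, s1$tissue, sep = "|")
  s1$direction <- ifelse(!is.na(s1$p_value) & s1$p_value < alpha & s1$hom > s1$wt,
                         "up",
                         ifelse(!is.na(s1$p_value) & s1$p_value < alpha &
                                  s1$hom < s1$wt, "down", "ns"))
  nb <- s1[!is_target, ]
  tg <- s1[is_target, ]

  # per-target and per-library flags over neighbors only
  by_target <- dplyr::summarise(
    dplyr::group_by(nb, .data$line),
    n_genes_in_window = dplyr::n_distinct(.data$gene),
    has_up = any(.data$direction == "up"),
    has_down = any(.data$direction == "down"),
    .groups = "drop"
  )
  by_target$allele_class <- unname(cls[by_target$line])
  by_library <- dplyr::summarise(
    dplyr::group_by(nb, .data$line, .data$library),
    has_up = any(.data$direction == "up"),
    has_down = any(.data$direction == "down"),
    .groups = "drop"
  )
  by_library$allele_class <- unname(cls[by_library$line])
  freq <- dplyr::bind_rows(lapply(c("DEL", "TRAP"), function(cl) {
    tt <- by_target[by_target$allele_class == cl, ]
    ll <- by_library[by_library$allele_class == cl, ]
    tibble::tibble(
      allele_class = cl,
      by = c("target", "library"),
      n = c(nrow(tt), nrow(ll)),
      pct_up = 100 * c(mean(tt$has_up), mean(ll$has_up)),
      pct_down = 100 * c(mean(tt$has_down), mean(ll$has_down))
    )
  }))

  dys <- nb[nb$direction %in% c("up", "down"),
            c("line", "gene", "centrum_distance", "direction", "library")]
  names(dys) <- c("target", "gene_id", "centrum_distance", "direction",
                  "hom_library")
  dys$allele_class <- unname(cls[dys$target])
  topo <- lapply(stats::setNames(c("DEL", "TRAP"), c("DEL", "TRAP")),
                 function(cl) {
    sub <- dys[dys$allele_class == cl, , drop = FALSE]
    list(pair = topography(sub, bin_width, window, dedupe = "pair"),
         instance = topography(sub, bin_width, window, dedupe = "instance"))
  })
  n_dys <- c(
    pair = nrow(dplyr::distinct(dys, .data$target, .data$gene_id,
                                .data$direction)),
    instance = nrow(dys)
  )
  density <- gene_density_contrast(by_target)

  flags_lib <- dplyr::summarise(
    dplyr::group_by(tg, .data$line, .data$library),
    flagged = any(flag_for_inspection(.data$hom, .data$wt)),
    .groups = "drop"
  )
  flags_target <- dplyr::summarise(
    dplyr::group_by(flags_lib, .data$line),
    flagged = any(.data$flagged), .groups = "drop"
  )
  flags_target$allele_class <- unname(cls[flags_target$line])
  flags <- dplyr::summarise(
    dplyr::group_by(flags_target, .data$allele_class),
    n = dplyr::n(),
    n_flagged = sum(.data$flagged),
    pct_flagged = 100 * mean(.data$flagged),
    .groups = "drop"
  )

  list(
    calls = s1,
    by_target = by_target,
    frequencies = freq,
    topography = topo,
    n_dysregulated = n_dys,
    density = density,
    flags = flags
  )
}
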