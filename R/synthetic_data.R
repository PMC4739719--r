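# Synthetic cohorts with the statistical structure the analysis assumes:
# non-overlapping gene models with exon structure, NB counts for pooled
# HOM/WT library pairs over multiple tissues, a targeted-gene knockdown,
# planted local dysregulation whose up-regulated genes are 3'-biased and
# whose down-regulated genes are symmetric and proximal, TFBS/ChIP interval
# fixtures with planted disruption, and exon-level profiles for each QC
# verdict. Every draw is fixed by the config seed.

#' Synthetic-cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: 29 DEL and
#' 15 TRAP targets over 4 tissues, an 8-fold knockdown of the target,
#' planted neighbor effects of |log2| = 2 whose probability decays with
#' distance (scale 100 kb), up-effects placed 3' of the target with
#' probability 0.774 and down-effects symmetric, NB counts with dispersion
#' 0.05 over a log-normal baseline.
#'
#' @param seed Integer RNG seed; fixes every draw.
#' @param n_chromosomes,chromosome_length_mb Genome shape.
#' @param genes_per_mb Gene density (includes miRNAs).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene lengths (bp).
#' @param mirna_fraction Fraction of single-exon miRNA gene models.
#' @param n_targets_del,n_targets_trap Cohort sizes per allele class.
#' @param n_tissues Tissues (one HOM/WT library pair per target per tissue).
#' @param baseline_meanlog,baseline_sdlog Log-normal expression baseline.
#' @param depth_sdlog Log-normal spread of library depth factors.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param knockdown_factor Multiplier on the target's HOM expression.
#' @param p_local_up,p_local_down Per-neighbor planting probabilities at
#'   distance zero (before decay and 3' weighting).
#' @param bias_3prime P(3' | planted up-regulation).
#' @param distance_decay Decay scale in bp for planting probability.
#' @param effect_size_log2 |log2| of planted neighbor effects.
#' @param p_disrupt_del,p_disrupt_trap Planted regulatory-disruption
#'   probabilities per allele class.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_chromosomes = 4,
                             chromosome_length_mb = 15,
                             genes_per_mb = 25,
                             gene_length_meanlog = log(12000),
                             gene_length_sdlog = 0.7,
                             mirna_fraction = 0.05,
                             n_targets_del = 29,
                             n_targets_trap = 15,
                             n_tissues = 4,
                             baseline_meanlog = log(300),
                             baseline_sdlog = 1.2,
                             depth_sdlog = 0.15,
                             dispersion = 0.05,
                             knockdown_factor = 1 / 8,
                             p_local_up = 0.15,
                             p_local_down = 0.2,
                             bias_3prime = 0.774,
                             distance_decay = 100000,
                             effect_size_log2 = 2,
                             p_disrupt_del = 0.586,
                             p_disrupt_trap = 0.067) {
  cfg <- as.list(environment())
  probs <- c(cfg$mirna_fraction, cfg$p_local_up, cfg$p_local_down,
             cfg$bias_3prime, cfg$p_disrupt_del, cfg$p_disrupt_trap)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  scales <- c(cfg$chromosome_length_mb, cfg$genes_per_mb, cfg$dispersion,
              cfg$distance_decay, cfg$knockdown_factor)
  if (any(scales <= 0)) stop("scales must be positive")
  # the worst-case planting probability must stay a probability
  if (2 * cfg$bias_3prime * cfg$p_local_up + cfg$p_local_down > 1) {
    stop("p_local_up / p_local_down too large for the 3' weighting")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic annotation and target alleles
#'
#' Genes are placed without overlap along each chromosome (log-normal
#' lengths, exponential gaps), given random strands and exon structures;
#' a `mirna_fraction` of models are single-exon miRNAs. Targets are sampled
#' among protein-coding genes with at least 4 exons and at least 5 neighbors
#' within 500 kb; TRAP alleles get a proximal insertion intron, DEL alleles
#' a full (90%) or 5'-partial (10%) deleted-exon range.
#'
#' @param cfg A `synthetic_config`.
#' @return List with `gene_models` and `alleles` tibbles.
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  L <- cfg$chromosome_length_mb * 1e6
  rows <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    n <- stats::rpois(1, cfg$genes_per_mb * cfg$chromosome_length_mb)
    if (n == 0) next
    is_mirna <- stats::runif(n) < cfg$mirna_fraction
    len <- round(stats::rlnorm(n, cfg$gene_length_meanlog, cfg$gene_length_sdlog))
    len <- pmin(pmax(len, 1000), 300000)
    len[is_mirna] <- round(stats::runif(sum(is_mirna), 80, 200))
    if (sum(len) >= 0.8 * L) {
      stop("gene density too high: genes do not fit on the chromosome")
    }
    gaps <- stats::rexp(n + 1)
    gaps <- floor(gaps / sum(gaps) * (L - sum(len)))
    start <- cumsum(c(1, len[-n])) + cumsum(gaps[-(n + 1)])
    end <- start + len - 1
    strand <- sample(c("+", "-"), n, replace = TRUE)
    exons <- lapply(seq_len(n), function(i) {
      if (is_mirna[i]) {
        return(data.frame(start = start[i], end = end[i]))
      }
      make_exon_structure(start[i], end[i])
    })
    rows[[ci]] <- tibble::tibble(
      gene_id = sprintf("%s_g%04d", chrom, seq_len(n)),
      chromosome = chrom, start = start, end = end, strand = strand,
      biotype = ifelse(is_mirna, "miRNA", "protein_coding"),
      exons = exons
    )
  }
  gm <- validate_gene_models(dplyr::bind_rows(rows))

  n_exons <- vapply(gm$exons, nrow, integer(1))
  n_nb <- count_neighbors(gm, window = 500000)
  eligible <- gm$gene_id[gm$biotype == "protein_coding" & n_exons >= 4 & n_nb >= 5]
  n_targets <- cfg$n_targets_del + cfg$n_targets_trap
  if (length(eligible) < n_targets) {
    stop("gene density too low: only ", length(eligible),
         " candidate targets with >= 5 neighbors within 500 kb (need ",
         n_targets, ")")
  }
  picked <- sample(eligible, n_targets)
  cls <- c(rep("DEL", cfg$n_targets_del), rep("TRAP", cfg$n_targets_trap))
  ne <- stats::setNames(n_exons, gm$gene_id)[picked]
  trap_intron <- ifelse(cls == "TRAP",
                        vapply(ne, function(e) sample(seq_len(min(3, e - 1)), 1),
                               numeric(1)),
                        NA_real_)
  full_del <- stats::runif(n_targets) < 0.9
  del_first <- ifelse(cls == "DEL", 1, NA_real_)
  del_last <- ifelse(cls == "DEL", ifelse(full_del, ne, ceiling(ne / 2)),
                     NA_real_)
  alleles <- tibble::tibble(
    gene_id = picked,
    allele_class = cls,
    trap_insertion_intron = trap_intron,
    deleted_exon_first = del_first,
    deleted_exon_last = del_last,
    neo_promoter = ifelse(cls == "DEL", "hUBC",
                          sample(c("hACTB", "mPgk", "promoterless"), n_targets,
                                 replace = TRUE, prob = c(0.9, 0.05, 0.05)))
  )
  list(gene_models = gm, alleles = validate_alleles(alleles, gm))
}

make_exon_structure <- function(start, end, mean_exons = 7) {
  len <- end - start + 1
  e_max <- max(2, floor((len - 100) / 350))
  e <- max(2, min(2 + stats::rpois(1, mean_exons - 2), e_max))
  el <- round(stats::runif(e, 80, 250))
  intron_total <- len - sum(el)
  if (intron_total < (e - 1)) {
    el <- floor(el * (len - (e - 1)) / sum(el))
    intron_total <- len - sum(el)
  }
  w <- stats::rexp(e - 1)
  il <- 1 + floor((intron_total - (e - 1)) * w / sum(w))
  # absorb rounding into the final exon so the last exon ends at the gene end
  starts <- start + cumsum(c(0, el[-e] + il))
  ends <- starts + el - 1
  ends[e] <- end
  data.frame(start = starts, end = ends)
}

count_neighbors <- function(gm, window = 500000) {
  cen <- gene_centrum(gm)
  out <- integer(nrow(gm))
  for (chr in unique(gm$chromosome)) {
    sel <- which(gm$chromosome == chr)
    pos <- sort(cen[sel])
    n_in <- findInterval(pos + window, pos) -
      findInterval(pos - window, pos, left.open = TRUE) - 1L
    out[sel][order(cen[sel])] <- n_in
  }
  out
}

#' Generate NB counts with a target knockdown and planted local effects
#'
#' One WT control library per tissue (shared across lines, as with a common
#' wild-type reference) and one HOM library per line x tissue. WT counts are
#' NB(mu_g * depth, alpha); HOM counts multiply the target's mean by the
#' knockdown factor and planted neighbors' means by 2^(+/- effect). A
#' neighbor at signed strand-adjusted distance d is planted up with
#' probability `p_local_up * exp(-|d|/decay) * 2b` (b = `bias_3prime` when d
#' > 0, `1 - bias_3prime` when d < 0) and down with probability
#' `p_local_down * exp(-|d|/decay)`; a planted pair carries its effect in
#' every tissue.
#'
#' @param cfg A `synthetic_config`.
#' @param annotation Result of [generate_annotation()].
#' @return List: `counts` (matrix), `meta`, `pairs`, `truth` (one row per
#'   planted (line, gene, tissue) with direction and distance).
#' @export
generate_counts <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gm <- annotation$gene_models
  alleles <- annotation$alleles
  set.seed(cfg$seed + 1L)
  n_genes <- nrow(gm)
  mu <- stats::rlnorm(n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  names(mu) <- gm$gene_id
  tissues <- paste0("tissue", seq_len(cfg$n_tissues))
  size <- 1 / cfg$dispersion

  # planted truth per (line, neighbor) pair, shared across tissues
  truth_pairs <- list()
  mult <- list()  # per line: named multiplier vector over genes
  for (i in seq_len(nrow(alleles))) {
    line <- alleles$gene_id[i]
    nb <- extract_neighborhood(line, gm, window = 500000)
    m <- rep(1, n_genes)
    names(m) <- gm$gene_id
    m[line] <- cfg$knockdown_factor
    if (nrow(nb) > 0) {
      decay <- exp(-abs(nb$centrum_distance) / cfg$distance_decay)
      side_w <- ifelse(nb$centrum_distance > 0, 2 * cfg$bias_3prime,
                       ifelse(nb$centrum_distance < 0,
                              2 * (1 - cfg$bias_3prime), 1))
      p_up <- cfg$p_local_up * decay * side_w
      p_down <- cfg$p_local_down * decay
      u <- stats::runif(nrow(nb))
      dir <- ifelse(u < p_up, "up", ifelse(u < p_up + p_down, "down", "none"))
      planted <- dir != "none"
      if (any(planted)) {
        m[nb$gene_id[planted]] <- ifelse(dir[planted] == "up",
                                         2^cfg$effect_size_log2,
                                         2^(-cfg$effect_size_log2))
        truth_pairs[[line]] <- tibble::tibble(
          line = line,
          gene_id = nb$gene_id[planted],
          direction = dir[planted],
          centrum_distance = nb$centrum_distance[planted]
        )
      }
    }
    mult[[line]] <- m
  }
  truth <- dplyr::bind_rows(truth_pairs)
  if (nrow(truth) > 0) {
    truth <- tidyr::crossing(truth, tissue = tissues)
  } else {
    truth <- tibble::tibble(line = character(0), gene_id = character(0),
                            direction = character(0),
                            centrum_distance = numeric(0), tissue = character(0))
  }

  wt_libs <- paste0("WT_", tissues)
  hom_libs <- as.vector(outer(alleles$gene_id, tissues,
                              function(l, t) paste0(l, "_", t, "_HOM")))
  libs <- c(wt_libs, hom_libs)
  depth <- stats::rlnorm(length(libs), 0, cfg$depth_sdlog)
  names(depth) <- libs
  counts <- matrix(0L, nrow = n_genes, ncol = length(libs),
                   dimnames = list(gm$gene_id, libs))
  for (t in seq_along(tissues)) {
    lib <- wt_libs[t]
    counts[, lib] <- stats::rnbinom(n_genes, size = size,
                                    mu = mu * depth[[lib]])
  }
  for (i in seq_len(nrow(alleles))) {
    line <- alleles$gene_id[i]
    m <- mult[[line]]
    for (t in seq_along(tissues)) {
      lib <- paste0(line, "_", tissues[t], "_HOM")
      counts[, lib] <- stats::rnbinom(n_genes, size = size,
                                      mu = mu * m * depth[[lib]])
    }
  }
  meta <- dplyr::bind_rows(
    tibble::tibble(library_id = wt_libs, line = "WT", tissue = tissues,
                   genotype = "WT"),
    tibble::tibble(library_id = hom_libs,
                   line = rep(alleles$gene_id, times = length(tissues)),
                   tissue = rep(tissues, each = nrow(alleles)),
                   genotype = "HOM")
  )
  pairs <- make_pairs(meta)
  list(counts = counts, meta = meta, pairs = pairs, truth = truth)
}

#' Generate TFBS and ChIP-peak fixtures with planted disruption
#'
#' For each allele the disruption status is drawn from the class-specific
#' probability; disrupted targets receive 2-4 qualifying TFBS in the
#' affected region (high-confidence for TRAP) plus 1-2 overlapping ChIP
#' peaks for DEL, non-disrupted targets at most one qualifying TFBS.
#' Background sites are scattered outside the affected regions.
#'
#' @param cfg A `synthetic_config`.
#' @param annotation Result of [generate_annotation()].
#' @return List: `tfbs`, `chip` tibbles and `truth` (per-target planted
#'   disruption status).
#' @export
generate_reg_annotation <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gm <- annotation$gene_models
  alleles <- annotation$alleles
  set.seed(cfg$seed + 2L)
  tfbs <- list()
  chip <- list()
  truth <- list()
  place_sites <- function(region, n, width = 12) {
    lo <- region[1]
    hi <- max(region[1] + width, region[2] - width)
    s <- sort(round(stats::runif(n, lo, hi - width)))
    tibble::tibble(start = s, end = s + width - 1)
  }
  for (i in seq_len(nrow(alleles))) {
    allele <- alleles[i, ]
    model <- gm[gm$gene_id == allele$gene_id, ]
    is_del <- allele$allele_class == "DEL"
    region <- if (is_del) deleted_span(allele, model) else
      post_trap_region(allele, model)
    p <- if (is_del) cfg$p_disrupt_del else cfg$p_disrupt_trap
    disrupted <- stats::runif(1) < p
    n_sites <- if (disrupted) sample(2:4, 1) else sample(0:1, 1)
    if (n_sites > 0) {
      sites <- place_sites(region, n_sites)
      tfbs[[length(tfbs) + 1]] <- tibble::tibble(
        chromosome = model$chromosome, start = sites$start, end = sites$end,
        tfbs_id = sprintf("%s_tfbs%d", allele$gene_id, seq_len(n_sites)),
        confidence = if (is_del) sample(c("high", "low"), n_sites, replace = TRUE)
                     else "high"
      )
    }
    if (is_del && disrupted) {
      n_pk <- sample(1:2, 1)
      pk <- place_sites(region, n_pk, width = 300)
      chip[[length(chip) + 1]] <- tibble::tibble(
        chromosome = model$chromosome, start = pk$start, end = pk$end,
        peak_id = sprintf("%s_peak%d", allele$gene_id, seq_len(n_pk)),
        factor = sample(c("Pol2", "CTCF", "p300"), n_pk, replace = TRUE),
        tissue = "liver"
      )
    }
    truth[[i]] <- tibble::tibble(gene_id = allele$gene_id,
                                 allele_class = allele$allele_class,
                                 disrupted = disrupted)
  }
  # background peaks well away from any gene (beyond chromosome ends is not
  # allowed, so use the first intergenic megabase of a spare coordinate range)
  bg <- tibble::tibble(
    chromosome = "chr_bg", start = seq(1000, 10000, by = 1000),
    end = seq(1000, 10000, by = 1000) + 299,
    peak_id = sprintf("bg_peak%d", 1:10),
    factor = "Pol2", tissue = "liver"
  )
  empty_tfbs <- tibble::tibble(chromosome = character(0), start = numeric(0),
                               end = numeric(0), tfbs_id = character(0),
                               confidence = character(0))
  list(
    tfbs = if (length(tfbs) == 0) empty_tfbs else dplyr::bind_rows(tfbs),
    chip = dplyr::bind_rows(c(chip, list(bg))),
    truth = dplyr::bind_rows(truth)
  )
}

#' Generate HOM/WT exon-profile pairs realizing a QC verdict scenario
#'
#' Builds a dedicated synthetic gene model and allele for the scenario and
#' draws per-exon counts (Poisson around the scenario's per-exon means when
#' `noise = TRUE`, the means themselves otherwise).
#'
#' @param cfg A `synthetic_config` (only the seed is used).
#' @param scenario One of the eight QC verdicts.
#' @param n Number of replicate profile pairs.
#' @param wt_exon_mean WT per-exon mean normalized reads (default 600).
#' @param noise Draw Poisson counts around the scenario means?
#' @return List of length `n`; each element has `model`, `allele`, `hom`,
#'   `wt`, `scenario`.
#' @export
generate_exon_profiles <- function(cfg, scenario, n = 1, wt_exon_mean = 600,
                                   noise = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!scenario %in% qc_verdicts) {
    stop("unknown scenario '", scenario, "'; must be one of: ",
         paste(qc_verdicts, collapse = ", "))
  }
  set.seed(cfg$seed + 3L + match(scenario, qc_verdicts) * 1000L)
  spec <- qc_scenario_spec(scenario, wt_exon_mean)
  n_ex <- length(spec$wt_lambda)
  model <- synthetic_qc_gene(scenario, n_ex)
  allele <- tibble::tibble(
    gene_id = model$gene_id,
    allele_class = spec$allele_class,
    trap_insertion_intron = spec$trap_intron,
    deleted_exon_first = spec$del_first,
    deleted_exon_last = spec$del_last,
    neo_promoter = if (spec$allele_class == "DEL") "hUBC" else "hACTB"
  )
  draw <- function(lambda) if (noise) stats::rpois(length(lambda), lambda) else lambda
  lapply(seq_len(n), function(r) {
    list(
      model = model,
      allele = allele,
      hom = exon_profile(model$gene_id, paste0("HOM_", r),
                         draw(spec$hom_lambda),
                         if (noise) stats::rpois(1, spec$hom_intronic)
                         else spec$hom_intronic),
      wt = exon_profile(model$gene_id, paste0("WT_", r),
                        draw(spec$wt_lambda),
                        if (noise) stats::rpois(1, spec$wt_intronic)
                        else spec$wt_intronic),
      scenario = scenario
    )
  })
}

qc_scenario_spec <- function(scenario, base) {
  switch(scenario,
    trap_complete = list(
      allele_class = "TRAP", trap_intron = 2, del_first = NA, del_last = NA,
      wt_lambda = rep(base, 20),
      hom_lambda = c(rep(base / 3, 2), rep(0, 18)),
      wt_intronic = 0, hom_intronic = 0
    ),
    splice_around = list(
      # trap 5' of exon 13; exons 13-16 skipped, distal exons resume at 40%
      allele_class = "TRAP", trap_intron = 12, del_first = NA, del_last = NA,
      wt_lambda = rep(base, 20),
      hom_lambda = c(rep(base, 12), rep(0, 4), rep(0.4 * base, 4)),
      wt_intronic = 0, hom_intronic = 0
    ),
    uniform_hypomorph = list(
      allele_class = "TRAP", trap_intron = 1, del_first = NA, del_last = NA,
      wt_lambda = rep(base, 10),
      hom_lambda = rep(0.3 * base, 10),
      wt_intronic = 0, hom_intronic = 0
    ),
    confirmed_null = list(
      allele_class = "DEL", trap_intron = NA, del_first = 1, del_last = 13,
      wt_lambda = rep(base, 13),
      hom_lambda = rep(0, 13),
      wt_intronic = 0, hom_intronic = 0
    ),
    failed_targeting = list(
      allele_class = "DEL", trap_intron = NA, del_first = 1, del_last = 13,
      wt_lambda = rep(base, 13),
      hom_lambda = rep(base, 13),
      wt_intronic = 0, hom_intronic = 0
    ),
    intronic_only = list(
      allele_class = "DEL", trap_intron = NA, del_first = 1, del_last = 13,
      wt_lambda = rep(base, 13),
      hom_lambda = rep(5, 13),
      wt_intronic = 50, hom_intronic = 2000
    ),
    distal_retention = list(
      # proximal exons 1-8 deleted, retained exons 9-13 above WT level
      allele_class = "DEL", trap_intron = NA, del_first = 1, del_last = 8,
      wt_lambda = rep(base, 13),
      hom_lambda = c(rep(0, 8), rep(1.5 * base, 5)),
      wt_intronic = 0, hom_intronic = 0
    ),
    indeterminate = list(
      allele_class = "DEL", trap_intron = NA, del_first = 1, del_last = 13,
      wt_lambda = rep(2, 13),
      hom_lambda = rep(1, 13),
      wt_intronic = 0, hom_intronic = 0
    )
  )
}

synthetic_qc_gene <- function(scenario, n_exons) {
  exon_len <- 150
  intron_len <- 500
  starts <- 1000 + (seq_len(n_exons) - 1) * (exon_len + intron_len)
  gene_models(
    gene_id = paste0("synthetic_", scenario),
    chromosome = "chrQ",
    start = starts[1],
    end = starts[n_exons] + exon_len - 1,
    strand = "+",
    exons = list(data.frame(start = starts, end = starts + exon_len - 1)),
    biotype = "protein_coding"
  )
}
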