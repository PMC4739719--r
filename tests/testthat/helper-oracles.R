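# Independent brute-force re-implementations used as oracles. These stay
# deliberately naive (plain loops, case enumeration) and share no code with
# the package internals they check.

oracle_nb_conditional_p <- function(k_hom, k_wt, s_hom, s_wt, alpha) {
  n <- k_hom + k_wt
  if (n == 0) return(1)
  mu <- n / (s_hom + s_wt)
  size <- 1 / alpha
  w <- numeric(n + 1)
  for (a in 0:n) {
    w[a + 1] <- dnbinom(a, size = size, mu = s_hom * mu) *
      dnbinom(n - a, size = size, mu = s_wt * mu)
  }
  w <- w / sum(w)
  lower <- 0
  upper <- 0
  for (a in 0:n) {
    if (a <= k_hom) lower <- lower + w[a + 1]
    if (a >= k_hom) upper <- upper + w[a + 1]
  }
  min(1, 2 * min(lower, upper))
}

oracle_signed_distance <- function(t_start, t_end, t_strand, n_start, n_end) {
  tc <- floor((t_start + t_end) / 2)
  nc <- floor((n_start + n_end) / 2)
  if (t_strand == "+") {
    if (nc >= tc) nc - tc else -(tc - nc)
  } else {
    if (nc >= tc) -(nc - tc) else tc - nc
  }
}

oracle_neighborhood <- function(target_id, gm, window) {
  ti <- which(gm$gene_id == target_id)
  target <- gm[ti, ]
  hits <- character(0)
  for (i in seq_len(nrow(gm))) {
    if (gm$gene_id[i] == target_id) next
    if (gm$chromosome[i] != target$chromosome) next
    d <- oracle_signed_distance(target$start, target$end, target$strand,
                                gm$start[i], gm$end[i])
    if (abs(d) <= window) hits <- c(hits, gm$gene_id[i])
  }
  sort(hits)
}

oracle_genome_wide_null <- function(calls, gm, window) {
  cen <- floor((gm$start + gm$end) / 2)
  names(cen) <- gm$gene_id
  chrom <- setNames(gm$chromosome, gm$gene_id)
  n_focal <- 0; n_inst <- 0; n_up <- 0; n_down <- 0
  for (lib in unique(calls$hom_library)) {
    cl <- calls[calls$hom_library == lib, ]
    dirs <- setNames(cl$direction, cl$gene_id)
    for (fg in cl$gene_id[cl$direction == "down"]) {
      n_focal <- n_focal + 1
      for (ng in cl$gene_id) {
        if (ng == fg) next
        if (chrom[[ng]] != chrom[[fg]]) next
        if (abs(cen[[ng]] - cen[[fg]]) > window) next
        n_inst <- n_inst + 1
        if (dirs[[ng]] == "up") n_up <- n_up + 1
        if (dirs[[ng]] == "down") n_down <- n_down + 1
      }
    }
  }
  list(f_up = n_up / n_inst, f_down = n_down / n_inst,
       n_focal = n_focal, n_neighbor_instances = n_inst)
}

oracle_flag <- function(hom, wt) {
  (hom >= 100 || wt >= 100) && hom >= 0.2 * wt
}

oracle_score_trap <- function(region, chromosome, tfbs) {
  n <- 0
  for (i in seq_len(nrow(tfbs))) {
    if (tfbs$chromosome[i] == chromosome &&
        tfbs$confidence[i] == "high" &&
        tfbs$start[i] >= region[1] && tfbs$end[i] <= region[2]) {
      n <- n + 1
    }
  }
  n >= 2
}

oracle_score_del <- function(span, chromosome, tfbs, chip) {
  n_tfbs <- 0
  for (i in seq_len(nrow(tfbs))) {
    if (tfbs$chromosome[i] == chromosome &&
        tfbs$start[i] >= span[1] && tfbs$end[i] <= span[2]) {
      n_tfbs <- n_tfbs + 1
    }
  }
  n_chip <- 0
  for (i in seq_len(nrow(chip))) {
    if (chip$chromosome[i] == chromosome &&
        chip$start[i] <= span[2] && chip$end[i] >= span[1]) {
      n_chip <- n_chip + 1
    }
  }
  n_tfbs >= 2 && n_chip >= 1
}

oracle_bin_histogram <- function(d, bin_width, window) {
  edges <- seq(-window, window, by = bin_width)
  counts <- integer(length(edges) - 1)
  for (x in d) {
    for (b in seq_along(counts)) {
      hi_closed <- b == length(counts)
      if (x >= edges[b] && (x < edges[b + 1] || (hi_closed && x <= edges[b + 1]))) {
        counts[b] <- counts[b] + 1
        break
      }
    }
  }
  counts
}
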