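#' @import tibble
#' @importFrom rlang .data
NULL

# Coordinate convention: 1-based, inclusive on both ends, everywhere inside the
# package. BED input (0-based half-open) is converted on read; GTF/GFF3 are
# already 1-based inclusive and pass through unchanged.

#' Construct a gene-model table
#'
#' A gene-model table is a tibble with one row per gene and columns
#' `gene_id`, `chromosome`, `start`, `end`, `strand` (`"+"`/`"-"`),
#' `biotype` (`protein_coding`, `miRNA`, or `other`) and `exons`, a
#' list-column of two-column data frames (`start`, `end`) sorted in
#' ascending genomic order. Coordinates are 1-based inclusive.
#'
#' @param gene_id,chromosome,start,end,strand,biotype Per-gene vectors.
#' @param exons List of data frames with `start`/`end` columns, one per gene.
#' @return A validated gene-model tibble.
#' @export
gene_models <- function(gene_id, chromosome, start, end, strand,
                        exons, biotype = "protein_coding") {
  gm <- tibble::tibble(
    gene_id = as.character(gene_id),
    chromosome = as.character(chromosome),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    biotype = rep_len(as.character(biotype), length(gene_id)),
    exons = lapply(exons, function(e) {
      e <- as.data.frame(e)[, c("start", "end")]
      e[order(e$start), , drop = FALSE]
    })
  )
  validate_gene_models(gm)
}

#' Validate a gene-model table
#'
#' Checks the invariants the rest of the package relies on: spans with
#' `start <= end`, strands in `{+,-}`, at least one exon per gene, exons
#' sorted, non-overlapping and contained in the gene span, unique gene ids.
#'
#' @param gm A gene-model tibble.
#' @return `gm`, invisibly usable, after validation.
#' @export
validate_gene_models <- function(gm) {
  stopifnot(is.data.frame(gm))
  needed <- c("gene_id", "chromosome", "start", "end", "strand", "biotype", "exons")
  missing <- setdiff(needed, names(gm))
  if (length(missing) > 0) {
    stop("gene-model table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(gm$gene_id)) {
    stop("duplicate gene_id in gene-model table: ",
         paste(unique(gm$gene_id[duplicated(gm$gene_id)]), collapse = ", "))
  }
  if (any(gm$start > gm$end)) stop("gene with start > end")
  if (!all(gm$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(gm))) {
    e <- gm$exons[[i]]
    if (is.null(e) || nrow(e) == 0) {
      stop("gene with zero exons: ", gm$gene_id[i])
    }
    if (any(e$start > e$end)) stop("exon with start > end in gene ", gm$gene_id[i])
    if (is.unsorted(e$start)) stop("exons not sorted in gene ", gm$gene_id[i])
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)])) {
      stop("overlapping exons in gene ", gm$gene_id[i])
    }
    if (e$start[1] < gm$start[i] || e$end[nrow(e)] > gm$end[i]) {
      stop("exon outside gene span in gene ", gm$gene_id[i])
    }
  }
  gm
}

#' Centrum (midpoint) of gene spans
#'
#' The centrum is the floor of the arithmetic midpoint of the genomic span,
#' `floor((start + end) / 2)`. It is the reference point for all flanking
#' distances.
#'
#' @param gm A gene-model tibble (or any data frame with `start`/`end`).
#' @return Numeric vector of centrum positions, named by `gene_id` when
#'   present.
#' @export
gene_centrum <- function(gm) {
  cen <- floor((gm$start + gm$end) / 2)
  if (!is.null(gm$gene_id)) names(cen) <- gm$gene_id
  cen
}

#' Read gene models from GTF, GFF3 or a TSV dialect
#'
#' For GTF/GFF3 the file is parsed with `rtracklayer`; gene spans are taken
#' from `gene` features when present, otherwise from the union of each
#' gene's exons, and exon lists come from `exon` features grouped by gene
#' id. The TSV dialect has columns `gene_id`, `chromosome`, `start`, `end`,
#' `strand`, `biotype`, `exon_starts`, `exon_ends`, with exon coordinates
#' comma-separated.
#'
#' @param path Path to the annotation file.
#' @param format One of `"gtf"`, `"gff3"`, `"tsv"`.
#' @return A gene-model tibble (see [gene_models()]).
#' @export
read_gene_models <- function(path, format = c("gtf", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    return(read_gene_models_tsv(path))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = toupper(format)),
    error = function(e) stop("failed to parse ", format, " file '", path, "': ",
                             conditionMessage(e))
  )
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) stop("annotation has no gene_id attribute")
  types <- as.character(md$type)
  is_exon <- types == "exon"
  if (!any(is_exon)) stop("annotation contains no exon features")
  exon_gr <- gr[is_exon]
  exon_gid <- as.character(S4Vectors::mcols(exon_gr)$gene_id)
  exon_df <- data.frame(
    gene_id = exon_gid,
    start = GenomicRanges::start(exon_gr),
    end = GenomicRanges::end(exon_gr)
  )
  exon_split <- split(exon_df[c("start", "end")], exon_df$gene_id)
  exon_split <- lapply(exon_split, function(e) e[order(e$start), , drop = FALSE])

  is_gene <- types == "gene"
  if (any(is_gene)) {
    gene_gr <- gr[is_gene]
    gid <- as.character(S4Vectors::mcols(gene_gr)$gene_id)
    bt <- S4Vectors::mcols(gene_gr)$gene_biotype
    if (is.null(bt)) bt <- S4Vectors::mcols(gene_gr)$biotype
    if (is.null(bt)) bt <- "protein_coding"
    gm <- tibble::tibble(
      gene_id = gid,
      chromosome = as.character(GenomicRanges::seqnames(gene_gr)),
      start = GenomicRanges::start(gene_gr),
      end = GenomicRanges::end(gene_gr),
      strand = as.character(GenomicRanges::strand(gene_gr)),
      biotype = as.character(bt)
    )
  } else {
    # derive gene spans from exon extent
    gid <- names(exon_split)
    chrom <- vapply(gid, function(g) {
      as.character(GenomicRanges::seqnames(exon_gr[exon_gid == g][1]))
    }, character(1))
    str <- vapply(gid, function(g) {
      as.character(GenomicRanges::strand(exon_gr[exon_gid == g][1]))
    }, character(1))
    gm <- tibble::tibble(
      gene_id = gid,
      chromosome = chrom,
      start = vapply(exon_split, function(e) min(e$start), numeric(1)),
      end = vapply(exon_split, function(e) max(e$end), numeric(1)),
      strand = str,
      biotype = "protein_coding"
    )
  }
  missing_exons <- setdiff(gm$gene_id, names(exon_split))
  if (length(missing_exons) > 0) {
    stop("gene with zero exons: ", paste(missing_exons, collapse = ", "))
  }
  gm$exons <- exon_split[gm$gene_id]
  gm$biotype <- ifelse(gm$biotype %in% c("protein_coding", "miRNA"),
                       gm$biotype, "other")
  validate_gene_models(gm)
}

read_gene_models_tsv <- function(path) {
  # exon lists are comma-separated; stop readr from reading them as grouped
  # numbers
  df <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(exon_starts = readr::col_character(),
                            exon_ends = readr::col_character(),
                            .default = readr::col_guess())
  )
  needed <- c("gene_id", "chromosome", "start", "end", "strand",
              "biotype", "exon_starts", "exon_ends")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("gene-model TSV is missing columns: ", paste(missing, collapse = ", "))
  }
  exons <- lapply(seq_len(nrow(df)), function(i) {
    es <- as.numeric(strsplit(as.character(df$exon_starts[i]), ",")[[1]])
    ee <- as.numeric(strsplit(as.character(df$exon_ends[i]), ",")[[1]])
    if (length(es) == 0 || length(es) != length(ee) || anyNA(es) || anyNA(ee)) {
      stop("malformed exon list at line ", i + 1, " of ", path)
    }
    data.frame(start = es, end = ee)[order(es), , drop = FALSE]
  })
  gene_models(df$gene_id, df$chromosome, df$start, df$end, df$strand,
              exons, biotype = df$biotype)
}

#' Write gene models to the TSV dialect
#'
#' @param gm A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  gm <- validate_gene_models(gm)
  out <- tibble::tibble(
    gene_id = gm$gene_id,
    chromosome = gm$chromosome,
    start = gm$start,
    end = gm$end,
    strand = gm$strand,
    biotype = gm$biotype,
    exon_starts = vapply(gm$exons, function(e) paste(e$start, collapse = ","),
                         character(1)),
    exon_ends = vapply(gm$exons, function(e) paste(e$end, collapse = ","),
                       character(1))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a count matrix and library metadata
#'
#' The count file is a TSV whose first column is `gene_id` and whose
#' remaining columns are libraries. Metadata (one row per library with
#' `library_id`, `line`, `tissue`, `genotype`) comes from a sidecar TSV.
#'
#' @param path Count-matrix TSV.
#' @param meta_path Library-metadata TSV (optional).
#' @return A list with `counts` (numeric matrix, genes x libraries) and
#'   `meta` (tibble or NULL).
#' @export
read_counts <- function(path, meta_path = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "gene_id") stop("first column of count table must be gene_id")
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in count table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric values in count table")
  if (anyNA(m)) stop("missing cells in count table")
  if (any(m < 0)) stop("negative count in count table")
  rownames(m) <- df$gene_id
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- read_library_meta(meta_path)
    absent <- setdiff(colnames(m), meta$library_id)
    if (length(absent) > 0) {
      stop("libraries missing from metadata: ", paste(absent, collapse = ", "))
    }
  }
  list(counts = m, meta = meta)
}

#' Read library metadata
#'
#' @param path TSV with columns `library_id`, `line`, `tissue`, `genotype`.
#' @return A tibble; genotype restricted to HOM/WT and
#'   `(line, tissue, genotype)` required to be unique.
#' @export
read_library_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("library_id", "line", "tissue", "genotype")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    stop("library metadata is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(meta$genotype %in% c("HOM", "WT"))) {
    stop("genotype must be HOM or WT")
  }
  key <- paste(meta$line, meta$tissue, meta$genotype)
  if (anyDuplicated(key)) stop("(line, tissue, genotype) not unique in metadata")
  meta
}

#' Write a count matrix (and optional metadata sidecar)
#'
#' @param counts Numeric matrix with gene rownames and library colnames.
#' @param path Output TSV path.
#' @param meta,meta_path Optional metadata tibble and its output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, meta = NULL, meta_path = NULL) {
  df <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(meta) && !is.null(meta_path)) {
    readr::write_tsv(meta, meta_path, progress = FALSE)
  }
  invisible(path)
}

s1_columns <- c("line", "synonym", "tissue", "chromosome", "gene", "start",
                "end", "centrum_distance", "strand", "hom", "wt", "p_value",
                "hom_wt_ratio", "log2")

#' Read a supplementary-table export of per-neighborhood calls
#'
#' The dialect is a delimited (TSV or CSV) export of a per-library survey of
#' the target gene and all genes within +/-500 kb of its centrum: one row
#' per (line, tissue, gene) with normalized HOM and WT read counts, the
#' per-gene unadjusted p-value, the HOM/WT ratio and its log2. The
#' `centrum_distance` column carries the signed, strand-adjusted distance
#' (negative = 5' of the target). Blank p-values (genes the test did not
#' score) are kept as `NA`.
#'
#' @param path Path to the TSV/CSV export.
#' @return A typed tibble with the documented columns.
#' @export
read_s1_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  names(df) <- normalize_s1_names(names(df))
  missing <- setdiff(s1_columns, names(df))
  if (length(missing) > 0) {
    stop("supplementary-table export is missing columns: ",
         paste(missing, collapse = ", "))
  }
  df <- df[s1_columns]
  for (col in c("start", "end", "centrum_distance", "hom", "wt",
                "p_value", "hom_wt_ratio", "log2")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad_p <- !is.na(df$p_value) & (df$p_value < 0 | df$p_value > 1)
  if (any(bad_p)) stop("p_value outside [0,1] at row ", which(bad_p)[1])
  bad_d <- !is.na(df$centrum_distance) & abs(df$centrum_distance) > 500000
  if (any(bad_d)) stop("centrum_distance outside +/-500 kb at row ", which(bad_d)[1])
  df
}

normalize_s1_names <- function(x) {
  y <- tolower(gsub("[ /.-]+", "_", trimws(x)))
  map <- c(
    "line" = "line", "synonym" = "synonym", "tissue" = "tissue",
    "chromosome" = "chromosome", "gene" = "gene", "start" = "start",
    "end" = "end", "centrum_distance" = "centrum_distance",
    "strand" = "strand", "hom" = "hom", "wt" = "wt",
    "p_value" = "p_value", "hom_wt" = "hom_wt_ratio",
    "hom_wt_ratio" = "hom_wt_ratio", "log2" = "log2"
  )
  ifelse(y %in% names(map), unname(map[y]), y)
}

#' Write rows in the supplementary-table dialect
#'
#' @param df Tibble with the columns [read_s1_table()] documents.
#' @param path Output path (`.csv` for comma-delimited, TSV otherwise).
#' @return `path`, invisibly.
#' @export
write_s1_table <- function(df, path) {
  missing <- setdiff(s1_columns, names(df))
  if (length(missing) > 0) {
    stop("cannot write supplementary-table export; missing columns: ",
         paste(missing, collapse = ", "))
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df[s1_columns], path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a target-allele table
#'
#' TSV with columns `gene_id`, `allele_class` (TRAP/DEL),
#' `trap_insertion_intron` (TRAP only; the cassette sits 5' of the critical
#' exon, so intron k precedes transcription-order exon k+1),
#' `deleted_exon_first`/`deleted_exon_last` (DEL only; inclusive ordinals in
#' transcription order), and `neo_promoter`.
#'
#' @param path Allele TSV.
#' @param gm Optional gene-model tibble for ordinal validation.
#' @return A tibble of alleles.
#' @export
read_alleles <- function(path, gm = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_alleles(df, gm)
}

#' Validate a target-allele table
#'
#' @param alleles Allele tibble.
#' @param gm Optional gene-model tibble for ordinal validation.
#' @return The validated tibble.
#' @export
validate_alleles <- function(alleles, gm = NULL) {
  needed <- c("gene_id", "allele_class", "trap_insertion_intron",
              "deleted_exon_first", "deleted_exon_last", "neo_promoter")
  missing <- setdiff(needed, names(alleles))
  if (length(missing) > 0) {
    stop("allele table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(alleles$allele_class %in% c("TRAP", "DEL"))) {
    stop("allele_class must be TRAP or DEL")
  }
  is_trap <- alleles$allele_class == "TRAP"
  if (any(is_trap & is.na(alleles$trap_insertion_intron))) {
    stop("TRAP allele without trap_insertion_intron")
  }
  if (any(is_trap & (!is.na(alleles$deleted_exon_first) |
                     !is.na(alleles$deleted_exon_last)))) {
    stop("TRAP allele with deleted-exon range set")
  }
  if (any(!is_trap & (is.na(alleles$deleted_exon_first) |
                      is.na(alleles$deleted_exon_last)))) {
    stop("DEL allele without deleted-exon range")
  }
  if (any(!is_trap & !is.na(alleles$trap_insertion_intron))) {
    stop("DEL allele with trap_insertion_intron set")
  }
  ok_del <- !is_trap & !is.na(alleles$deleted_exon_first)
  if (any(alleles$deleted_exon_first[ok_del] > alleles$deleted_exon_last[ok_del])) {
    stop("deleted_exon_first > deleted_exon_last")
  }
  if (!is.null(gm)) {
    n_ex <- vapply(gm$exons, nrow, integer(1))
    names(n_ex) <- gm$gene_id
    absent <- setdiff(alleles$gene_id, gm$gene_id)
    if (length(absent) > 0) {
      stop("allele for gene absent from annotation: ",
           paste(absent, collapse = ", "))
    }
    ne <- n_ex[alleles$gene_id]
    bad_trap <- is_trap & (alleles$trap_insertion_intron < 1 |
                           alleles$trap_insertion_intron >= ne)
    if (any(bad_trap)) stop("trap_insertion_intron outside the gene's introns")
    bad_del <- !is_trap & (alleles$deleted_exon_first < 1 |
                           alleles$deleted_exon_last > ne)
    if (any(bad_del)) stop("deleted-exon range outside the gene's exons")
  }
  alleles
}

#' Write a target-allele table
#' @param alleles Allele tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_alleles <- function(alleles, path) {
  readr::write_tsv(validate_alleles(alleles), path, progress = FALSE)
  invisible(path)
}

#' Read TFBS intervals from an extended BED file
#'
#' Columns: chrom, start, end, name, confidence (`high`/`low`). BED
#' coordinates (0-based half-open) are converted to 1-based inclusive.
#'
#' @param path BED-like TSV without header.
#' @return Tibble with `chromosome`, `start`, `end`, `tfbs_id`, `confidence`.
#' @export
read_tfbs_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chromosome", "start", "end",
                                            "tfbs_id", "confidence"),
                        show_col_types = FALSE, progress = FALSE)
  if (!all(df$confidence %in% c("high", "low"))) {
    stop("TFBS confidence must be 'high' or 'low'")
  }
  df$start <- df$start + 1  # BED is 0-based half-open
  tibble::as_tibble(df)
}

#' Read ChIP-peak intervals from an extended BED file
#'
#' Columns: chrom, start, end, name, factor (`Pol2`/`CTCF`/`p300`), tissue.
#' BED coordinates are converted to 1-based inclusive.
#'
#' @param path BED-like TSV without header.
#' @return Tibble with `chromosome`, `start`, `end`, `peak_id`, `factor`,
#'   `tissue`.
#' @export
read_chip_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chromosome", "start", "end",
                                            "peak_id", "factor", "tissue"),
                        show_col_types = FALSE, progress = FALSE)
  if (!all(df$factor %in% c("Pol2", "CTCF", "p300"))) {
    stop("ChIP factor must be Pol2, CTCF or p300")
  }
  df$start <- df$start + 1
  tibble::as_tibble(df)
}

#' Exon ordinals in transcription order
#'
#' Maps transcription-order exon ordinals (1 = 5'-most exon of the
#' transcript) to row indexes of the genomically sorted exon table. For a
#' plus-strand gene these coincide; for a minus-strand gene ordinal 1 is the
#' genomically last exon.
#'
#' @param gene One row of a gene-model tibble.
#' @return Integer vector `ix` such that `exons[ix[k], ]` is the k-th exon in
#'   transcription order.
#' @export
exon_order_tx <- function(gene) {
  n <- nrow(gene$exons[[1]])
  if (gene$strand == "+") seq_len(n) else rev(seq_len(n))
}
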