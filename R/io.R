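#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Canonical column sets for the tabular containers used throughout.
.seg_cols <- c("sample_id", "chrom", "start", "end", "seg_mean")
.mut_cols <- c(
  "sample_id", "gene_id", "chrom", "position", "ref_allele", "alt_allele",
  "variant_classification", "somatic", "context"
)
.cov_cols <- c("sample_id", "chrom", "start", "end")

#' Normalize chromosome labels
#'
#' Strips any leading `"chr"` prefix, upper-cases the sex chromosomes, and
#' (by default) flags mitochondrial records for removal. Copy-number and
#' mutation sources differ in dialect ("chr17" vs "17", "x" vs "X"); all
#' genomic tables in this package are normalized on entry so cohorts can be
#' joined by chromosome.
#'
#' @param chrom character vector of chromosome labels.
#' @returns Character vector of normalized labels ("1".."22", "X", "Y", "MT").
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x <- toupper(x)
  x[x == "M"] <- "MT"
  x
}

.is_mito <- function(chrom) normalize_chrom(chrom) == "MT"

#' Merge overlapping intervals within each sample and chromosome
#'
#' Intervals are half-open `[start, end)` (BED convention). Overlapping or
#' book-ended intervals belonging to the same sample and chromosome are
#' coalesced; the operation is idempotent. Used to guarantee that covered-base
#' counts never double-count duplicated coverage records.
#'
#' @param intervals tibble with columns `sample_id`, `chrom`, `start`, `end`.
#' @returns Tibble with the same columns, sorted, with disjoint intervals per
#'   sample/chromosome.
#' @export
merge_intervals <- function(intervals) {
  stopifnot(all(.cov_cols %in% names(intervals)))
  if (nrow(intervals) == 0) {
    return(tibble::as_tibble(intervals)[.cov_cols])
  }
  intervals %>%
    dplyr::group_by(.data$sample_id, .data$chrom) %>%
    dplyr::arrange(.data$start, .data$end, .by_group = TRUE) %>%
    dplyr::mutate(
      .grp = cumsum(c(TRUE, .data$start[-1] > cummax(.data$end)[-dplyr::n()]))
    ) %>%
    dplyr::group_by(.data$.grp, .add = TRUE) %>%
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    ) %>%
    dplyr::select(dplyr::all_of(.cov_cols)) %>%
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start)
}

#' Total covered bases per sample
#'
#' @param coverage coverage tibble (0-based half-open intervals).
#' @returns Tibble with columns `sample_id`, `bases` (intervals are merged
#'   first, so duplicated or overlapping records are not double-counted).
#' @export
covered_bases <- function(coverage) {
  merge_intervals(coverage) %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(bases = sum(.data$end - .data$start), .groups = "drop")
}

.check_no_segment_overlap <- function(seg) {
  bad <- seg %>%
    dplyr::group_by(.data$sample_id, .data$chrom) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::filter(.data$start <= dplyr::lag(cummax(.data$end), default = -Inf)) %>%
    dplyr::ungroup()
  if (nrow(bad) > 0) {
    stop(sprintf(
      "overlapping segments for sample '%s' on chromosome %s",
      bad$sample_id[1], bad$chrom[1]
    ), call. = FALSE)
  }
  invisible(seg)
}

#' Validate a segment table
#'
#' Checks the SEG invariants: `start <= end` on every record, finite segment
#' means, and no overlapping segments for the same sample on the same
#' chromosome (segments are 1-based inclusive, as emitted by CBS-style
#' segmentation).
#'
#' @param seg segment tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `seg_mean`).
#' @returns The input, invisibly, if valid; otherwise an error.
#' @export
validate_segments <- function(seg) {
  stopifnot(all(.seg_cols %in% names(seg)))
  bad <- which(seg$start > seg$end)
  if (length(bad) > 0) {
    stop(sprintf("segment start > end at row %d", bad[1]), call. = FALSE)
  }
  if (any(!is.finite(seg$seg_mean))) {
    stop("non-finite segment mean", call. = FALSE)
  }
  .check_no_segment_overlap(seg)
  invisible(seg)
}

#' Read a SEG file of copy-number segments
#'
#' Expects the conventional tab-delimited SEG layout with header columns
#' `ID`, `chrom`, `loc.start`, `loc.end`, `seg.mean`. Positions are 1-based
#' inclusive, so a segment's length is `end - start + 1`. Chromosome labels
#' are normalized (leading "chr" stripped) and mitochondrial records dropped
#' unless `keep_mito = TRUE`.
#'
#' @param path path to a SEG file.
#' @param keep_mito keep mitochondrial segments? Default `FALSE`.
#' @returns Validated segment tibble with columns `sample_id`, `chrom`,
#'   `start`, `end`, `seg_mean`.
#' @export
read_seg <- function(path, keep_mito = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "seg.mean")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(sprintf("SEG file missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(raw$loc.start))
  end <- suppressWarnings(as.numeric(raw$loc.end))
  mean_ <- suppressWarnings(as.numeric(raw$seg.mean))
  bad <- which(is.na(start) | is.na(end) | is.na(mean_))
  if (length(bad) > 0) {
    stop(sprintf("malformed SEG row at line %d", bad[1] + 1L), call. = FALSE)
  }
  bad <- which(start > end)
  if (length(bad) > 0) {
    stop(sprintf("SEG start > end at line %d", bad[1] + 1L), call. = FALSE)
  }
  seg <- tibble::tibble(
    sample_id = raw$ID,
    chrom = normalize_chrom(raw$chrom),
    start = start, end = end, seg_mean = mean_
  )
  if (!keep_mito) seg <- dplyr::filter(seg, !.is_mito(.data$chrom))
  validate_segments(seg)
  seg
}

#' Write a segment table as a SEG file
#'
#' Inverse of [read_seg()]; numeric values are written at full precision so
#' the write/read round trip is exact.
#'
#' @param seg segment tibble.
#' @param path output path.
#' @returns `path`, invisibly.
#' @export
write_seg <- function(seg, path) {
  out <- tibble::tibble(
    ID = seg$sample_id, chrom = seg$chrom,
    `loc.start` = format(seg$start, scientific = FALSE, trim = TRUE),
    `loc.end` = format(seg$end, scientific = FALSE, trim = TRUE),
    `seg.mean` = formatC(seg$seg_mean, digits = 17, format = "g")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a mutation table
#'
#' Enforces that reference and alternate alleles differ and that any context
#' string is 5 bases long with the reference base at its center.
#'
#' @param muts mutation tibble.
#' @returns The input, invisibly, if valid.
#' @export
validate_mutations <- function(muts) {
  stopifnot(all(setdiff(.mut_cols, "context") %in% names(muts)))
  bad <- which(muts$ref_allele == muts$alt_allele)
  if (length(bad) > 0) {
    stop(sprintf("ref allele equals alt allele at row %d", bad[1]), call. = FALSE)
  }
  if ("context" %in% names(muts)) {
    ctx <- muts$context
    has <- !is.na(ctx)
    if (any(has & nchar(ctx) != 5L)) {
      stop("context strings must have length 5", call. = FALSE)
    }
    mid <- substr(ctx[has], 3, 3)
    if (any(mid != muts$ref_allele[has])) {
      stop("context middle base must equal the reference allele", call. = FALSE)
    }
  }
  invisible(muts)
}

#' Read a MAF file of somatic mutation calls
#'
#' Minimal TCGA-style MAF reader. The mandatory columns are `Hugo_Symbol`,
#' `Chromosome`, `Start_position`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' `Variant_Classification`, `Mutation_Status` and `Tumor_Sample_Barcode`; an
#' optional `context` column carries the 5-base sequence centered on the
#' variant site (used for flanking-context profiles). The somatic flag is
#' derived case-insensitively from `Mutation_Status`.
#'
#' @param path path to a tab-delimited MAF file.
#' @returns Mutation tibble with columns `sample_id`, `gene_id`, `chrom`,
#'   `position`, `ref_allele`, `alt_allele`, `variant_classification`,
#'   `somatic`, `context`.
#' @export
read_maf <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), comment = "#", progress = FALSE)
  need <- c("Hugo_Symbol", "Chromosome", "Start_position", "Reference_Allele",
            "Tumor_Seq_Allele2", "Variant_Classification", "Mutation_Status",
            "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(sprintf("MAF missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  muts <- tibble::tibble(
    sample_id = raw$Tumor_Sample_Barcode,
    gene_id = raw$Hugo_Symbol,
    chrom = normalize_chrom(raw$Chromosome),
    position = as.numeric(raw$Start_position),
    ref_allele = toupper(raw$Reference_Allele),
    alt_allele = toupper(raw$Tumor_Seq_Allele2),
    variant_classification = raw$Variant_Classification,
    somatic = tolower(raw$Mutation_Status) == "somatic",
    context = if ("context" %in% names(raw)) toupper(raw$context) else NA_character_
  )
  validate_mutations(muts)
  muts
}

#' Write a mutation table as a MAF file
#'
#' @param muts mutation tibble.
#' @param path output path.
#' @returns `path`, invisibly.
#' @export
write_maf <- function(muts, path) {
  out <- tibble::tibble(
    Hugo_Symbol = muts$gene_id,
    Chromosome = muts$chrom,
    Start_position = format(muts$position, scientific = FALSE, trim = TRUE),
    Reference_Allele = muts$ref_allele,
    Tumor_Seq_Allele2 = muts$alt_allele,
    Variant_Classification = muts$variant_classification,
    Mutation_Status = ifelse(muts$somatic, "Somatic", "Germline"),
    Tumor_Sample_Barcode = muts$sample_id,
    context = if ("context" %in% names(muts)) muts$context else NA_character_
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a features-by-samples numeric matrix
#'
#' Tab-delimited layout: first column holds feature ids, first row holds
#' sample ids. Empty cells become `NA` (missing is first-class; downstream
#' correlations use pairwise-complete observations, never silent zeros).
#'
#' @param path path to a tab-delimited matrix file.
#' @returns Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  ids <- raw[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate feature id: %s", dup[1]), call. = FALSE)
  }
  sample_ids <- names(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id in header", call. = FALSE)
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- ids
  m
}

#' Write a features-by-samples matrix
#'
#' Inverse of [read_matrix()]; `NA` entries are written as empty cells and
#' numbers at full (round-trip safe) precision.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_col header name for the feature-id column.
#' @returns `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read per-sample coverage intervals from BED
#'
#' Accepts either a 4-column table (`sample`, `chrom`, `start`, `end`) or a
#' plain BED3 file combined with the `sample` argument. Coordinates are
#' 0-based half-open, so covered bases per interval equal `end - start`.
#' Intervals are normalized on read: sorted and merged per sample and
#' chromosome.
#'
#' @param path path to a headerless BED file.
#' @param sample sample id to assign when the file is BED3.
#' @returns Coverage tibble (`sample_id`, `chrom`, `start`, `end`) with
#'   disjoint sorted intervals.
#' @export
read_bed_coverage <- function(path, sample = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric()))
  }
  if (ncol(raw) >= 4 && is.null(sample)) {
    cov <- tibble::tibble(
      sample_id = raw[[1]], chrom = normalize_chrom(raw[[2]]),
      start = as.numeric(raw[[3]]), end = as.numeric(raw[[4]])
    )
  } else if (ncol(raw) >= 3) {
    if (is.null(sample)) {
      stop("BED3 input requires a `sample` id", call. = FALSE)
    }
    cov <- tibble::tibble(
      sample_id = sample, chrom = normalize_chrom(raw[[1]]),
      start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]])
    )
  } else {
    stop("coverage BED needs at least 3 columns", call. = FALSE)
  }
  bad <- which(!(cov$start < cov$end))
  if (length(bad) > 0) {
    stop(sprintf("coverage interval with start >= end at line %d", bad[1]),
         call. = FALSE)
  }
  merge_intervals(cov)
}

#' Write coverage intervals as a 4-column BED-like table
#'
#' @param coverage coverage tibble.
#' @param path output path.
#' @returns `path`, invisibly.
#' @export
write_bed_coverage <- function(coverage, path) {
  out <- coverage %>%
    dplyr::transmute(
      .data$sample_id, .data$chrom,
      start = format(.data$start, scientific = FALSE, trim = TRUE),
      end = format(.data$end, scientific = FALSE, trim = TRUE)
    )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene model table
#'
#' Tab-delimited BED-like table of gene extents used for segment-to-gene
#' mapping: columns `chrom`, `start`, `end`, `gene_id` (BED order) or a
#' headered table with those names. Positions are interpreted as 1-based
#' inclusive to match the SEG convention they are intersected with.
#'
#' @param path path to the gene table.
#' @returns Tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  if (has_header) {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    g <- tibble::tibble(
      gene_id = raw$gene_id, chrom = normalize_chrom(raw$chrom),
      start = as.numeric(raw$start), end = as.numeric(raw$end)
    )
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    g <- tibble::tibble(
      gene_id = raw[[4]], chrom = normalize_chrom(raw[[1]]),
      start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]])
    )
  }
  if (anyDuplicated(g$gene_id)) {
    stop("duplicate gene_id in gene model table", call. = FALSE)
  }
  if (any(g$start > g$end)) stop("gene start > end", call. = FALSE)
  g
}

#' Read a sample annotation table with hormone-receptor status
#'
#' Tab-delimited with columns `sample_id`, `er`, `pr`, `her2`; marker values
#' may be `+`, `-`, `positive`, `negative`, or empty/`NA` (unknown).
#'
#' @param path path to the annotation table.
#' @returns Tibble with `sample_id` and `er`, `pr`, `her2` each one of
#'   `"positive"`, `"negative"`, `"unknown"`.
#' @export
read_marker_annotations <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  need <- c("sample_id", "er", "pr", "her2")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(sprintf("annotation table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  dplyr::mutate(raw[need], dplyr::across(c("er", "pr", "her2"), normalize_marker))
}

#' Normalize a marker-status value
#'
#' @param x character vector of marker readings (`"+"`, `"-"`, `"positive"`,
#'   `"neg"`, `NA`, ...).
#' @returns Character vector over `"positive"`, `"negative"`, `"unknown"`.
#' @export
normalize_marker <- function(x) {
  x <- tolower(trimws(as.character(x)))
  dplyr::case_when(
    is.na(x) | x == "" | x == "unknown" | x == "na" ~ "unknown",
    x %in% c("+", "pos", "positive", "1", "true") ~ "positive",
    x %in% c("-", "−", "neg", "negative", "0", "false") ~ "negative",
    TRUE ~ "unknown"
  )
}
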