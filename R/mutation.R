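#' Six complement-collapsed substitution categories
#'
#' Single-base substitutions are reported with the reference base normalized
#' to a pyrimidine-free convention: any G>* or T>* change is
#' reverse-complemented so every substitution falls into one of `A>C`, `A>G`,
#' `A>T`, `C>A`, `C>G`, `C>T`. `A>G` and `C>T` are the two transition
#' categories; the other four are transversions.
#'
#' @returns Character vector of the six categories in fixed order.
#' @export
spectrum_categories <- function() {
  c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")
}

#' Default functional variant classifications
#'
#' The keep-set used when restricting a mutation table to protein-affecting
#' somatic events; intronic, silent, UTR and other non-coding classes fall
#' outside it.
#'
#' @returns Character vector of MAF `Variant_Classification` values.
#' @export
functional_classes <- function() {
  c("Missense_Mutation", "Missense", "Nonsense_Mutation", "Nonsense",
    "Nonstop_Mutation", "Nonstop", "Splice_Site",
    "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
    "Translation_Start_Site")
}

.revcomp_base <- function(x) chartr("ACGT", "TGCA", x)

.revcomp_seq <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(.revcomp_base(s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.is_snv <- function(ref, alt) {
  ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
}

#' Keep somatic, functional, non-germline mutations
#'
#' Restricts a mutation table to records that are flagged somatic, carry a
#' protein-affecting variant classification, and do not sit at a known
#' germline polymorphism site. Germline removal is driven by an explicit
#' site blacklist (chromosome + position), standing in for database lookups
#' of common polymorphisms.
#'
#' @param muts mutation tibble.
#' @param germline_sites optional tibble with `chrom` and `position` columns
#'   listing sites to drop.
#' @param keep_classes variant classifications retained; defaults to
#'   [functional_classes()].
#' @returns Filtered mutation tibble.
#' @export
filter_somatic_functional <- function(muts, germline_sites = NULL,
                                      keep_classes = functional_classes()) {
  out <- dplyr::filter(muts, .data$somatic,
                       .data$variant_classification %in% keep_classes)
  if (!is.null(germline_sites) && nrow(germline_sites) > 0) {
    out <- dplyr::anti_join(out, germline_sites[c("chrom", "position")],
                            by = c("chrom", "position"))
  }
  out
}

#' Gene-by-sample mutation indicator matrix
#'
#' Encodes mutation presence as 0/1: a gene/sample cell is 1 when at least
#' one (already filtered) record exists for that gene in that sample,
#' regardless of multiplicity. Panel genes never seen in the table are 0
#' everywhere.
#'
#' @param muts filtered mutation tibble.
#' @param gene_panel character vector of genes forming the matrix rows.
#' @param samples character vector of sample ids forming the columns.
#' @returns Numeric 0/1 matrix, genes x samples.
#' @export
binarize_mutations <- function(muts, gene_panel, samples) {
  m <- matrix(0, nrow = length(gene_panel), ncol = length(samples),
              dimnames = list(gene_panel, samples))
  hit <- dplyr::filter(muts, .data$gene_id %in% gene_panel,
                       .data$sample_id %in% samples)
  if (nrow(hit) > 0) {
    m[cbind(match(hit$gene_id, gene_panel), match(hit$sample_id, samples))] <- 1
  }
  m
}

#' Per-gene mutation frequency
#'
#' The fraction of samples in which each gene carries at least one mutation
#' (the row mean of the 0/1 matrix).
#'
#' @param binary 0/1 matrix from [binarize_mutations()].
#' @returns Tibble with `gene_id`, `frequency`.
#' @export
mutation_frequency <- function(binary) {
  stopifnot(ncol(binary) >= 1)
  tibble::tibble(gene_id = rownames(binary),
                 frequency = unname(rowMeans(binary)))
}

#' Somatic mutation rate per megabase
#'
#' For each sample, the count of (filtered) mutation records divided by the
#' sample's sequencing footprint in megabases. The footprint is the total
#' length of the sample's coverage intervals after merging, so duplicated or
#' overlapping coverage records are never double-counted (BED intervals are
#' 0-based half-open: bases = end - start).
#'
#' @param muts filtered mutation tibble.
#' @param coverage coverage tibble.
#' @returns Tibble with `sample_id`, `n_mutations`, `covered_bases`,
#'   `rate_per_mb` for every sample present in `coverage`.
#' @export
mutation_rate_per_mb <- function(muts, coverage) {
  bases <- covered_bases(coverage)
  if (any(bases$bases <= 0)) {
    stop("sample with zero covered bases", call. = FALSE)
  }
  counts <- muts %>%
    dplyr::count(.data$sample_id, name = "n_mutations")
  bases %>%
    dplyr::left_join(counts, by = "sample_id") %>%
    dplyr::mutate(
      n_mutations = dplyr::coalesce(.data$n_mutations, 0L),
      rate_per_mb = .data$n_mutations * 1e6 / .data$bases
    ) %>%
    dplyr::select("sample_id", "n_mutations", covered_bases = "bases",
                  "rate_per_mb")
}

# Complement-collapse substitutions: returns a tibble of category plus the
# (possibly reverse-complemented) context, dropping non-SNV records.
.collapse_snvs <- function(muts) {
  snv <- dplyr::filter(muts, .is_snv(.data$ref_allele, .data$alt_allele))
  if (nrow(snv) == 0) return(snv)
  flip <- snv$ref_allele %in% c("G", "T")
  ref <- ifelse(flip, .revcomp_base(snv$ref_allele), snv$ref_allele)
  alt <- ifelse(flip, .revcomp_base(snv$alt_allele), snv$alt_allele)
  ctx <- if ("context" %in% names(snv)) snv$context else rep(NA_character_, nrow(snv))
  ctx[flip] <- .revcomp_seq(ctx[flip])
  dplyr::mutate(snv, category = paste0(ref, ">", alt), context = ctx)
}

#' Six-category substitution spectrum
#'
#' Tallies the single-base substitutions of a mutation table into the six
#' complement-collapsed categories of [spectrum_categories()] and returns
#' their proportions (pooled counts over all records; indels and other
#' non-SNV alleles are excluded). The spectrum is strand-symmetric by
#' construction: reverse-complementing every record leaves it unchanged.
#'
#' @param muts mutation tibble (typically already filtered to somatic
#'   functional records).
#' @returns Tibble with `category`, `n`, `proportion` (six rows, fixed
#'   order; proportions sum to 1).
#' @export
mutation_spectrum <- function(muts) {
  snv <- .collapse_snvs(muts)
  if (nrow(snv) == 0) {
    stop("no single-base substitution present; spectrum undefined",
         call. = FALSE)
  }
  n <- table(factor(snv$category, levels = spectrum_categories()))
  tibble::tibble(
    category = spectrum_categories(),
    n = as.integer(n),
    proportion = as.numeric(n) / sum(n)
  )
}

#' Flanking-nucleotide context profile of substitutions
#'
#' For each substitution category, the base composition at the four flanking
#' positions (-2, -1, +1, +2) of the variant site, computed from the 5-base
#' context strings carried by the records. Records whose reference base was
#' complement-collapsed contribute their reverse-complemented context, so the
#' profile shares the spectrum's strand symmetry. Records without a context
#' are skipped and counted in a warning.
#'
#' @param muts mutation tibble with a `context` column.
#' @returns Tibble with `category`, `position` (-2, -1, 1, 2), `base`,
#'   `n`, `proportion`; within each category and position the proportions
#'   sum to 1.
#' @export
context_profile <- function(muts) {
  snv <- .collapse_snvs(muts)
  n_missing <- sum(is.na(snv$context))
  if (n_missing > 0) {
    warning(sprintf("%d record(s) without context excluded", n_missing),
            call. = FALSE)
  }
  snv <- dplyr::filter(snv, !is.na(.data$context))
  if (nrow(snv) == 0) {
    stop("no record with a context string; profile undefined", call. = FALSE)
  }
  offsets <- c(`-2` = 1L, `-1` = 2L, `1` = 4L, `2` = 5L)
  long <- purrr::imap_dfr(offsets, function(chr_pos, pos_label) {
    tibble::tibble(
      category = snv$category,
      position = as.integer(pos_label),
      base = substr(snv$context, chr_pos, chr_pos)
    )
  })
  long %>%
    dplyr::count(.data$category, .data$position, .data$base, name = "n") %>%
    tidyr::complete(.data$category, .data$position,
                    base = c("A", "C", "G", "T"), fill = list(n = 0L)) %>%
    dplyr::group_by(.data$category, .data$position) %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$category, .data$position, .data$base)
}

#' Correlation between two spectra or context profiles
#'
#' Pearson correlation of two proportion vectors of the same kind — two
#' six-category spectra, or two flattened context profiles — e.g. the pooled
#' spectrum of one subtype's cell lines against the same subtype's tumors.
#'
#' @param a,b numeric vectors of equal length, or tibbles from
#'   [mutation_spectrum()] / [context_profile()] (their `proportion` columns
#'   are used, aligned by category/position/base).
#' @returns Pearson correlation coefficient.
#' @export
spectrum_correlation <- function(a, b) {
  to_vec <- function(x) {
    if (is.data.frame(x)) {
      key_cols <- intersect(c("category", "position", "base"), names(x))
      x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(key_cols)))
      x$proportion
    } else {
      as.numeric(x)
    }
  }
  va <- to_vec(a)
  vb <- to_vec(b)
  if (length(va) != length(vb)) {
    stop("spectra have different dimensions", call. = FALSE)
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("constant spectrum; correlation undefined", call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Mutation-profile similarity between cell lines and tumors
#'
#' Pearson correlation between the 0/1 mutation columns of each (cell line,
#' tumor) pair over their shared gene panel — for binary vectors this equals
#' the phi coefficient of the 2x2 presence/absence table. A constant column
#' (a sample with no mutated panel gene, or all mutated) yields a missing
#' correlation.
#'
#' @param cells_binary 0/1 matrix, genes x cell lines.
#' @param tumors_binary 0/1 matrix, genes x tumors.
#' @param min_obs minimum shared panel genes.
#' @returns Long correlation tibble as from [pairwise_correlation()].
#' @export
mutation_similarity <- function(cells_binary, tumors_binary, min_obs = 3) {
  shared <- intersect(rownames(cells_binary), rownames(tumors_binary))
  if (length(shared) == 0) {
    stop("no shared gene panel between the binary matrices", call. = FALSE)
  }
  pairwise_correlation(cells_binary, tumors_binary, min_obs = min_obs,
                       layer = "mut")
}
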