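#' Fraction of genome altered per sample
#'
#' For each sample, the fraction of total segmented length carried by
#' segments whose absolute segment mean (log2(CN/2)) exceeds the threshold:
#' `FGA = sum(L_i for |CN_i| > T) / sum(L_i)` with segment length
#' `L_i = end - start + 1` (SEG coordinates are 1-based inclusive). The
#' conventional thresholds are 0.2 for tumors and 0.3 for cell lines, whose
#' segment profiles are noisier and more aberrant.
#'
#' @param segments segment tibble (may hold many samples).
#' @param threshold positive segment-mean cutoff `T`.
#' @returns Tibble with `sample_id`, `fga` in `[0, 1]`.
#' @export
compute_fga <- function(segments, threshold = 0.2) {
  stopifnot(is.numeric(threshold), threshold > 0)
  if (nrow(segments) == 0) {
    stop("FGA is undefined for an empty segment set", call. = FALSE)
  }
  segments %>%
    dplyr::mutate(len = .data$end - .data$start + 1) %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      fga = sum(.data$len[abs(.data$seg_mean) > threshold]) / sum(.data$len),
      .groups = "drop"
    )
}

#' Map copy-number segments onto gene regions
#'
#' Converts a per-sample segment profile into a genes x samples matrix of
#' copy-number values: each gene receives the overlap-length-weighted mean of
#' the segment means overlapping its extent. A gene with no overlapping
#' segment in a sample is missing for that sample. Both tables must use the
#' same normalized chromosome naming and 1-based inclusive coordinates; the
#' weighting makes the result identical to averaging the per-base segment
#' value across the gene body.
#'
#' @param segments segment tibble.
#' @param genes gene model tibble (`gene_id`, `chrom`, `start`, `end`).
#' @returns Numeric matrix, genes x samples (all input genes and samples
#'   present; `NA` where no segment overlaps).
#' @export
map_segments_to_genes <- function(segments, genes) {
  samples <- unique(segments$sample_id)
  hits <- dplyr::inner_join(
    dplyr::rename(genes, g_start = "start", g_end = "end"),
    dplyr::rename(segments, s_start = "start", s_end = "end"),
    by = "chrom", relationship = "many-to-many"
  ) %>%
    dplyr::mutate(
      ov = pmin(.data$g_end, .data$s_end) - pmax(.data$g_start, .data$s_start) + 1
    ) %>%
    dplyr::filter(.data$ov > 0)
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
              dimnames = list(genes$gene_id, samples))
  if (nrow(hits) > 0) {
    # overlap-weighted mean per (gene, sample) cell via C-level rowsum
    idx <- cbind(match(hits$gene_id, genes$gene_id),
                 match(hits$sample_id, samples))
    key <- (idx[, 1] - 1) * length(samples) + idx[, 2]
    num <- rowsum(hits$ov * hits$seg_mean, key)
    den <- rowsum(hits$ov, key)
    keys <- as.numeric(rownames(num))
    m[cbind((keys - 1) %/% length(samples) + 1,
            (keys - 1) %% length(samples) + 1)] <- num[, 1] / den[, 1]
  }
  m
}

#' Threshold a gene-level copy-number matrix into discrete calls
#'
#' A gene/sample value above `amp_threshold` is called amplified, below
#' `del_threshold` deleted, otherwise neutral; missing stays missing. The
#' default cutoffs of +/- 0.3 on the log2(CN/2) scale are the conventional
#' ones for calling focal gains and losses from SNP-array segment means.
#'
#' @param m genes x samples numeric matrix of segment-mean values.
#' @param amp_threshold amplification cutoff (default 0.3).
#' @param del_threshold deletion cutoff (default -0.3).
#' @returns Character matrix over `"amplified"`, `"deleted"`, `"neutral"`,
#'   `NA`.
#' @export
call_cnv <- function(m, amp_threshold = 0.3, del_threshold = -0.3) {
  stopifnot(del_threshold < amp_threshold)
  calls <- matrix(NA_character_, nrow(m), ncol(m), dimnames = dimnames(m))
  calls[!is.na(m)] <- "neutral"
  calls[!is.na(m) & m > amp_threshold] <- "amplified"
  calls[!is.na(m) & m < del_threshold] <- "deleted"
  calls
}

#' Per-gene amplification and deletion frequency
#'
#' @param calls character matrix from [call_cnv()].
#' @returns Tibble with `gene_id`, `n` (samples with a call),
#'   `amp_fraction`, `del_fraction`; genes with no called sample are missing.
#' @export
alteration_frequency <- function(calls) {
  stopifnot(ncol(calls) >= 1)
  n <- rowSums(!is.na(calls))
  tibble::tibble(
    gene_id = rownames(calls),
    n = as.integer(n),
    amp_fraction = ifelse(n > 0, rowSums(calls == "amplified", na.rm = TRUE) / n,
                          NA_real_),
    del_fraction = ifelse(n > 0, rowSums(calls == "deleted", na.rm = TRUE) / n,
                          NA_real_)
  )
}

#' Select the most variable genes of a copy-number matrix
#'
#' Ranks genes by the variance of their values across all samples (cohorts
#' pooled, so cell lines and tumors see the same gene set) and returns the
#' top fraction. Ties are broken lexicographically by gene id for
#' determinism; genes with fewer than two non-missing values are ineligible.
#'
#' @param m genes x samples numeric matrix.
#' @param fraction fraction of eligible genes to keep, in `(0, 1]`.
#' @param n_genes optional explicit gene count overriding `fraction`.
#' @returns Character vector of selected gene ids, highest variance first.
#' @export
select_top_variable <- function(m, fraction = 0.10, n_genes = NULL) {
  if (is.null(n_genes) && (fraction <= 0 || fraction > 1)) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  v <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::var(x)
  })
  eligible <- names(v)[!is.na(v)]
  if (length(eligible) == 0) {
    stop("no gene with >= 2 non-missing values", call. = FALSE)
  }
  k <- if (is.null(n_genes)) ceiling(fraction * length(eligible))
       else min(as.integer(n_genes), length(eligible))
  ord <- order(-v[eligible], eligible)
  eligible[ord][seq_len(k)]
}

#' Copy-number similarity between cell lines and tumors
#'
#' Pairwise Pearson correlation of gene-level copy-number profiles,
#' restricted to a high-variance gene set: either an explicit `genes` list or
#' the top `top_fraction` of genes by pooled-cohort variance (the default, 10
#' percent). Restricting to variable genes suppresses the flat diploid
#' background that would otherwise dominate the correlation.
#'
#' @param cells genes x cell-lines copy-number matrix.
#' @param tumors genes x tumors copy-number matrix.
#' @param genes optional explicit gene set.
#' @param top_fraction fraction of pooled-variance-ranked genes used when
#'   `genes` is not given.
#' @param min_obs minimum pairwise-complete genes per pair.
#' @returns Long correlation tibble as from [pairwise_correlation()].
#' @export
cnv_similarity <- function(cells, tumors, genes = NULL, top_fraction = 0.10,
                           min_obs = 3) {
  if (is.null(genes)) {
    shared <- intersect(rownames(cells), rownames(tumors))
    pooled <- cbind(cells[shared, , drop = FALSE], tumors[shared, , drop = FALSE])
    genes <- select_top_variable(pooled, fraction = top_fraction)
  }
  pairwise_correlation(cells, tumors, features = genes, min_obs = min_obs,
                       layer = "cnv")
}
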