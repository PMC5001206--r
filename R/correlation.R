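#' Pairwise cell-line-vs-tumor correlation on shared features
#'
#' The workhorse of every similarity layer: Pearson correlation between each
#' cell-line column and each tumor column, computed over the features the two
#' matrices share (optionally restricted to a caller-supplied feature list).
#' Missing entries are handled pairwise-complete; a pair with fewer than
#' `min_obs` complete observations gets a missing correlation rather than a
#' spurious one.
#'
#' @param cells numeric matrix, features x cell lines.
#' @param tumors numeric matrix, features x tumors.
#' @param features optional character vector restricting the feature set.
#' @param min_obs minimum pairwise-complete observations per pair (default
#'   3); also the minimum number of shared features.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param layer optional layer name recorded on the result (e.g. `"expr"`).
#' @returns Long tibble with columns `cell_id`, `tumor_id`, `r`; attribute
#'   `layer` and `n_features` record what was correlated.
#' @export
pairwise_correlation <- function(cells, tumors, features = NULL, min_obs = 3,
                                 method = c("pearson", "spearman"),
                                 layer = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(cells), is.matrix(tumors))
  shared <- intersect(rownames(cells), rownames(tumors))
  if (!is.null(features)) shared <- intersect(shared, features)
  if (length(shared) < min_obs) {
    stop(sprintf("only %d shared feature(s) between the matrices (need >= %d)",
                 length(shared), min_obs), call. = FALSE)
  }
  x <- cells[shared, , drop = FALSE]
  y <- tumors[shared, , drop = FALSE]
  r <- suppressWarnings(stats::cor(x, y, use = "pairwise.complete.obs",
                                   method = method))
  n_complete <- crossprod(!is.na(x), !is.na(y))
  r[n_complete < min_obs] <- NA_real_
  out <- tibble::as_tibble(r, rownames = "cell_id") %>%
    tidyr::pivot_longer(-"cell_id", names_to = "tumor_id", values_to = "r")
  attr(out, "layer") <- layer
  attr(out, "n_features") <- length(shared)
  class(out) <- c("portrait_cor", class(out))
  out
}

#' Average a pairwise correlation table per cell line
#'
#' Collapses a (cell line, tumor) correlation table to one mean correlation
#' per cell line — the per-layer similarity component entering the combined
#' suitability score. With `subtype_map`, only tumors sharing a cell line's
#' subtype label enter its mean (the subtype-matched variant); cell lines
#' with no usable pair get a missing mean, never zero.
#'
#' @param tab long correlation tibble from [pairwise_correlation()].
#' @param subtype_map optional tibble with `sample_id` and `final_label`
#'   covering both cell lines and tumors.
#' @returns Tibble with `cell_id`, `n_pairs` (non-missing correlations used)
#'   and `mean_r`.
#' @export
aggregate_by_cell <- function(tab, subtype_map = NULL) {
  stopifnot(nrow(tab) > 0)
  all_cells <- unique(tab$cell_id)
  if (!is.null(subtype_map)) {
    lab <- stats::setNames(subtype_map$final_label, subtype_map$sample_id)
    tab <- dplyr::filter(
      tab,
      !is.na(lab[.data$cell_id]), !is.na(lab[.data$tumor_id]),
      lab[.data$cell_id] == lab[.data$tumor_id]
    )
  }
  agg <- tab %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::summarise(
      n_pairs = sum(!is.na(.data$r)),
      mean_r = ifelse(.data$n_pairs > 0, mean(.data$r, na.rm = TRUE), NA_real_),
      .groups = "drop"
    )
  # every input cell line stays in the output, missing when nothing usable
  tibble::tibble(cell_id = all_cells) %>%
    dplyr::left_join(agg, by = "cell_id") %>%
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L))
}

#' Per-gene correlation between mRNA and (phospho-)protein abundance
#'
#' A gene may be probed by several mRNA probe sets and detected as several
#' protein or phospho-protein forms; the mapping table enumerates the
#' (probe, protein-form) pairs per gene. For each pair, Pearson correlation
#' is computed across the samples shared by the two matrices, and the pair
#' correlations are averaged into one value per gene.
#'
#' @param expr numeric matrix, probes x samples (mRNA).
#' @param protein numeric matrix, protein forms x samples.
#' @param mapping tibble with columns `gene_id`, `probe_id`, `protein_id`.
#' @param min_obs minimum shared samples per pair (default 3); genes whose
#'   pairs all fall short get a missing value and a warning is emitted with
#'   the count of such genes.
#' @returns Tibble with `gene_id`, `n_pairs`, `mean_r`.
#' @export
mrna_protein_correlation <- function(expr, protein, mapping, min_obs = 3) {
  stopifnot(all(c("gene_id", "probe_id", "protein_id") %in% names(mapping)))
  shared <- intersect(colnames(expr), colnames(protein))
  if (length(shared) < min_obs) {
    stop(sprintf("only %d shared sample(s) between matrices (need >= %d)",
                 length(shared), min_obs), call. = FALSE)
  }
  pair_r <- purrr::pmap_dbl(
    mapping[c("probe_id", "protein_id")],
    function(probe_id, protein_id) {
      if (!probe_id %in% rownames(expr) || !protein_id %in% rownames(protein)) {
        return(NA_real_)
      }
      x <- expr[probe_id, shared]
      y <- protein[protein_id, shared]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_obs) return(NA_real_)
      suppressWarnings(stats::cor(x[ok], y[ok]))
    }
  )
  out <- mapping %>%
    dplyr::mutate(.r = pair_r) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      n_pairs = sum(!is.na(.data$.r)),
      mean_r = ifelse(.data$n_pairs > 0, mean(.data$.r, na.rm = TRUE), NA_real_),
      .groups = "drop"
    )
  n_miss <- sum(is.na(out$mean_r))
  if (n_miss > 0) {
    warning(sprintf("%d gene(s) had no pair with >= %d shared observations",
                    n_miss, min_obs), call. = FALSE)
  }
  out
}
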