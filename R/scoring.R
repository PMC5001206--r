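#' Combined cell-line suitability score
#'
#' Sums a cell line's four layer-wise mean correlations with the tumor
#' cohort — expression (A), copy number (B), mutation (C) and protein (D) —
#' into one unweighted score, `Score = A + B + C + D`. Under the default
#' `require_all` policy the score is missing unless all four components are
#' present (a cell line must be assayed on every platform to be ranked);
#' under `available_mean` the mean of the present components is rescaled to
#' the four-component range (`mean * 4`), missing only when no component is
#' present.
#'
#' @param expr,cnv,mut,prot numeric vectors of layer components, recycled to
#'   a common length; `NA` marks a missing layer.
#' @param policy `"require_all"` (default) or `"available_mean"`.
#' @returns Numeric vector of scores (with `NA` where undefined).
#' @export
#' @examples
#' total_score(0.7, 0.5, 0.2, 0.3)                    # 1.7
#' total_score(0.6, 0.4, NA, NA)                      # NA
#' total_score(0.6, 0.4, NA, NA, policy = "available_mean")  # 2.0
total_score <- function(expr, cnv, mut, prot,
                        policy = c("require_all", "available_mean")) {
  policy <- match.arg(policy)
  comp <- cbind(expr = expr, cnv = cnv, mut = mut, prot = prot)
  if (policy == "require_all") {
    expr + cnv + mut + prot
  } else {
    n_present <- rowSums(!is.na(comp))
    ifelse(n_present > 0, rowMeans(comp, na.rm = TRUE) * 4, NA_real_)
  }
}

#' Score and rank cell lines by their four-layer similarity components
#'
#' Builds the full score table from a per-cell-line component table: the
#' combined score under the chosen policy, and a descending-score rank.
#' Equal scores are ordered by cell id; cell lines without a defined score
#' are listed last, unranked.
#'
#' @param components tibble with columns `cell_id`, `expr`, `cnv`, `mut`,
#'   `prot` (layer mean correlations; `NA` = layer missing).
#' @param policy score policy, see [total_score()].
#' @returns Tibble of class `portrait_scores` with columns `cell_id`,
#'   `expr`, `cnv`, `mut`, `prot`, `n_layers_present`, `score`, `rank`.
#' @export
rank_cell_lines <- function(components,
                            policy = c("require_all", "available_mean")) {
  policy <- match.arg(policy)
  need <- c("cell_id", "expr", "cnv", "mut", "prot")
  miss <- setdiff(need, names(components))
  if (length(miss) > 0) {
    stop(sprintf("component table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- components %>%
    dplyr::mutate(
      n_layers_present = rowSums(!is.na(cbind(.data$expr, .data$cnv,
                                              .data$mut, .data$prot))),
      score = total_score(.data$expr, .data$cnv, .data$mut, .data$prot,
                          policy = policy)
    )
  if (all(is.na(out$score))) {
    stop("no cell line with a defined score under this policy", call. = FALSE)
  }
  out <- dplyr::arrange(out, is.na(.data$score), dplyr::desc(.data$score),
                        .data$cell_id)
  out$rank <- ifelse(is.na(out$score), NA_integer_,
                     seq_len(nrow(out)))
  attr(out, "policy") <- policy
  class(out) <- c("portrait_scores", class(out))
  out
}

#' Tidy a score table
#'
#' @param x `portrait_scores` tibble.
#' @param ... unused.
#' @returns The score table as a plain tibble (long-lived attributes
#'   dropped).
#' @method tidy portrait_scores
#' @export
tidy.portrait_scores <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "portrait_scores")
  attr(out, "policy") <- NULL
  out
}

#' One-line summary of a score table
#'
#' @param x `portrait_scores` tibble.
#' @param ... unused.
#' @returns One-row tibble with `n_cells`, `n_scored`, `policy`,
#'   `top_cell`, `top_score`.
#' @method glance portrait_scores
#' @export
glance.portrait_scores <- function(x, ...) {
  scored <- dplyr::filter(x, !is.na(.data$score))
  tibble::tibble(
    n_cells = nrow(x),
    n_scored = nrow(scored),
    policy = attr(x, "policy"),
    top_cell = scored$cell_id[1],
    top_score = scored$score[1]
  )
}
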