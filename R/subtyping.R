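#' Canonical breast-cancer subtype labels
#'
#' The closed label set used throughout: `"LuminalA"`, `"LuminalB"`,
#' `"HER2amp"`, `"BasalLike"` and `"Unclassified"` (the catch-all for
#' normal-like calls, unresolvable marker status, and "NON" table entries).
#'
#' @returns Character vector of the five labels in their fixed precedence
#'   order (used for deterministic tie-breaking in centroid calls).
#' @export
subtype_levels <- function() {
  c("LuminalA", "LuminalB", "HER2amp", "BasalLike", "Unclassified")
}

#' Normalize a subtype label to the canonical set
#'
#' Maps the spellings found in published tables ("Luminal A", "Her2amp",
#' "Basal-like", "NON", "Normal", "Normal-like", "other") onto
#' [subtype_levels()]. Normal-like and "NON" map to `"Unclassified"`.
#'
#' @param x character vector of labels.
#' @returns Character vector over the canonical label set.
#' @export
normalize_subtype <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(as.character(x)))
  dplyr::case_when(
    key %in% c("luminala", "luma", "lua") ~ "LuminalA",
    key %in% c("luminalb", "lumb", "lub") ~ "LuminalB",
    key %in% c("her2amp", "her2", "her2enriched", "her2enrichment") ~ "HER2amp",
    key %in% c("basallike", "basal") ~ "BasalLike",
    TRUE ~ "Unclassified"
  )
}

# Table-2 immunoprofile rule for fully known marker triples.
.ihc_rule_known <- function(er, pr, her2) {
  hr_pos <- er == "positive" | pr == "positive"
  dplyr::case_when(
    hr_pos & her2 == "negative" ~ "LuminalA",
    hr_pos & her2 == "positive" ~ "LuminalB",
    !hr_pos & her2 == "positive" ~ "HER2amp",
    TRUE ~ "BasalLike"
  )
}

# Lookup over all 27 (er, pr, her2) status triples: a non-Unclassified label
# is returned only when every completion of the unknown markers agrees.
.ihc_lookup <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    vals <- c("positive", "negative", "unknown")
    grid <- expand.grid(er = vals, pr = vals, her2 = vals,
                        stringsAsFactors = FALSE)
    known <- c("positive", "negative")
    grid$label <- vapply(seq_len(nrow(grid)), function(i) {
      comp <- expand.grid(
        er = if (grid$er[i] == "unknown") known else grid$er[i],
        pr = if (grid$pr[i] == "unknown") known else grid$pr[i],
        her2 = if (grid$her2[i] == "unknown") known else grid$her2[i],
        stringsAsFactors = FALSE
      )
      labs <- unique(.ihc_rule_known(comp$er, comp$pr, comp$her2))
      if (length(labs) == 1L) labs else "Unclassified"
    }, character(1))
    tab <<- grid
    tab
  }
})

#' Classify samples by ER/PR/HER2 immunoprofile
#'
#' Implements the hormone-receptor rule table: HER2-negative with ER or PR
#' positive is Luminal A; HER2-positive with ER or PR positive is Luminal B;
#' triple ER-/PR-/HER2+ is HER2-amplified; triple-negative is Basal-like.
#' Unknown markers are handled by rule closure: every completion of the
#' unknown values is evaluated, and a label is returned only if all
#' completions agree, otherwise `"Unclassified"`. The function is therefore
#' total and never guesses.
#'
#' @param er,pr,her2 character vectors of marker status; any spelling
#'   accepted by [normalize_marker()].
#' @returns Character vector of subtype labels (see [subtype_levels()]).
#' @export
#' @examples
#' classify_ihc("+", "+", "-")        # LuminalA
#' classify_ihc("-", "-", "+")        # HER2amp
#' classify_ihc("+", NA, "-")         # LuminalA: PR cannot change the call
#' classify_ihc(NA, "-", "-")         # Unclassified: ER decides LumA vs Basal
classify_ihc <- function(er, pr, her2) {
  status <- tibble::tibble(
    er = normalize_marker(er), pr = normalize_marker(pr),
    her2 = normalize_marker(her2)
  )
  dplyr::left_join(status, .ihc_lookup(), by = c("er", "pr", "her2"))$label
}

#' Nearest-centroid subtype prediction for one expression profile
#'
#' Scores a sample's expression profile against each column of a centroid
#' matrix by Pearson correlation over the genes shared between profile and
#' centroids, and returns the best-correlated subtype. Centroid columns
#' labelled normal-like (anything normalizing to `"Unclassified"`, e.g.
#' "Normal") can win the correlation contest but are reported as
#' `"Unclassified"`, since normal-like calls are excluded from subtype
#' comparisons. Ties are broken by the fixed label order of
#' [subtype_levels()], then alphabetically, so the call is deterministic.
#'
#' @param profile named numeric vector (names are gene ids).
#' @param centroids numeric matrix, genes x subtypes, with gene rownames and
#'   subtype colnames.
#' @param min_shared minimum genes shared between profile and centroids
#'   (default 3); fewer is an error.
#' @returns A one-row tibble with `centroid_label` and `centroid_r`.
#' @export
classify_centroid <- function(profile, centroids, min_shared = 3) {
  stopifnot(is.matrix(centroids), ncol(centroids) >= 2)
  shared <- intersect(names(profile)[!is.na(profile)], rownames(centroids))
  if (length(shared) < min_shared) {
    stop(sprintf("only %d gene(s) shared with the centroid table (need >= %d)",
                 length(shared), min_shared), call. = FALSE)
  }
  x <- profile[shared]
  r <- apply(centroids[shared, , drop = FALSE], 2, function(cent) {
    ok <- !is.na(cent)
    if (sum(ok) < min_shared) return(NA_real_)
    suppressWarnings(stats::cor(x[ok], cent[ok]))
  })
  if (all(is.na(r))) {
    return(tibble::tibble(centroid_label = "Unclassified", centroid_r = NA_real_))
  }
  labs <- colnames(centroids)
  norm <- normalize_subtype(labs)
  ord <- order(-r, match(norm, subtype_levels()), labs, na.last = TRUE)
  best <- ord[1]
  tibble::tibble(centroid_label = norm[best], centroid_r = unname(r[best]))
}

#' Nearest-centroid prediction for every sample of a matrix
#'
#' @param expr numeric matrix, genes x samples.
#' @param centroids centroid matrix as in [classify_centroid()].
#' @param min_shared minimum shared genes per sample.
#' @returns Tibble with `sample_id`, `centroid_label`, `centroid_r`.
#' @export
classify_centroid_matrix <- function(expr, centroids, min_shared = 3) {
  purrr::map_dfr(colnames(expr), function(s) {
    dplyr::bind_cols(
      tibble::tibble(sample_id = s),
      classify_centroid(expr[, s], centroids, min_shared = min_shared)
    )
  })
}

#' Combine marker-based and centroid-based subtype calls
#'
#' Marker status, when it resolves, takes precedence; the expression-based
#' centroid call only fills in samples whose immunoprofile is unresolvable.
#'
#' @param ihc,centroid character vectors of subtype labels (recycled to a
#'   common length).
#' @returns Character vector of final labels.
#' @export
assign_final <- function(ihc, centroid) {
  ihc <- normalize_subtype(ihc)
  centroid <- normalize_subtype(centroid)
  ifelse(ihc != "Unclassified", ihc, centroid)
}

#' Subtype calls for a cohort
#'
#' Runs the full assignment for a set of samples: the immunoprofile rule on
#' the annotation table, the nearest-centroid prediction on the expression
#' matrix (when both `expr` and `centroids` are given), and the final label
#' that prefers resolved marker status.
#'
#' @param annotations tibble with `sample_id`, `er`, `pr`, `her2` (any marker
#'   spelling); samples absent from it get unknown markers.
#' @param expr optional genes x samples expression matrix.
#' @param centroids optional centroid matrix.
#' @param min_shared minimum shared genes for the centroid step.
#' @returns Tibble with `sample_id`, `ihc_label`, `centroid_label`,
#'   `centroid_r`, `final_label`.
#' @export
call_subtypes <- function(annotations, expr = NULL, centroids = NULL,
                          min_shared = 3) {
  samples <- if (!is.null(expr)) colnames(expr) else annotations$sample_id
  ann <- tibble::tibble(sample_id = samples) %>%
    dplyr::left_join(annotations, by = "sample_id")
  calls <- tibble::tibble(
    sample_id = samples,
    ihc_label = classify_ihc(ann$er, ann$pr, ann$her2)
  )
  if (!is.null(expr) && !is.null(centroids)) {
    cen <- classify_centroid_matrix(expr, centroids, min_shared = min_shared)
    calls <- dplyr::left_join(calls, cen, by = "sample_id")
  } else {
    calls$centroid_label <- "Unclassified"
    calls$centroid_r <- NA_real_
  }
  calls$final_label <- assign_final(calls$ihc_label, calls$centroid_label)
  calls
}

#' Concordance between two subtype call lists
#'
#' Compares two index-aligned label vectors and reports the agreement
#' fraction. Pairs whose entry in the designated list is `"Unclassified"` are
#' dropped from the denominator — the convention used when comparing an
#' expression-based prediction (which may return no call) against a
#' reference classification.
#'
#' @param calls_a,calls_b equal-length character vectors of subtype labels
#'   (normalized internally).
#' @param exclude_unclassified_in which list's `"Unclassified"` entries drop
#'   the pair: `"a"`, `"b"`, `"both"` or `"none"`.
#' @returns One-row tibble with `n_match`, `n_total`, `fraction`.
#' @export
concordance <- function(calls_a, calls_b,
                        exclude_unclassified_in = c("a", "b", "both", "none")) {
  exclude_unclassified_in <- match.arg(exclude_unclassified_in)
  if (length(calls_a) != length(calls_b)) {
    stop("call lists must have equal length", call. = FALSE)
  }
  a <- normalize_subtype(calls_a)
  b <- normalize_subtype(calls_b)
  keep <- switch(exclude_unclassified_in,
    a = a != "Unclassified",
    b = b != "Unclassified",
    both = a != "Unclassified" & b != "Unclassified",
    none = rep(TRUE, length(a))
  )
  n_total <- sum(keep)
  if (n_total == 0) {
    stop("no comparable pairs after exclusion", call. = FALSE)
  }
  n_match <- sum(a[keep] == b[keep])
  tibble::tibble(n_match = n_match, n_total = n_total,
                 fraction = n_match / n_total)
}

#' Published cell-line annotation table
#'
#' The packaged table of 68 breast-cancer cell lines with ER/PR/HER2 status,
#' the expression-based intrinsic-subtype prediction (`pam50_mrna`, with
#' `"NON"` marking lines without a call), and the final classification, as
#' printed in the source annotation table — including its internally
#' inconsistent rows, which are preserved verbatim so that published summary
#' statistics can be recomputed from it.
#'
#' @returns Tibble with columns `cell_line`, `er`, `pr`, `her2`,
#'   `pam50_mrna`, `final_classification`.
#' @export
table3_cell_lines <- function() {
  path <- system.file("extdata", "table3_cell_lines.tsv",
                      package = "oncoportrait", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE)
}
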