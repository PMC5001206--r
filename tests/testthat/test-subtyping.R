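test_that("immunoprofile rules reproduce the marker table", {
  expect_equal(classify_ihc("+", "+", "-"), "LuminalA")
  expect_equal(classify_ihc("+", "-", "-"), "LuminalA")
  expect_equal(classify_ihc("-", "+", "-"), "LuminalA")
  expect_equal(classify_ihc("+", "+", "+"), "LuminalB")
  expect_equal(classify_ihc("-", "-", "+"), "HER2amp")
  expect_equal(classify_ihc("-", "-", "-"), "BasalLike")
})

test_that("unknown markers only resolve when every completion agrees", {
  # PR cannot change the call once ER is positive and HER2 negative
  expect_equal(classify_ihc("+", NA, "-"), "LuminalA")
  expect_equal(classify_ihc("+", NA, "+"), "LuminalB")
  # ER decides between LuminalA and BasalLike, so the call must abstain
  expect_equal(classify_ihc(NA, "-", "-"), "Unclassified")
  expect_equal(classify_ihc(NA, NA, NA), "Unclassified")
})

test_that("the rule closure is exact over all 27 marker triples", {
  vals <- c("positive", "negative", "unknown")
  grid <- expand.grid(er = vals, pr = vals, her2 = vals,
                      stringsAsFactors = FALSE)
  known <- c("positive", "negative")
  for (i in seq_len(nrow(grid))) {
    call <- classify_ihc(grid$er[i], grid$pr[i], grid$her2[i])
    comp <- expand.grid(
      er = if (grid$er[i] == "unknown") known else grid$er[i],
      pr = if (grid$pr[i] == "unknown") known else grid$pr[i],
      her2 = if (grid$her2[i] == "unknown") known else grid$her2[i],
      stringsAsFactors = FALSE
    )
    completions <- unique(classify_ihc(comp$er, comp$pr, comp$her2))
    if (call != "Unclassified") {
      expect_equal(completions, call)
    } else {
      expect_gt(length(completions), 1)
    }
  }
})

test_that("nearest-centroid calls maximize Pearson correlation", {
  set.seed(11)
  genes <- paste0("g", 1:4)
  centroids <- matrix(c(1, 2, 3, 4, 2, -1, 0, 3), ncol = 2,
                      dimnames = list(genes, c("LuminalA", "BasalLike")))
  # profile identical to a centroid wins with r = 1
  out <- classify_centroid(centroids[, "BasalLike"], centroids)
  expect_equal(out$centroid_label, "BasalLike")
  expect_equal(out$centroid_r, 1)

  # anticorrelated profile must not pick its own negative
  two <- matrix(c(1, 2, 3, 4, 0.3, -1.2, 0.8, 0.1), ncol = 2,
                dimnames = list(genes, c("LuminalA", "BasalLike")))
  flipped <- -two[, "LuminalA"]
  expect_false(classify_centroid(flipped, two)$centroid_label == "LuminalA")

  # agrees with the brute-force Pearson oracle on random profiles
  for (rep in 1:20) {
    profile <- stats::setNames(rnorm(4), genes)
    r_by_label <- apply(centroids, 2, oracle_pearson, x = profile)
    out <- classify_centroid(profile, centroids)
    expect_equal(out$centroid_label, names(which.max(r_by_label)))
    expect_equal(out$centroid_r, unname(max(r_by_label)), tolerance = 1e-12)
  }
})

test_that("centroid calls are invariant to positive affine rescaling", {
  set.seed(12)
  genes <- paste0("g", 1:20)
  centroids <- matrix(rnorm(80), ncol = 4,
                      dimnames = list(genes,
                                      c("LuminalA", "LuminalB", "HER2amp",
                                        "BasalLike")))
  for (rep in 1:10) {
    profile <- stats::setNames(rnorm(20), genes)
    base <- classify_centroid(profile, centroids)
    scaled <- classify_centroid(profile * runif(1, 0.1, 5) + rnorm(1),
                                centroids)
    expect_equal(scaled$centroid_label, base$centroid_label)
    expect_equal(scaled$centroid_r, base$centroid_r, tolerance = 1e-9)
  }
})

test_that("normal-like centroid wins are reported as Unclassified", {
  genes <- paste0("g", 1:5)
  centroids <- matrix(c(1:5, 5:1, 1, 3, 2, 5, 4), ncol = 3,
                      dimnames = list(genes, c("Normal", "LuminalA", "BasalLike")))
  out <- classify_centroid(stats::setNames(c(1, 2, 3, 4, 5), genes), centroids)
  expect_equal(out$centroid_label, "Unclassified")
  expect_equal(out$centroid_r, 1)
})

test_that("too little gene overlap with the centroids is an error", {
  centroids <- matrix(1:4, ncol = 2,
                      dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(classify_centroid(c(g1 = 1, g2 = 2), centroids), "shared")
})

test_that("marker-based labels take precedence over centroid labels", {
  expect_equal(assign_final("LuminalA", "BasalLike"), "LuminalA")
  expect_equal(assign_final("Unclassified", "HER2amp"), "HER2amp")
  expect_equal(assign_final("Unclassified", "Unclassified"), "Unclassified")
  expect_equal(assign_final(c("LuminalA", "Unclassified"),
                            c("BasalLike", "BasalLike")),
               c("LuminalA", "BasalLike"))
})

test_that("concordance drops the designated list's no-calls and is symmetric", {
  a <- c("LuminalA", "LuminalB", "BasalLike")
  expect_equal(concordance(a, a)$fraction, 1)

  b <- c("LuminalB", "BasalLike", "LuminalA")
  out <- concordance(a, b)
  expect_equal(c(out$n_match, out$n_total), c(0L, 3L))

  a2 <- c("LuminalA", "Unclassified", "BasalLike")
  b2 <- c("LuminalA", "LuminalB", "LuminalB")
  out <- concordance(a2, b2, exclude_unclassified_in = "a")
  expect_equal(c(out$n_match, out$n_total), c(1L, 2L))

  set.seed(3)
  perm <- sample(3)
  expect_equal(concordance(a2[perm], b2[perm], "a"), out)

  expect_error(concordance("Unclassified", "LuminalA", "a"), "no comparable")
  expect_error(concordance(a, b[1:2]), "equal length")
})

test_that("the packaged cell-line table reproduces its printed concordance", {
  t3 <- table3_cell_lines()
  expect_equal(nrow(t3), 68L)
  out <- concordance(t3$pam50_mrna, t3$final_classification,
                     exclude_unclassified_in = "a")
  expect_equal(c(out$n_match, out$n_total), c(34L, 56L))
  expect_equal(out$fraction, 34 / 56, tolerance = 1e-12)
})

test_that("cohort-level subtype calls fall back to centroids only when needed", {
  set.seed(21)
  genes <- paste0("g", 1:30)
  centroids <- matrix(rnorm(60), ncol = 2,
                      dimnames = list(genes, c("LuminalA", "BasalLike")))
  expr <- cbind(S1 = centroids[, 1] + rnorm(30, 0, 0.01),
                S2 = centroids[, 2] + rnorm(30, 0, 0.01))
  rownames(expr) <- genes
  ann <- tibble::tibble(sample_id = c("S1", "S2"),
                        er = c("-", NA), pr = c("-", NA), her2 = c("-", NA))
  calls <- call_subtypes(ann, expr, centroids)
  # S1's markers resolve (triple negative) and override its centroid call
  expect_equal(calls$final_label[calls$sample_id == "S1"], "BasalLike")
  expect_equal(calls$ihc_label[calls$sample_id == "S2"], "Unclassified")
  expect_equal(calls$final_label[calls$sample_id == "S2"], "BasalLike")
})
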