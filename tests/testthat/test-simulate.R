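# Small cohorts keep the unit suite fast; the full-size generator behaviour
# is exercised by the acceptance suite.
small_cfg <- function(...) {
  defaults <- list(n_tumors_per_subtype = 5, n_cells_per_subtype = 2,
                   n_genes = 120, panel_size = 40, n_drivers_per_subtype = 4,
                   n_proteins = 20, coverage_mb = 10)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("one seed yields one cohort, bit for bit", {
  a <- simulate_cohort(small_cfg(seed = 9))
  b <- simulate_cohort(small_cfg(seed = 9))
  expect_identical(a$expr_tumors, b$expr_tumors)
  expect_identical(a$seg_cells, b$seg_cells)
  expect_identical(a$muts_tumors, b$muts_tumors)
  expect_identical(a$prot_cells, b$prot_cells)
  c_ <- simulate_cohort(small_cfg(seed = 10))
  expect_false(identical(a$expr_tumors, c_$expr_tumors))
})

test_that("generated tables satisfy the container invariants", {
  ch <- simulate_cohort(small_cfg(seed = 13))
  expect_silent(validate_segments(ch$seg_tumors))
  expect_silent(validate_segments(ch$seg_cells))
  expect_silent(validate_mutations(ch$muts_tumors))
  expect_identical(merge_intervals(ch$coverage_tumors), ch$coverage_tumors)
  expect_setequal(ch$truth$sample_id,
                  c(colnames(ch$expr_tumors), colnames(ch$expr_cells)))
  expect_false(any(duplicated(rownames(ch$expr_tumors))))
})

test_that("zero expression noise reproduces the centroids exactly", {
  ch <- simulate_cohort(small_cfg(seed = 14, expr_noise_sd = 0,
                                  cell_expr_noise_mult = 1))
  for (s in colnames(ch$expr_tumors)[1:3]) {
    sub <- ch$truth$subtype[ch$truth$sample_id == s]
    expect_identical(unname(ch$expr_tumors[, s]), unname(ch$centroids[, sub]))
  }
})

test_that("a degenerate spectrum propagates through the analyzer", {
  ch <- simulate_cohort(small_cfg(seed = 15,
                                  spectrum_weights = c(0, 0, 0, 0, 0, 1)))
  sp <- mutation_spectrum(filter_somatic_functional(ch$muts_tumors))
  expect_equal(sp$proportion[sp$category == "C>T"], 1)
})

test_that("infeasible coupling targets are rejected", {
  expect_error(small_cfg(protein_r_target = 1), "infeasible")
  expect_error(small_cfg(spectrum_weights = rep(0.2, 6)), "sum to 1")
  expect_error(small_cfg(cell_expr_noise_mult = 0.5))
})

test_that("the sub-seeded sections leave the caller's RNG stream untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(simulate_cohort(small_cfg(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("growing one cohort arm does not change the other samples", {
  small <- simulate_cohort(small_cfg(seed = 16))
  big <- simulate_cohort(small_cfg(seed = 16, n_cells_per_subtype = 3))
  expect_identical(big$expr_tumors, small$expr_tumors)
  expect_identical(big$muts_tumors, small$muts_tumors)
  shared_cells <- colnames(small$expr_cells)
  expect_identical(big$expr_cells[, shared_cells], small$expr_cells)
})

test_that("the planted clone copies its source tumor on every layer", {
  ch <- simulate_cohort(small_cfg(seed = 17, clone_cell = TRUE))
  clone <- ch$truth$sample_id[!is.na(ch$truth$cloned_from)]
  src <- ch$truth$cloned_from[!is.na(ch$truth$cloned_from)]
  expect_length(clone, 1)
  expect_identical(unname(ch$expr_cells[, clone]),
                   unname(ch$expr_tumors[, src]))
  expect_identical(unname(ch$prot_cells[, clone]),
                   unname(ch$prot_tumors[, src]))
  seg_c <- dplyr::filter(ch$seg_cells, sample_id == clone)
  seg_t <- dplyr::filter(ch$seg_tumors, sample_id == src)
  expect_equal(seg_c[c("chrom", "start", "end", "seg_mean")],
               seg_t[c("chrom", "start", "end", "seg_mean")])
  expect_equal(ch$truth$subtype[ch$truth$sample_id == clone],
               ch$truth$subtype[ch$truth$sample_id == src])
})

test_that("a noise-free cohort is classified perfectly", {
  ch <- simulate_cohort(small_cfg(seed = 18, expr_noise_sd = 0,
                                  cell_expr_noise_mult = 1,
                                  marker_missing_rate = 1))
  calls <- call_subtypes(ch$annotations,
                         cbind(ch$expr_tumors, ch$expr_cells), ch$centroids)
  joined <- dplyr::inner_join(calls, ch$truth, by = "sample_id")
  expect_equal(mean(joined$final_label == joined$subtype), 1)
})

test_that("recovery reports catch sample-id mismatches", {
  ch <- simulate_cohort(small_cfg(seed = 19))
  res <- run_cohort_pipeline(ch)
  bad_calls <- dplyr::mutate(res$subtype_calls,
                             sample_id = paste0("X", sample_id))
  expect_error(planted_recovery_report(ch, res$scores, bad_calls),
               "absent from the cohort")
})
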