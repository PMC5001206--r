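mut_row <- function(gene = "G1", sample = "S1", ref = "C", alt = "T",
                    cls = "Missense_Mutation", somatic = TRUE,
                    chrom = "1", pos = 100, ctx = NA_character_) {
  tibble::tibble(sample_id = sample, gene_id = gene, chrom = chrom,
                 position = pos, ref_allele = ref, alt_allele = alt,
                 variant_classification = cls, somatic = somatic,
                 context = ctx)
}

test_that("somatic-functional filtering keeps only protein-affecting calls", {
  muts <- dplyr::bind_rows(
    mut_row(cls = "Silent"),
    mut_row(gene = "G2", pos = 200),
    mut_row(gene = "G3", pos = 300, somatic = FALSE),
    mut_row(gene = "G4", pos = 400, cls = "Intron"),
    mut_row(gene = "G5", pos = 500, cls = "Frame_Shift_Del", alt = "-")
  )
  kept <- filter_somatic_functional(muts)
  expect_equal(sort(kept$gene_id), c("G2", "G5"))

  blacklist <- tibble::tibble(chrom = "1", position = 200)
  kept <- filter_somatic_functional(muts, germline_sites = blacklist)
  expect_equal(kept$gene_id, "G5")
})

test_that("binarization is an indicator, not a count", {
  muts <- dplyr::bind_rows(
    mut_row(), mut_row(pos = 101), mut_row(pos = 102),   # 3 hits, same gene
    mut_row(gene = "G2", sample = "S2", pos = 200)
  )
  b <- binarize_mutations(muts, c("G1", "G2", "G3"), c("S1", "S2"))
  expect_equal(b["G1", "S1"], 1)
  expect_equal(b["G1", "S2"], 0)
  expect_equal(b["G2", "S2"], 1)
  expect_equal(sum(b["G3", ]), 0)

  empty <- binarize_mutations(muts[0, ], c("G1", "G2"), c("S1", "S2"))
  expect_true(all(empty == 0))

  freq <- mutation_frequency(b)
  expect_equal(freq$frequency[freq$gene_id == "G1"], 0.5)
  expect_equal(freq$frequency[freq$gene_id == "G3"], 0)
})

test_that("per-gene frequency reproduces a known cohort fraction", {
  b <- matrix(0, 1, 100, dimnames = list("TP53", paste0("s", 1:100)))
  b[1, 1:31] <- 1
  expect_equal(mutation_frequency(b)$frequency, 0.31)
})

test_that("mutation rate per Mb uses merged covered bases", {
  muts <- dplyr::bind_rows(lapply(1:4, function(i) mut_row(pos = i * 1000)))
  cov <- tibble::tibble(sample_id = "S1", chrom = c("1", "2"),
                        start = c(0, 0), end = c(1.5e6, 5e5))
  out <- mutation_rate_per_mb(muts, cov)
  expect_equal(out$rate_per_mb, 2.0)
  expect_equal(out$covered_bases, 2e6)

  # duplicated coverage listings must not halve the rate
  dup <- dplyr::bind_rows(cov, cov)
  expect_equal(mutation_rate_per_mb(muts, dup)$rate_per_mb, 2.0)
  # splitting an interval changes nothing
  split <- tibble::tibble(sample_id = "S1", chrom = c("1", "1", "2"),
                          start = c(0, 7e5, 0), end = c(7e5, 1.5e6, 5e5))
  expect_equal(mutation_rate_per_mb(muts, split)$rate_per_mb, 2.0)

  none <- mutation_rate_per_mb(muts[0, ], cov)
  expect_equal(none$rate_per_mb, 0)
})

test_that("substitution spectra collapse strands onto six categories", {
  expect_equal(mutation_spectrum(mut_row())$proportion,
               c(0, 0, 0, 0, 0, 1))
  # G>A is C>T read from the other strand
  expect_equal(mutation_spectrum(mut_row(ref = "G", alt = "A"))$proportion,
               c(0, 0, 0, 0, 0, 1))

  hand <- dplyr::bind_rows(
    mut_row(), mut_row(pos = 101),
    mut_row(ref = "G", alt = "C", pos = 102),
    mut_row(ref = "A", alt = "G", pos = 103)
  )
  sp <- mutation_spectrum(hand)
  expect_equal(sp$category, c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T"))
  expect_equal(sp$proportion, c(0, 0.25, 0, 0, 0.25, 0.5))

  indel <- mut_row(alt = "-", cls = "Frame_Shift_Del")
  expect_error(mutation_spectrum(indel), "substitution")
})

test_that("spectra are exactly strand-symmetric and sum to one", {
  set.seed(41)
  for (rep in 1:50) {
    muts <- random_mutations(sample.int(40, 1) + 1)
    sp <- mutation_spectrum(muts)
    expect_equal(sum(sp$proportion), 1, tolerance = 1e-12)
    expect_identical(sp$proportion,
                     mutation_spectrum(revcomp_mutations(muts))$proportion)
  }
})

test_that("context profiles read flanks off the 5-base window", {
  one <- mut_row(ctx = "AACTG")
  prof <- context_profile(one)
  pick <- function(pos, base) {
    prof$proportion[prof$category == "C>T" & prof$position == pos &
                      prof$base == base]
  }
  expect_equal(pick(-2, "A"), 1)
  expect_equal(pick(-1, "A"), 1)
  expect_equal(pick(1, "T"), 1)
  expect_equal(pick(2, "G"), 1)

  # the reverse-complement representation contributes identically
  flipped <- mut_row(ref = "G", alt = "A", ctx = "CAGTT")
  expect_equal(context_profile(flipped), prof)

  set.seed(42)
  many <- random_mutations(30)
  prof <- context_profile(many)
  sums <- dplyr::summarise(dplyr::group_by(prof, category, position),
                           s = sum(proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))

  muts <- dplyr::bind_rows(one, mut_row(pos = 101, ctx = NA))
  expect_warning(context_profile(muts), "without context")
})

test_that("spectrum correlation needs matching, non-constant vectors", {
  a <- c(0.1, 0.2, 0.05, 0.15, 0.2, 0.3)
  expect_equal(spectrum_correlation(a, a), 1)
  expect_lt(spectrum_correlation(a, rev(a)), 1)
  expect_equal(spectrum_correlation(a, rev(a)), oracle_pearson(a, rev(a)),
               tolerance = 1e-12)
  expect_error(spectrum_correlation(a, rep(1 / 6, 6)), "constant")
  expect_error(spectrum_correlation(a, a[1:3]), "dimensions")
})

test_that("binary mutation similarity equals the phi coefficient", {
  genes <- paste0("g", 1:6)
  a <- matrix(c(1, 0, 1, 0, 1, 0), ncol = 1, dimnames = list(genes, "c1"))
  same <- matrix(a, ncol = 1, dimnames = list(genes, "t1"))
  opp <- matrix(1 - a, ncol = 1, dimnames = list(genes, "t2"))
  expect_equal(mutation_similarity(a, same)$r, 1)
  expect_equal(mutation_similarity(a, opp)$r, -1)

  set.seed(43)
  for (rep in 1:30) {
    x <- matrix(rbinom(8, 1, 0.4), ncol = 1,
                dimnames = list(paste0("g", 1:8), "c"))
    y <- matrix(rbinom(8, 1, 0.4), ncol = 1,
                dimnames = list(paste0("g", 1:8), "t"))
    got <- mutation_similarity(x, y)$r
    want <- oracle_phi(x[, 1], y[, 1])
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(mutation_similarity(a, matrix(1, 1, 1, dimnames = list("zz", "t"))),
               "shared gene panel")
})
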