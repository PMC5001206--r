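test_that("fraction genome altered follows the length-weighted definition", {
  seg <- tibble::tibble(
    sample_id = "S1", chrom = "1",
    start = c(1, 101), end = c(100, 400),
    seg_mean = c(0.5, 0.1)
  )
  expect_equal(compute_fga(seg, 0.2)$fga, 100 / 400)

  low <- dplyr::mutate(seg, seg_mean = c(0.1, -0.15))
  expect_equal(compute_fga(low, 0.2)$fga, 0)
  high <- dplyr::mutate(seg, seg_mean = c(0.9, -0.8))
  expect_equal(compute_fga(high, 0.2)$fga, 1)

  expect_error(compute_fga(seg[0, ], 0.2), "empty")
  expect_error(compute_fga(seg, threshold = -1))
})

test_that("FGA matches the per-base oracle and is monotone in the threshold", {
  set.seed(31)
  for (rep in 1:60) {
    seg <- random_segments(sample.int(10, 1))
    for (thr in c(0.1, 0.3, 0.6)) {
      expect_equal(compute_fga(seg, thr)$fga, oracle_fga_perbase(seg, thr),
                   tolerance = 1e-12)
    }
    fgas <- vapply(c(0.05, 0.2, 0.4, 0.8), function(t) compute_fga(seg, t)$fga,
                   numeric(1))
    expect_true(all(diff(fgas) <= 1e-12))
    expect_true(all(fgas >= 0 & fgas <= 1))
  }
})

test_that("splitting a segment changes neither FGA nor gene values", {
  seg <- tibble::tibble(sample_id = "S1", chrom = "1",
                        start = c(1, 1001), end = c(1000, 3000),
                        seg_mean = c(0.45, -0.1))
  split <- tibble::tibble(sample_id = "S1", chrom = "1",
                          start = c(1, 401, 1001), end = c(400, 1000, 3000),
                          seg_mean = c(0.45, 0.45, -0.1))
  expect_equal(compute_fga(split, 0.2)$fga, compute_fga(seg, 0.2)$fga)
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "1",
                          start = c(200, 900), end = c(600, 1400))
  expect_equal(map_segments_to_genes(split, genes),
               map_segments_to_genes(seg, genes))
})

test_that("segment-to-gene mapping is the overlap-weighted mean", {
  seg <- tibble::tibble(sample_id = "S1", chrom = "1",
                        start = c(1, 501), end = c(500, 1000),
                        seg_mean = c(0.2, 0.6))
  genes <- tibble::tibble(
    gene_id = c("inside", "split", "elsewhere"),
    chrom = c("1", "1", "7"),
    start = c(100, 401, 100), end = c(300, 600, 300)
  )
  m <- map_segments_to_genes(seg, genes)
  expect_equal(m["inside", "S1"], 0.2)
  # equal 100-base overlap with each segment
  expect_equal(m["split", "S1"], 0.4)
  expect_true(is.na(m["elsewhere", "S1"]))
})

test_that("segment-to-gene mapping agrees with per-base averaging", {
  set.seed(32)
  for (rep in 1:40) {
    seg <- random_segments(sample.int(10, 1), max_len = 500)
    genes <- tibble::tibble(
      gene_id = paste0("g", 1:5), chrom = "1",
      start = sort(sample.int(max(seg$end), 5))
    )
    genes$end <- genes$start + sample.int(400, 5)
    m <- map_segments_to_genes(seg, genes)
    for (k in 1:5) {
      expect_equal(
        m[genes$gene_id[k], "S1"],
        oracle_gene_value(seg, "1", genes$start[k], genes$end[k]),
        tolerance = 1e-12
      )
    }
  }
})

test_that("copy-number calls use the +/- 0.3 cutoffs", {
  m <- matrix(c(0.31, -0.31, 0, 0.3, -0.3, NA), nrow = 6,
              dimnames = list(paste0("g", 1:6), "S1"))
  calls <- call_cnv(m)
  expect_equal(unname(calls[1:5, 1]),
               c("amplified", "deleted", "neutral", "neutral", "neutral"))
  expect_true(is.na(calls[6, 1]))
})

test_that("alteration frequencies count over samples with calls", {
  calls <- matrix(c("amplified", "neutral", "amplified", "deleted",
                    "neutral", "neutral", "neutral", "neutral",
                    NA, NA, NA, NA),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  freq <- alteration_frequency(calls)
  expect_equal(freq$amp_fraction[freq$gene_id == "gA"], 0.5)
  expect_equal(freq$del_fraction[freq$gene_id == "gA"], 0.25)
  expect_equal(freq$amp_fraction[freq$gene_id == "gB"], 0)
  expect_true(is.na(freq$amp_fraction[freq$gene_id == "gC"]))
})

test_that("top-variable selection ranks by variance with lexicographic ties", {
  m <- rbind(
    gE = c(0, 10, 0, 10),   # var 33.3
    gA = c(1, 2, 1, 2),     # var 1/3
    gC = c(5, 5, 5, 5),     # constant
    gB = c(0, 4, 0, 4),     # var 16/3
    gD = c(2, 3, 2, 3)      # var 1/3, ties with gA
  )
  colnames(m) <- paste0("s", 1:4)
  expect_equal(select_top_variable(m, fraction = 0.4), c("gE", "gB"))
  expect_equal(select_top_variable(m, fraction = 1),
               c("gE", "gB", "gA", "gD", "gC"))
  # brute-force variance ranking agrees
  v <- sort(apply(m, 1, var), decreasing = TRUE)
  expect_equal(select_top_variable(m, fraction = 0.4), names(v)[1:2])
  expect_error(select_top_variable(m, fraction = 0), "fraction")
  expect_equal(select_top_variable(m, n_genes = 3), c("gE", "gB", "gA"))
})

test_that("CNV similarity is Pearson on the selected genes", {
  genes <- paste0("g", 1:6)
  cells <- matrix(c(0.5, -0.2, 0.1, 0.9, -0.6, 0), ncol = 1,
                  dimnames = list(genes, "c1"))
  tumors <- cbind(t1 = cells[, 1], t2 = cells[, 1] + 0.25)
  rownames(tumors) <- genes
  tab <- cnv_similarity(cells, tumors, genes = genes)
  expect_equal(tab$r, c(1, 1), tolerance = 1e-12)

  set.seed(33)
  t3 <- matrix(rnorm(6), ncol = 1, dimnames = list(genes, "t3"))
  tab <- cnv_similarity(cells, t3, genes = genes)
  expect_equal(tab$r, oracle_pearson(cells[, 1], t3[, 1]), tolerance = 1e-12)
})
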