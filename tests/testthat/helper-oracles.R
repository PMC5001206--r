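# Independent brute-force oracles used to pin the semantics of the fast
# implementations. These deliberately share no code with the package.

# Pearson correlation from the raw sum formula.
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Fraction genome altered by literal per-base expansion of the segments.
oracle_fga_perbase <- function(seg, threshold) {
  v <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    rep(seg$seg_mean[i], seg$end[i] - seg$start[i] + 1)
  }))
  mean(abs(v) > threshold)
}

# Per-gene copy-number value by averaging the segment value at every base of
# the gene body (NA where no base is covered).
oracle_gene_value <- function(seg_one_sample, g_chrom, g_start, g_end) {
  vals <- rep(NA_real_, g_end - g_start + 1)
  pos <- g_start:g_end
  for (i in seq_len(nrow(seg_one_sample))) {
    if (seg_one_sample$chrom[i] != g_chrom) next
    inside <- pos >= seg_one_sample$start[i] & pos <= seg_one_sample$end[i]
    vals[inside] <- seg_one_sample$seg_mean[i]
  }
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# Phi coefficient from the closed-form 2x2 contingency expression.
oracle_phi <- function(a, b) {
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

# Naive agglomerative clustering: repeatedly merge the closest pair of
# clusters under the chosen linkage over a distance matrix.
oracle_agglomerate <- function(d, linkage = "average") {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        pair_d <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        lk <- switch(linkage, average = mean(pair_d),
                     complete = max(pair_d), single = min(pair_d))
        if (lk < best_d) { best_d <- lk; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# Canonical signature of a partition (membership vector relabelled in order
# of first appearance) so partitions can be compared across algorithms.
partition_signature <- function(membership) {
  as.integer(factor(membership, levels = unique(membership)))
}

# Random generators for property-style tests (callers seed).
random_segments <- function(n_segments, sample_id = "S1", max_len = 1e4) {
  len <- sample.int(max_len, n_segments, replace = TRUE)
  gap <- sample.int(100, n_segments, replace = TRUE)
  end <- cumsum(len + gap)
  start <- end - len + 1
  tibble::tibble(
    sample_id = sample_id, chrom = "1",
    start = start, end = end,
    seg_mean = round(stats::runif(n_segments, -1, 1), 3)
  )
}

random_mutations <- function(n, sample_id = "S1") {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ctx <- vapply(seq_len(n), function(i) {
    paste0(paste(sample(bases, 2, replace = TRUE), collapse = ""), ref[i],
           paste(sample(bases, 2, replace = TRUE), collapse = ""))
  }, character(1))
  tibble::tibble(
    sample_id = sample_id, gene_id = paste0("g", seq_len(n)), chrom = "1",
    position = seq_len(n) * 10, ref_allele = ref, alt_allele = unname(alt),
    variant_classification = "Missense_Mutation", somatic = TRUE,
    context = ctx
  )
}

revcomp_mutations <- function(muts) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rc <- function(s) vapply(strsplit(comp(s), ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
  muts$ref_allele <- comp(muts$ref_allele)
  muts$alt_allele <- comp(muts$alt_allele)
  muts$context <- rc(muts$context)
  muts
}
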