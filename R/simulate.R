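# Seeded evaluation that never leaks into the caller's RNG stream, plus a
# deterministic sub-seed scheme: every (section, unit) pair of the generator
# draws from its own derived seed, so enlarging one cohort section never
# perturbs the values generated for another.
.seeded <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

.sub_seed <- function(seed, section, unit = 0) {
  (((seed %% 99991) + 1) * 20011 + section * 1000003 + unit) %% 2147483647
}

#' Default autosome lengths (Mb)
#'
#' Twenty-two autosomes with lengths proportional to the human karyotype,
#' rounded to 1 Mb; the recurrent-event priors of the generator
#' (amplification on chromosomes 1 and 8, deletion on 13 and 16) are defined
#' against this model.
#'
#' @returns Named numeric vector of chromosome lengths in Mb.
#' @export
default_chrom_lengths_mb <- function() {
  stats::setNames(
    c(249, 242, 198, 190, 182, 171, 159, 145, 138, 134,
      135, 133, 114, 107, 102, 90, 83, 80, 59, 63, 47, 51),
    as.character(1:22)
  )
}

#' Configuration of the synthetic matched-cohort generator
#'
#' Bundles every tunable of [simulate_cohort()] with validated defaults. The
#' defaults encode the cohort structure the analysis assumes: four intrinsic
#' subtypes with expression centroids separated by five noise standard
#' deviations, recurrent arm-level amplification on chromosomes 1/8 and
#' deletion on 13/16 over a focal-alteration background, a somatic
#' functional mutation rate of 2 per Mb with a C>T-dominated substitution
#' spectrum, cell lines slightly more mutated and more aberrant than tumors,
#' and protein abundance coupled to mRNA at a target correlation of 0.7.
#'
#' @param seed integer seed; one seed fully determines the cohort.
#' @param subtypes subtype labels (>= 2).
#' @param n_tumors_per_subtype,n_cells_per_subtype cohort sizes.
#' @param n_genes total genes on the expression platform.
#' @param n_signature_genes_per_subtype marker genes elevated per subtype.
#' @param expr_baseline_mean,expr_baseline_sd log-scale baseline intensity
#'   distribution shared by all centroids.
#' @param centroid_separation elevation (expression units) of a subtype's
#'   marker genes in its centroid.
#' @param expr_noise_sd per-gene iid Gaussian noise around the centroid.
#' @param cell_expr_noise_mult extra expression-noise multiplier (>= 1) for
#'   cell lines, reflecting culture drift.
#' @param chrom_lengths_mb genome model, see [default_chrom_lengths_mb()].
#' @param n_segments segments per sample (allocated across chromosomes
#'   proportionally to length); the default keeps several segments per
#'   chromosome arm so gene-level profiles are not dominated by a handful
#'   of segment draws.
#' @param baseline_seg_sd segment-mean jitter of unaltered segments.
#' @param focal_alt_prob per-segment probability of a focal alteration.
#' @param arm_event_prob per-sample probability of the recurrent arm-level
#'   event on each designated chromosome; the default models these as
#'   clonal changes present in every sample (their magnitude still varies
#'   per sample).
#' @param amp_chroms,del_chroms chromosomes carrying recurrent gains /
#'   losses.
#' @param arm_effect_range,focal_effect_range uniform magnitude ranges of
#'   arm and focal segment-mean shifts.
#' @param cell_focal_extra_prob additional random-sign, random-chromosome
#'   focal alteration probability for cell lines.
#' @param cell_cnv_noise_sd continuous segment-mean perturbation applied to
#'   every cell-line segment (culture-acquired divergence affects every
#'   line, not only an occasional one).
#' @param mutation_rate_per_mb expected somatic functional mutations per Mb
#'   of covered genome (tumors).
#' @param cell_mutation_rate_mult rate multiplier (>= 1) for cell lines.
#' @param spectrum_weights 6-vector of substitution-category weights (order
#'   of [spectrum_categories()]); must sum to 1.
#' @param panel_size genes in the mutation panel.
#' @param n_drivers_per_subtype panel genes acting as enriched drivers per
#'   subtype.
#' @param driver_mutation_prob probability that a mutation hits one of its
#'   sample's subtype drivers rather than the background.
#' @param silent_fraction,germline_fraction extra non-functional / germline
#'   records generated per functional one (exercise the somatic-functional
#'   filter; they do not count toward `mutation_rate_per_mb`).
#' @param coverage_mb total sequencing footprint per sample (Mb).
#' @param n_proteins proteins on the RPPA panel (half mapped to signature
#'   genes, half to background genes).
#' @param cell_protein_noise_mult extra protein measurement-noise
#'   multiplier (>= 1) for cell lines.
#' @param protein_r_target expected Pearson correlation between a gene's
#'   mRNA and its protein, in `[0, 1)`.
#' @param marker_missing_rate fraction of samples with unknown ER/PR/HER2
#'   status (exercises the centroid fallback).
#' @param clone_cell when `TRUE`, the first cell line is an exact copy of
#'   the first tumor on every layer — a planted best-match whose top rank
#'   the scoring stage should recover.
#' @returns A validated `portrait_sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       subtypes = c("LuminalA", "LuminalB", "HER2amp", "BasalLike"),
                       n_tumors_per_subtype = 40,
                       n_cells_per_subtype = 8,
                       n_genes = 500,
                       n_signature_genes_per_subtype = 10,
                       expr_baseline_mean = 8,
                       expr_baseline_sd = 1,
                       centroid_separation = 5,
                       expr_noise_sd = 1,
                       cell_expr_noise_mult = 2.5,
                       chrom_lengths_mb = default_chrom_lengths_mb(),
                       n_segments = 120,
                       baseline_seg_sd = 0.05,
                       focal_alt_prob = 0.10,
                       arm_event_prob = 1,
                       amp_chroms = c("1", "8"),
                       del_chroms = c("13", "16"),
                       arm_effect_range = c(0.3, 1.2),
                       focal_effect_range = c(0.4, 1.0),
                       cell_focal_extra_prob = 0.15,
                       cell_cnv_noise_sd = 0.4,
                       mutation_rate_per_mb = 2,
                       cell_mutation_rate_mult = 1.5,
                       spectrum_weights = c(0.05, 0.15, 0.05, 0.10, 0.20, 0.45),
                       panel_size = 60,
                       n_drivers_per_subtype = 6,
                       driver_mutation_prob = 0.3,
                       silent_fraction = 0.3,
                       germline_fraction = 0.15,
                       coverage_mb = 30,
                       n_proteins = 50,
                       cell_protein_noise_mult = 1.5,
                       protein_r_target = 0.7,
                       marker_missing_rate = 0.25,
                       clone_cell = FALSE) {
  cfg <- as.list(environment())
  stopifnot(
    length(cfg$subtypes) >= 2,
    cfg$n_tumors_per_subtype >= 1, cfg$n_cells_per_subtype >= 1,
    cfg$n_genes >= cfg$n_signature_genes_per_subtype * length(cfg$subtypes),
    cfg$expr_noise_sd >= 0, cfg$cell_expr_noise_mult >= 1,
    cfg$mutation_rate_per_mb >= 0, cfg$cell_mutation_rate_mult >= 1,
    length(cfg$spectrum_weights) == 6, all(cfg$spectrum_weights >= 0),
    cfg$panel_size >= cfg$n_drivers_per_subtype * length(cfg$subtypes),
    cfg$driver_mutation_prob >= 0, cfg$driver_mutation_prob <= 1,
    cfg$coverage_mb > 0, cfg$cell_cnv_noise_sd >= 0,
    cfg$cell_protein_noise_mult >= 1,
    cfg$marker_missing_rate >= 0,
    cfg$marker_missing_rate <= 1
  )
  if (abs(sum(cfg$spectrum_weights) - 1) > 1e-8) {
    stop("spectrum weights must sum to 1", call. = FALSE)
  }
  if (cfg$protein_r_target < 0 || cfg$protein_r_target >= 1) {
    stop("protein_r_target must lie in [0, 1): perfect coupling is infeasible under measurement noise",
         call. = FALSE)
  }
  structure(cfg, class = "portrait_sim_config")
}

# Gene model: genes spread evenly across chromosomes (proportional counts),
# each 100 kb wide, 1-based inclusive coordinates.
.sim_gene_models <- function(cfg) {
  len_mb <- cfg$chrom_lengths_mb
  counts <- stats::setNames(pmax(1L, round(cfg$n_genes * len_mb / sum(len_mb))),
                            names(len_mb))
  # adjust to hit n_genes exactly on the largest chromosomes
  while (sum(counts) != cfg$n_genes) {
    i <- if (sum(counts) > cfg$n_genes) which.max(counts) else which.min(counts)
    counts[i] <- counts[i] + sign(cfg$n_genes - sum(counts))
  }
  purrr::imap_dfr(as.list(counts), function(k, chrom) {
    L <- len_mb[[chrom]] * 1e6
    start <- floor((seq_len(k) - 0.5) / k * L) + 1
    tibble::tibble(chrom = chrom, start = start,
                   end = pmin(start + 1e5 - 1, L))
  }) %>%
    dplyr::mutate(gene_id = sprintf("g%04d", dplyr::row_number())) %>%
    dplyr::select("gene_id", "chrom", "start", "end")
}

.sim_coverage_template <- function(cfg) {
  len_mb <- cfg$chrom_lengths_mb
  cov_len <- round(len_mb * 1e6 * cfg$coverage_mb / sum(len_mb))
  tibble::tibble(chrom = names(len_mb), start = 0, end = as.numeric(cov_len))
}

.sim_segments_one <- function(cfg, sample_id, subtype, is_cell, seed) {
  .seeded(seed, {
    len_mb <- cfg$chrom_lengths_mb
    n_per <- stats::setNames(pmax(1L, round(cfg$n_segments * len_mb / sum(len_mb))),
                             names(len_mb))
    acc <- vector("list", length(n_per))
    for (ci in seq_along(n_per)) {
      chrom <- names(n_per)[ci]
      k <- n_per[[ci]]
      L <- len_mb[[chrom]] * 1e6
      brk <- if (k > 1) sort(sample.int(L - 1, k - 1)) else integer(0)
      start <- c(1, brk + 1)
      end <- c(brk, L)
      mean_ <- stats::rnorm(k, 0, cfg$baseline_seg_sd)
      # recurrent arm-level event on designated chromosomes, with regional
      # (per-segment) magnitude variation along the gained or lost arm
      if (chrom %in% cfg$amp_chroms && stats::runif(1) < cfg$arm_event_prob) {
        mean_ <- mean_ + stats::runif(k, cfg$arm_effect_range[1], cfg$arm_effect_range[2])
      }
      if (chrom %in% cfg$del_chroms && stats::runif(1) < cfg$arm_event_prob) {
        mean_ <- mean_ - stats::runif(k, cfg$arm_effect_range[1], cfg$arm_effect_range[2])
      }
      # focal alterations: recurrent sign on designated chromosomes
      hit <- stats::runif(k) < cfg$focal_alt_prob
      sgn <- if (chrom %in% cfg$amp_chroms) rep(1, k)
             else if (chrom %in% cfg$del_chroms) rep(-1, k)
             else sample(c(-1, 1), k, replace = TRUE)
      eff <- stats::runif(k, cfg$focal_effect_range[1], cfg$focal_effect_range[2])
      mean_ <- mean_ + hit * sgn * eff
      if (is_cell) {
        # culture-acquired divergence: occasional extra focal events plus a
        # continuous perturbation of every segment mean
        if (cfg$cell_focal_extra_prob > 0) {
          hit2 <- stats::runif(k) < cfg$cell_focal_extra_prob
          eff2 <- stats::runif(k, cfg$focal_effect_range[1], cfg$focal_effect_range[2])
          mean_ <- mean_ + hit2 * sample(c(-1, 1), k, replace = TRUE) * eff2
        }
        if (cfg$cell_cnv_noise_sd > 0) {
          mean_ <- mean_ + stats::rnorm(k, 0, cfg$cell_cnv_noise_sd)
        }
      }
      acc[[ci]] <- list(chrom = rep(chrom, k), start = start,
                        end = as.numeric(end), seg_mean = mean_)
    }
    tibble::tibble(
      sample_id = sample_id,
      chrom = unlist(lapply(acc, `[[`, "chrom"), use.names = FALSE),
      start = unlist(lapply(acc, `[[`, "start"), use.names = FALSE),
      end = unlist(lapply(acc, `[[`, "end"), use.names = FALSE),
      seg_mean = unlist(lapply(acc, `[[`, "seg_mean"), use.names = FALSE)
    )
  })
}

.sim_mutations_one <- function(cfg, sample_id, subtype, is_cell, seed,
                               genes, panel, drivers, cov_bases) {
  .seeded(seed, {
    rate <- cfg$mutation_rate_per_mb *
      (if (is_cell) cfg$cell_mutation_rate_mult else 1)
    n_func <- stats::rpois(1, rate * cov_bases / 1e6)
    n_sil <- stats::rpois(1, cfg$silent_fraction * rate * cov_bases / 1e6)
    n_germ <- stats::rpois(1, cfg$germline_fraction * rate * cov_bases / 1e6)
    n_all <- n_func + n_sil + n_germ
    if (n_all == 0) {
      return(tibble::tibble(
        sample_id = character(), gene_id = character(), chrom = character(),
        position = numeric(), ref_allele = character(), alt_allele = character(),
        variant_classification = character(), somatic = logical(),
        context = character()
      ))
    }
    my_drivers <- drivers[[subtype]]
    is_driver <- stats::runif(n_all) < cfg$driver_mutation_prob
    gene_idx <- integer(n_all)
    chrom <- character(n_all)
    position <- numeric(n_all)
    # driver hits land inside a subtype driver gene
    nd <- sum(is_driver)
    if (nd > 0) {
      gi <- match(sample(my_drivers, nd, replace = TRUE), genes$gene_id)
      gene_idx[is_driver] <- gi
      chrom[is_driver] <- genes$chrom[gi]
      position[is_driver] <- genes$start[gi] +
        floor(stats::runif(nd) * (genes$end[gi] - genes$start[gi] + 1))
    }
    # background hits land uniformly in the covered genome
    nb <- n_all - nd
    if (nb > 0) {
      cov <- .sim_coverage_template(cfg)
      ci <- sample.int(nrow(cov), nb, replace = TRUE,
                       prob = cov$end - cov$start)
      bg_chrom <- cov$chrom[ci]
      bg_pos <- cov$start[ci] + floor(stats::runif(nb) * (cov$end[ci] - cov$start[ci])) + 1
      chrom[!is_driver] <- bg_chrom
      position[!is_driver] <- bg_pos
      # gene assignment by containment (genes are sorted and disjoint per
      # chromosome); intergenic hits keep a placeholder id
      bg_gene <- sprintf("intergenic_%s", bg_chrom)
      for (ch in unique(bg_chrom)) {
        sel <- bg_chrom == ch
        g <- genes[genes$chrom == ch, ]
        if (nrow(g) == 0) next
        idx <- findInterval(bg_pos[sel], g$start)
        ok <- idx >= 1 & bg_pos[sel] <= g$end[pmax(idx, 1)]
        bg_gene[sel][ok] <- g$gene_id[idx[ok]]
      }
      gene_idx[!is_driver] <- NA_integer_
      gene_id <- character(n_all)
      gene_id[is_driver] <- genes$gene_id[gene_idx[is_driver]]
      gene_id[!is_driver] <- bg_gene
    } else {
      gene_id <- genes$gene_id[gene_idx]
    }
    # substitution category, strand representation and context
    cat_i <- sample.int(6, n_all, replace = TRUE, prob = cfg$spectrum_weights)
    cats <- spectrum_categories()[cat_i]
    ref <- substr(cats, 1, 1)
    alt <- substr(cats, 3, 3)
    flip <- stats::runif(n_all) < 0.5
    ref[flip] <- .revcomp_base(ref[flip])
    alt[flip] <- .revcomp_base(alt[flip])
    flank <- matrix(sample(c("A", "C", "G", "T"), 4 * n_all, replace = TRUE),
                    ncol = 4)
    context <- paste0(flank[, 1], flank[, 2], ref, flank[, 3], flank[, 4])
    cls <- c(rep("Missense_Mutation", n_func), rep("Silent", n_sil),
             rep("Missense_Mutation", n_germ))
    somatic <- c(rep(TRUE, n_func + n_sil), rep(FALSE, n_germ))
    validate_mutations(tibble::tibble(
      sample_id = sample_id, gene_id = gene_id, chrom = chrom,
      position = position, ref_allele = ref, alt_allele = alt,
      variant_classification = cls, somatic = somatic, context = context
    ))
  })
}

#' Simulate a matched tumor / cell-line multi-omic cohort
#'
#' Generates the full input set of the comparison pipeline with known
#' ground truth: subtype-structured expression (centroid plus iid Gaussian
#' noise), piecewise-constant copy-number segments with recurrent arm-level
#' gains/losses and focal alterations, somatic mutations with configurable
#' rate and substitution spectrum plus silent and germline decoys, per-sample
#' coverage intervals, protein abundance coupled to mRNA at a target
#' correlation, and marker annotations with a configurable missingness rate.
#' Cell lines differ from tumors by extra expression noise, extra random
#' aberrations, and a higher mutation rate. The output is fully determined
#' by `config$seed`; each sample draws from its own derived seed, so growing
#' one cohort arm never changes the other samples.
#'
#' @param config a `portrait_sim_config`, see [sim_config()].
#' @returns A `portrait_cohort` list with elements `expr_tumors`,
#'   `expr_cells`, `seg_tumors`, `seg_cells`, `muts_tumors`, `muts_cells`,
#'   `coverage_tumors`, `coverage_cells`, `prot_tumors`, `prot_cells`,
#'   `centroids`, `gene_models`, `panel`, `protein_mapping`, `annotations`,
#'   `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "portrait_sim_config"))
  cfg <- config
  seed <- cfg$seed
  S <- length(cfg$subtypes)
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  genes <- .sim_gene_models(cfg)
  panel <- genes$gene_id[seq_len(cfg$panel_size)]
  drivers <- stats::setNames(lapply(seq_len(S), function(k) {
    panel[((k - 1) * cfg$n_drivers_per_subtype + 1):(k * cfg$n_drivers_per_subtype)]
  }), cfg$subtypes)

  # section 1: subtype centroids (shared baseline + marker-block elevation)
  baseline <- .seeded(.sub_seed(seed, 1),
                      stats::rnorm(cfg$n_genes, cfg$expr_baseline_mean,
                                   cfg$expr_baseline_sd))
  centroids <- matrix(baseline, nrow = cfg$n_genes, ncol = S,
                      dimnames = list(gene_ids, cfg$subtypes))
  nsig <- cfg$n_signature_genes_per_subtype
  for (k in seq_len(S)) {
    block <- ((k - 1) * nsig + 1):(k * nsig)
    centroids[block, k] <- centroids[block, k] + cfg$centroid_separation
  }
  signature_genes <- gene_ids[seq_len(S * nsig)]

  # sample ids and RNG units are keyed by (role, subtype, within-subtype
  # index), so growing one cohort arm never changes the other samples
  truth <- dplyr::bind_rows(
    tidyr::expand_grid(subtype = cfg$subtypes,
                       i = seq_len(cfg$n_tumors_per_subtype)) %>%
      dplyr::mutate(role = "tumor"),
    tidyr::expand_grid(subtype = cfg$subtypes,
                       i = seq_len(cfg$n_cells_per_subtype)) %>%
      dplyr::mutate(role = "cell")
  ) %>%
    dplyr::mutate(
      sample_id = sprintf("%s_%s_%03d",
                          ifelse(.data$role == "tumor", "T", "C"),
                          .data$subtype, .data$i),
      unit = match(.data$subtype, cfg$subtypes) * 1000 + .data$i
    ) %>%
    dplyr::select("sample_id", "role", "subtype", "unit") %>%
    dplyr::mutate(cloned_from = NA_character_)

  tum <- dplyr::filter(truth, .data$role == "tumor")
  cel <- dplyr::filter(truth, .data$role == "cell")

  # section 2/3: expression (tumors, cells)
  sim_expr <- function(info, sd_mult, section) {
    m <- vapply(seq_len(nrow(info)), function(i) {
      .seeded(.sub_seed(seed, section, info$unit[i]), {
        centroids[, info$subtype[i]] +
          stats::rnorm(cfg$n_genes, 0, cfg$expr_noise_sd * sd_mult)
      })
    }, numeric(cfg$n_genes))
    dimnames(m) <- list(gene_ids, info$sample_id)
    m
  }
  expr_tumors <- sim_expr(tum, 1, 2)
  expr_cells <- sim_expr(cel, cfg$cell_expr_noise_mult, 3)

  # section 4/5: copy-number segments
  seg_tumors <- purrr::map_dfr(seq_len(nrow(tum)), function(i) {
    .sim_segments_one(cfg, tum$sample_id[i], tum$subtype[i], FALSE,
                      .sub_seed(seed, 4, tum$unit[i]))
  })
  seg_cells <- purrr::map_dfr(seq_len(nrow(cel)), function(i) {
    .sim_segments_one(cfg, cel$sample_id[i], cel$subtype[i], TRUE,
                      .sub_seed(seed, 5, cel$unit[i]))
  })

  # coverage: identical template per sample (exome-like footprint)
  cov_template <- .sim_coverage_template(cfg)
  cov_bases <- sum(cov_template$end - cov_template$start)
  mk_cov <- function(ids) {
    tidyr::expand_grid(sample_id = ids, cov_template) %>%
      dplyr::select("sample_id", "chrom", "start", "end") %>%
      merge_intervals()
  }
  coverage_tumors <- mk_cov(tum$sample_id)
  coverage_cells <- mk_cov(cel$sample_id)

  # section 6/7: mutations
  muts_tumors <- purrr::map_dfr(seq_len(nrow(tum)), function(i) {
    .sim_mutations_one(cfg, tum$sample_id[i], tum$subtype[i], FALSE,
                       .sub_seed(seed, 6, tum$unit[i]), genes, panel, drivers, cov_bases)
  })
  muts_cells <- purrr::map_dfr(seq_len(nrow(cel)), function(i) {
    .sim_mutations_one(cfg, cel$sample_id[i], cel$subtype[i], TRUE,
                       .sub_seed(seed, 7, cel$unit[i]), genes, panel, drivers, cov_bases)
  })

  # section 8: proteins coupled to mRNA. The panel mixes subtype-signature
  # genes with background genes, as antibody panels do; background proteins
  # carry the shared abundance baseline that keeps cross-subtype pairs
  # informative.
  n_prot <- cfg$n_proteins
  n_sig_prot <- min(length(signature_genes), ceiling(n_prot / 2))
  sig_take <- signature_genes[unique(round(seq(1, length(signature_genes),
                                               length.out = n_sig_prot)))]
  background <- setdiff(gene_ids, signature_genes)
  prot_genes <- c(sig_take, background[seq_len(n_prot - length(sig_take))])
  mapping <- tibble::tibble(gene_id = prot_genes, probe_id = prot_genes,
                            protein_id = paste0("p_", prot_genes))
  # protein = mRNA + per-gene Gaussian noise whose sd is calibrated, within
  # each cohort, so the expected Pearson correlation between a gene's mRNA
  # and its protein equals the coupling target; the affine form keeps the
  # shared abundance baseline in the protein profiles. Cell-line RPPA
  # measurements carry an extra noise multiplier.
  r <- cfg$protein_r_target
  couple <- function(expr_m, info, noise_mult, section) {
    x <- expr_m[prot_genes, , drop = FALSE]
    noise_sd <- apply(x, 1, stats::sd) * sqrt(1 / r^2 - 1) * noise_mult
    eps <- vapply(seq_len(nrow(info)), function(i) {
      .seeded(.sub_seed(seed, section, info$unit[i]),
              stats::rnorm(length(prot_genes)))
    }, numeric(length(prot_genes)))
    p <- x + noise_sd * eps
    rownames(p) <- mapping$protein_id
    p
  }
  prot_tumors <- couple(expr_tumors, tum, 1, 8)
  prot_cells <- couple(expr_cells, cel, cfg$cell_protein_noise_mult, 10)

  # section 9: marker annotations consistent with the planted subtype,
  # a fraction left unknown to exercise the centroid fallback
  marker_of <- function(subtype) {
    switch(subtype,
      LuminalA = c("+", "+", "-"), LuminalB = c("+", "+", "+"),
      HER2amp = c("-", "-", "+"), BasalLike = c("-", "-", "-"),
      c(NA, NA, NA)
    )
  }
  mk <- t(vapply(truth$subtype, marker_of, character(3)))
  missing_mask <- vapply(seq_len(nrow(truth)), function(i) {
    .seeded(.sub_seed(seed, 9, truth$unit[i] + 5000 * (truth$role[i] == "cell")),
            stats::runif(1) < cfg$marker_missing_rate)
  }, logical(1))
  mk[missing_mask, ] <- NA_character_
  annotations <- tibble::tibble(
    sample_id = truth$sample_id,
    er = mk[, 1], pr = mk[, 2], her2 = mk[, 3]
  )

  truth$unit <- NULL
  tum$unit <- NULL
  cel$unit <- NULL

  cohort <- list(
    expr_tumors = expr_tumors, expr_cells = expr_cells,
    seg_tumors = seg_tumors, seg_cells = seg_cells,
    muts_tumors = muts_tumors, muts_cells = muts_cells,
    coverage_tumors = coverage_tumors, coverage_cells = coverage_cells,
    prot_tumors = prot_tumors, prot_cells = prot_cells,
    centroids = centroids, gene_models = genes, panel = panel,
    protein_mapping = mapping, annotations = annotations,
    truth = truth, config = cfg
  )

  if (cfg$clone_cell) cohort <- .plant_clone(cohort)
  class(cohort) <- "portrait_cohort"
  cohort
}

# Replace the first cell line with an exact copy of the first tumor on every
# layer: the planted maximal-similarity cell.
.plant_clone <- function(cohort) {
  src <- cohort$truth$sample_id[cohort$truth$role == "tumor"][1]
  dst <- cohort$truth$sample_id[cohort$truth$role == "cell"][1]
  cohort$expr_cells[, dst] <- cohort$expr_tumors[, src]
  cohort$prot_cells[, dst] <- cohort$prot_tumors[, src]
  cohort$seg_cells <- dplyr::bind_rows(
    dplyr::filter(cohort$seg_cells, .data$sample_id != dst),
    dplyr::mutate(dplyr::filter(cohort$seg_tumors, .data$sample_id == src),
                  sample_id = dst)
  )
  cohort$muts_cells <- dplyr::bind_rows(
    dplyr::filter(cohort$muts_cells, .data$sample_id != dst),
    dplyr::mutate(dplyr::filter(cohort$muts_tumors, .data$sample_id == src),
                  sample_id = dst)
  )
  src_sub <- cohort$truth$subtype[cohort$truth$sample_id == src]
  cohort$truth$subtype[cohort$truth$sample_id == dst] <- src_sub
  cohort$truth$cloned_from[cohort$truth$sample_id == dst] <- src
  src_ann <- cohort$annotations[cohort$annotations$sample_id == src, ]
  cohort$annotations[cohort$annotations$sample_id == dst,
                     c("er", "pr", "her2")] <- src_ann[, c("er", "pr", "her2")]
  cohort
}

#' @export
print.portrait_cohort <- function(x, ...) {
  n_t <- sum(x$truth$role == "tumor")
  n_c <- sum(x$truth$role == "cell")
  cat(sprintf(
    "Synthetic matched cohort: %d tumors, %d cell lines, %d subtypes\n%d genes (expression), %d panel genes (mutation), %d proteins\nseed %d%s\n",
    n_t, n_c, length(unique(x$truth$subtype)), nrow(x$expr_tumors),
    length(x$panel), nrow(x$prot_tumors), x$config$seed,
    if (any(!is.na(x$truth$cloned_from))) "; planted clone present" else ""
  ))
  invisible(x)
}

#' Recovery of planted cohort structure by the pipeline
#'
#' Given a simulated cohort and the pipeline's outputs on it, reports how
#' well the analysis recovered the planted truth: (i) subtype-call accuracy
#' against the planted subtypes, (ii) the fraction of cell lines whose
#' top-correlated tumor (expression layer) shares their planted subtype, and
#' (iii) whether the planted clone — when present — holds rank 1 in the
#' score table.
#'
#' @param cohort `portrait_cohort`.
#' @param scores `portrait_scores` table from [rank_cell_lines()].
#' @param subtype_calls tibble from [call_subtypes()] covering the cohort's
#'   samples.
#' @param expr_cor optional expression correlation table (recomputed from
#'   the cohort if omitted).
#' @returns One-row tibble with `subtype_accuracy`, `top_match_fraction`,
#'   `clone_present`, `clone_rank`.
#' @export
planted_recovery_report <- function(cohort, scores, subtype_calls,
                                    expr_cor = NULL) {
  stopifnot(inherits(cohort, "portrait_cohort"))
  truth <- cohort$truth
  if (!all(subtype_calls$sample_id %in% truth$sample_id)) {
    stop("subtype calls contain sample ids absent from the cohort",
         call. = FALSE)
  }
  joined <- dplyr::inner_join(subtype_calls, truth, by = "sample_id")
  acc <- mean(joined$final_label == joined$subtype)

  if (is.null(expr_cor)) {
    expr_cor <- pairwise_correlation(cohort$expr_cells, cohort$expr_tumors,
                                     layer = "expr")
  }
  lab <- stats::setNames(truth$subtype, truth$sample_id)
  top <- expr_cor %>%
    dplyr::filter(!is.na(.data$r)) %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::slice_max(.data$r, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  top_match <- mean(lab[top$cell_id] == lab[top$tumor_id])

  clone <- truth$sample_id[!is.na(truth$cloned_from)]
  clone_rank <- NA_integer_
  if (length(clone) == 1) {
    if (!clone %in% scores$cell_id) {
      stop("planted clone missing from the score table", call. = FALSE)
    }
    clone_rank <- scores$rank[scores$cell_id == clone]
  }
  tibble::tibble(
    subtype_accuracy = acc,
    top_match_fraction = top_match,
    clone_present = length(clone) == 1,
    clone_rank = clone_rank
  )
}
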