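#' Run the four-layer comparison on an in-memory cohort
#'
#' Executes the full analysis on a `portrait_cohort` (or any list with the
#' same elements): subtype assignment, the four layer similarities —
#' expression (A), copy number (B), mutation (C), protein (D) — and the
#' combined suitability score ranking the cell lines. Layers whose inputs
#' are absent from the cohort are skipped and their component left missing.
#'
#' @param cohort `portrait_cohort` or compatible list; see
#'   [simulate_cohort()] for the element names.
#' @param fga_t_tumor,fga_t_cell segment-mean thresholds for the
#'   fraction-genome-altered summaries (defaults 0.2 / 0.3: cell-line
#'   profiles are noisier, so their cutoff is stricter).
#' @param top_fraction fraction of pooled-variance-ranked genes entering the
#'   copy-number correlation.
#' @param subtype_match when `TRUE`, the expression and protein components
#'   average only over tumors sharing each cell line's subtype.
#' @param policy score policy, see [total_score()].
#' @returns A `portrait_result` list: `subtype_calls`, per-layer
#'   correlation tables (`expr_cor`, `cnv_cor`, `mut_cor`, `prot_cor`),
#'   `components`, `scores`, plus diagnostics (`fga`, `mutation_rates`,
#'   `spectra`).
#' @export
run_cohort_pipeline <- function(cohort,
                                fga_t_tumor = 0.2, fga_t_cell = 0.3,
                                top_fraction = 0.10,
                                subtype_match = FALSE,
                                policy = c("require_all", "available_mean")) {
  policy <- match.arg(policy)
  has <- function(...) all(vapply(list(...), function(k) {
    !is.null(cohort[[k]]) &&
      (is.matrix(cohort[[k]]) || nrow(cohort[[k]]) > 0)
  }, logical(1)))

  # subtype assignment over all samples (markers first, centroids fallback)
  expr_all <- NULL
  if (has("expr_tumors", "expr_cells")) {
    expr_all <- cbind(cohort$expr_tumors, cohort$expr_cells)
  }
  ann <- cohort$annotations %||%
    tibble::tibble(sample_id = character(), er = character(),
                   pr = character(), her2 = character())
  calls <- call_subtypes(ann, expr = expr_all, centroids = cohort$centroids)
  subtype_map <- dplyr::select(calls, "sample_id", "final_label")

  restrict <- if (subtype_match) subtype_map else NULL
  components <- NULL
  result <- list(subtype_calls = calls)

  add_component <- function(components, agg, name) {
    agg <- dplyr::select(agg, "cell_id", !!name := "mean_r")
    if (is.null(components)) agg
    else dplyr::full_join(components, agg, by = "cell_id")
  }

  if (has("expr_tumors", "expr_cells")) {
    result$expr_cor <- pairwise_correlation(cohort$expr_cells,
                                            cohort$expr_tumors, layer = "expr")
    components <- add_component(components,
                                aggregate_by_cell(result$expr_cor, restrict),
                                "expr")
  }

  if (has("seg_tumors", "seg_cells") && !is.null(cohort$gene_models)) {
    cnv_t <- map_segments_to_genes(cohort$seg_tumors, cohort$gene_models)
    cnv_c <- map_segments_to_genes(cohort$seg_cells, cohort$gene_models)
    result$cnv_cor <- cnv_similarity(cnv_c, cnv_t, top_fraction = top_fraction)
    components <- add_component(components,
                                aggregate_by_cell(result$cnv_cor, restrict),
                                "cnv")
    result$fga <- dplyr::bind_rows(
      dplyr::mutate(compute_fga(cohort$seg_tumors, fga_t_tumor), role = "tumor"),
      dplyr::mutate(compute_fga(cohort$seg_cells, fga_t_cell), role = "cell")
    )
  }

  if (has("muts_tumors", "muts_cells") && !is.null(cohort$panel)) {
    f_t <- filter_somatic_functional(cohort$muts_tumors)
    f_c <- filter_somatic_functional(cohort$muts_cells)
    tum_ids <- unique(cohort$coverage_tumors$sample_id) %||%
      unique(cohort$muts_tumors$sample_id)
    cel_ids <- unique(cohort$coverage_cells$sample_id) %||%
      unique(cohort$muts_cells$sample_id)
    b_t <- binarize_mutations(f_t, cohort$panel, tum_ids)
    b_c <- binarize_mutations(f_c, cohort$panel, cel_ids)
    result$mut_cor <- mutation_similarity(b_c, b_t)
    components <- add_component(components,
                                aggregate_by_cell(result$mut_cor, restrict),
                                "mut")
    if (has("coverage_tumors", "coverage_cells")) {
      result$mutation_rates <- dplyr::bind_rows(
        dplyr::mutate(mutation_rate_per_mb(f_t, cohort$coverage_tumors),
                      role = "tumor"),
        dplyr::mutate(mutation_rate_per_mb(f_c, cohort$coverage_cells),
                      role = "cell")
      )
    }
    result$spectra <- dplyr::bind_rows(
      dplyr::mutate(mutation_spectrum(f_t), role = "tumor"),
      dplyr::mutate(mutation_spectrum(f_c), role = "cell")
    )
  }

  if (has("prot_tumors", "prot_cells")) {
    result$prot_cor <- protein_similarity(cohort$prot_cells,
                                          cohort$prot_tumors,
                                          subtype_map = restrict)
    components <- add_component(components,
                                aggregate_by_cell(result$prot_cor, NULL),
                                "prot")
  }

  if (is.null(components)) {
    stop("no layer inputs present in the cohort", call. = FALSE)
  }
  for (k in c("expr", "cnv", "mut", "prot")) {
    if (!k %in% names(components)) components[[k]] <- NA_real_
  }
  result$components <- components
  result$scores <- rank_cell_lines(components, policy = policy)
  class(result) <- "portrait_result"
  result
}

#' @export
print.portrait_result <- function(x, ...) {
  layers <- intersect(c("expr_cor", "cnv_cor", "mut_cor", "prot_cor"), names(x))
  cat(sprintf("Four-layer cell-line/tumor comparison: %d cell line(s), layers: %s\n",
              nrow(x$scores), paste(sub("_cor$", "", layers), collapse = ", ")))
  print(utils::head(tidy(x$scores), 5))
  invisible(x)
}

#' Write a cohort's tables to standard flat files
#'
#' Emits the SEG/MAF/BED/TSV files that [run_pipeline()] consumes, one file
#' per cohort element, into `dir`.
#'
#' @param cohort `portrait_cohort`.
#' @param dir output directory (created if needed).
#' @returns Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_matrix(cohort$expr_tumors, p("expr_tumors.tsv"), id_col = "gene_id")
  write_matrix(cohort$expr_cells, p("expr_cells.tsv"), id_col = "gene_id")
  write_seg(cohort$seg_tumors, p("tumors.seg"))
  write_seg(cohort$seg_cells, p("cells.seg"))
  write_maf(cohort$muts_tumors, p("tumors.maf"))
  write_maf(cohort$muts_cells, p("cells.maf"))
  write_bed_coverage(cohort$coverage_tumors, p("coverage_tumors.bed"))
  write_bed_coverage(cohort$coverage_cells, p("coverage_cells.bed"))
  write_matrix(cohort$prot_tumors, p("prot_tumors.tsv"), id_col = "protein_id")
  write_matrix(cohort$prot_cells, p("prot_cells.tsv"), id_col = "protein_id")
  write_matrix(cohort$centroids, p("centroids.tsv"), id_col = "gene_id")
  readr::write_tsv(cohort$gene_models, p("gene_models.tsv"), progress = FALSE)
  readr::write_lines(cohort$panel, p("panel.txt"))
  readr::write_tsv(cohort$annotations, p("annotations.tsv"), na = "",
                   progress = FALSE)
  readr::write_tsv(cohort$truth, p("truth.tsv"), na = "", progress = FALSE)
  files <- list.files(dir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}

#' Read a cohort back from a directory of flat files
#'
#' Inverse of [write_cohort()] for the analysis inputs (the truth table is
#' read too when present, so recovery reports still work).
#'
#' @param dir directory written by [write_cohort()].
#' @returns A `portrait_cohort`-compatible list.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  cohort <- list(
    expr_tumors = read_matrix(p("expr_tumors.tsv")),
    expr_cells = read_matrix(p("expr_cells.tsv")),
    seg_tumors = read_seg(p("tumors.seg")),
    seg_cells = read_seg(p("cells.seg")),
    muts_tumors = read_maf(p("tumors.maf")),
    muts_cells = read_maf(p("cells.maf")),
    coverage_tumors = read_bed_coverage(p("coverage_tumors.bed")),
    coverage_cells = read_bed_coverage(p("coverage_cells.bed")),
    prot_tumors = read_matrix(p("prot_tumors.tsv")),
    prot_cells = read_matrix(p("prot_cells.tsv")),
    centroids = read_matrix(p("centroids.tsv")),
    gene_models = readr::read_tsv(p("gene_models.tsv"),
                                  col_types = "ccdd", progress = FALSE),
    panel = readr::read_lines(p("panel.txt")),
    annotations = read_marker_annotations(p("annotations.tsv"))
  )
  if (file.exists(p("truth.tsv"))) {
    cohort$truth <- readr::read_tsv(p("truth.tsv"), col_types = "cccc",
                                    progress = FALSE)
  }
  class(cohort) <- "portrait_cohort"
  cohort
}

#' Run the full comparison pipeline from a configuration
#'
#' File-driven front end over [run_cohort_pipeline()]: reads every input
#' named in the configuration (a YAML file or an equivalent named list),
#' runs subtyping, the four similarity layers and the scoring stage, writes
#' all result tables as TSV into the output directory together with a JSON
#' run manifest (inputs, parameters, package version), and returns the
#' in-memory result. Configuration keys: the file paths `expr_tumors`,
#' `expr_cells`, `seg_tumors`, `seg_cells`, `maf_tumors`, `maf_cells`,
#' `coverage_tumors`, `coverage_cells`, `prot_tumors`, `prot_cells`,
#' `centroids`, `gene_models`, `panel`, `annotations` (each layer optional,
#' at least one layer required) and the options `fga_t_tumor`, `fga_t_cell`,
#' `top_fraction`, `subtype_match`, `policy`, `outdir`.
#'
#' @param config path to a YAML file, or a named list.
#' @returns The `portrait_result`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  rd <- function(key, reader) {
    if (is.null(config[[key]])) NULL else reader(config[[key]])
  }
  cohort <- list(
    expr_tumors = rd("expr_tumors", read_matrix),
    expr_cells = rd("expr_cells", read_matrix),
    seg_tumors = rd("seg_tumors", read_seg),
    seg_cells = rd("seg_cells", read_seg),
    muts_tumors = rd("maf_tumors", read_maf),
    muts_cells = rd("maf_cells", read_maf),
    coverage_tumors = rd("coverage_tumors", read_bed_coverage),
    coverage_cells = rd("coverage_cells", read_bed_coverage),
    prot_tumors = rd("prot_tumors", read_matrix),
    prot_cells = rd("prot_cells", read_matrix),
    centroids = rd("centroids", read_matrix),
    gene_models = rd("gene_models", read_gene_models),
    panel = rd("panel", readr::read_lines),
    annotations = rd("annotations", read_marker_annotations)
  )
  opts <- list(
    fga_t_tumor = config$fga_t_tumor %||% 0.2,
    fga_t_cell = config$fga_t_cell %||% 0.3,
    top_fraction = config$top_fraction %||% 0.10,
    subtype_match = isTRUE(config$subtype_match),
    policy = config$policy %||% "require_all"
  )
  result <- run_cohort_pipeline(
    cohort,
    fga_t_tumor = opts$fga_t_tumor, fga_t_cell = opts$fga_t_cell,
    top_fraction = opts$top_fraction, subtype_match = opts$subtype_match,
    policy = opts$policy
  )

  outdir <- config$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) {
      if (!is.null(x)) readr::write_tsv(tibble::as_tibble(x), file.path(outdir, f),
                                        na = "", progress = FALSE)
    }
    wr(result$subtype_calls, "subtype_calls.tsv")
    wr(result$expr_cor, "expr_corr.tsv")
    wr(result$cnv_cor, "cnv_corr.tsv")
    wr(result$mut_cor, "mut_corr.tsv")
    wr(result$prot_cor, "prot_corr.tsv")
    wr(result$components, "components.tsv")
    wr(tidy(result$scores), "scores.tsv")
    wr(result$fga, "fga.tsv")
    wr(result$mutation_rates, "mutation_rates.tsv")
    wr(result$spectra, "spectra.tsv")
    manifest <- list(
      package = "oncoportrait",
      version = as.character(utils::packageVersion("oncoportrait")),
      inputs = config[intersect(names(config),
                                c("expr_tumors", "expr_cells", "seg_tumors",
                                  "seg_cells", "maf_tumors", "maf_cells",
                                  "coverage_tumors", "coverage_cells",
                                  "prot_tumors", "prot_cells", "centroids",
                                  "gene_models", "panel", "annotations"))],
      parameters = opts
    )
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}
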