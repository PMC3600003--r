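#' Pipeline configuration defaults
#'
#' A pipeline config is a plain named list (typically read from a YAML file)
#' with these recognized fields, all optional:
#' `snp_table`, `ld_pairs`, `tracks` (named BED paths or a directory),
#' `tss_bed`, `simulate` (a list of [sim_config()] fields used when no input
#' files are given), `r2_threshold`, `max_pair_distance`,
#' `genomewide_threshold`, `suggestive_upper`, `n_permutations`, `n_samples`,
#' `n_tests` (Bonferroni family size), `alpha`, `exclude_annotations`
#' (candidate blacklist for the joint model), `seed`, `outdir`.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(snp_table = NULL, ld_pairs = NULL, tracks = NULL, tss_bed = NULL,
              simulate = list(), r2_threshold = 0.9, max_pair_distance = 250000,
              genomewide_threshold = 5e-8, suggestive_upper = 5e-5,
              n_permutations = 2000, n_samples = 100, n_tests = NULL,
              alpha = 0.05, exclude_annotations = character(),
              seed = 1L, outdir = ".")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown pipeline config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline config from YAML
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate inputs -> assign association status -> compute the
#' LD-expanded overlap matrix -> permutation enrichment and platform-sampling
#' enrichment for both SNP sets (significant and suggestive, from the one
#' status assignment) -> joint logistic model -> write TSV reports and a JSON
#' run manifest (config snapshot, seeds, input digests, per-stage timings).
#'
#' @param config a [pipeline_config()] (or plain list of its fields).
#' @param write write outputs under `config$outdir` (default `TRUE`).
#' @return list with `catalog`, `matrix`, `enrichment` (list of
#'   `enrich_result`s keyed `<set>_<method>`), `model`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), write = TRUE) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  seed <- as.integer(config$seed)
  digests <- list()

  if (!is.null(config$snp_table)) {
    catalog <- read_snp_table(config$snp_table)
    ldc <- ld_config(config$r2_threshold, config$max_pair_distance)
    ld <- if (!is.null(config$ld_pairs))
      read_ld_pairs(config$ld_pairs, ldc, catalog)
    else structure(list(), class = "ld_map")
    paths <- config$tracks
    if (length(paths) == 1 && dir.exists(paths))
      paths <- list.files(paths, "\\.bed$", full.names = TRUE)
    tracks <- lapply(paths, read_annotation_bed)
    for (f in c(config$snp_table, config$ld_pairs, unlist(paths)))
      digests[[basename(f)]] <- unname(tools::md5sum(f))
    truth <- NULL
  } else {
    sim <- do.call(sim_config, c(config$simulate,
                                 if (is.null(config$simulate$seed))
                                   list(seed = seed)))
    study <- simulate_study(sim)
    catalog <- study$catalog; ld <- study$ld; tracks <- study$tracks
    truth <- study$truth
    # express planted labels as p-values so status assignment is exercised
    catalog$pvalue <- ifelse(study$status, 1e-9, NA_real_)
  }
  tick("load_inputs")

  scfg <- status_config(config$genomewide_threshold, config$suggestive_upper)
  catalog <- assign_association_status(catalog, scfg, ld)
  message(sprintf("status: %d significant, %d suggestive, %d background (%d demoted)",
                  sum(catalog$status == "significant"),
                  sum(catalog$status == "suggestive"),
                  sum(catalog$status == "background"), sum(catalog$demoted)))
  tick("assign_status")

  mat <- compute_overlap_matrix(catalog, ld, tracks)
  # annotations covered by none (or all) of the analyzed SNPs carry no
  # information and would degenerate the 2x2 tables: drop them up front
  cs <- colSums(mat)
  uninf <- cs == 0 | cs == nrow(mat)
  if (any(uninf)) {
    message(sprintf("dropping %d uninformative annotation(s): %s",
                    sum(uninf), paste(colnames(mat)[uninf], collapse = ", ")))
    keep_attrs <- attributes(mat)[c("chrom", "pos", "class")]
    mat <- mat[, !uninf, drop = FALSE]
    attributes(mat)[c("chrom", "pos", "class")] <- keep_attrs
  }
  if (!ncol(mat)) stop("no informative annotations left", call. = FALSE)
  tick("overlap_matrix")

  sets <- list(significant = catalog$status == "significant",
               suggestive = catalog$status == "suggestive")
  sets <- Filter(any, sets)
  n_tests <- config$n_tests %||% ncol(mat)
  enrichment <- list()
  for (set in names(sets)) {
    enrichment[[paste0(set, "_permutation")]] <- enrichment_test(
      mat, sets[[set]], "permutation",
      cfg = perm_config(config$n_permutations, seed = seed))
    enrichment[[paste0(set, "_sampling")]] <- enrichment_test(
      mat, sets[[set]], "sampling", catalog = catalog,
      cfg = sampling_config(config$n_samples, seed = seed))
  }
  tick("enrichment")

  model <- NULL
  if (length(sets)) {
    tssd <- if (!is.null(config$tss_bed)) {
      tss <- read_tss_bed(config$tss_bed)
      distance_to_tss(catalog, ld, tss)
    } else NULL
    model <- annotation_model(mat, sets[[1]], catalog,
                              exclude = config$exclude_annotations,
                              tss_distance = tssd)
  }
  tick("joint_model")

  manifest <- list(
    tool = "circenrich",
    version = as.character(utils::packageVersion("circenrich")),
    seed = seed,
    config = config[!vapply(config, is.function, logical(1))],
    input_digests = digests,
    n_snps = nrow(catalog), n_annotations = ncol(mat),
    n_tests_bonferroni = n_tests,
    timings_sec = as.list(timings))
  out <- list(catalog = catalog, matrix = mat, enrichment = enrichment,
              model = model, manifest = manifest, truth = truth)

  if (write) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(enrichment))
      write_enrichment_table(enrichment[[nm]],
                             file.path(config$outdir,
                                       paste0("enrichment_", nm, ".tsv")),
                             alpha = config$alpha, n_tests = n_tests)
    if (!is.null(model))
      write_model_table(model, file.path(config$outdir, "model.tsv"))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(out)
}
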