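#' Test annotation tracks for enrichment of trait-associated SNPs
#'
#' The central fitting function. Given the precomputed LD-expanded overlap
#' matrix and the association labels, assesses each annotation for enrichment
#' or depletion of trait-associated SNPs under one of two null models:
#'
#' * `"permutation"` - chromosome-bound circular permutation of the label
#'   vector (the fully empirical null that preserves SNP clustering,
#'   annotation clustering and LD structure);
#' * `"sampling"` - platform-weighted random background SNP sets with Wald
#'   (theoretical) inference, the conventional comparison method.
#'
#' @param matrix an [compute_overlap_matrix()] result.
#' @param status logical vector of association labels, one per matrix row.
#' @param method `"permutation"` (default) or `"sampling"`.
#' @param catalog the [snp_catalog()] behind the matrix; required for
#'   `method = "sampling"` (platform weights).
#' @param cfg a [perm_config()] or [sampling_config()] matching `method`;
#'   defaults to the method's defaults with the given `seed`.
#' @param seed convenience override for the config seed.
#' @return an `enrich_result` data frame (one row per annotation) with columns
#'   `annotation`, `hits_obs`, `n_assoc`, `null_mean`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `pvalue`, `pvalue_bound`, `fold_enrichment`, `method`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_chromosomes = 2,
#'   snps_per_chromosome = 500, chromosome_length = 5e5, n_assoc = 50,
#'   tracks = default_sim_tracks()[1:3, ], planted_or = c(feat02 = 3),
#'   seed = 7))
#' res <- enrichment_test(study$matrix, study$status,
#'                        cfg = perm_config(n_permutations = 500, seed = 7))
#' res
enrichment_test <- function(matrix, status,
                            method = c("permutation", "sampling"),
                            catalog = NULL, cfg = NULL, seed = NULL) {
  method <- match.arg(method)
  if (method == "permutation") {
    if (is.null(cfg)) cfg <- perm_config(seed = seed %||% 1L)
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    null <- run_permutations(matrix, status, cfg)
    res <- permutation_enrichment(null)
    attr(res, "null") <- null
  } else {
    if (is.null(catalog)) stop("catalog required for the sampling method",
                               call. = FALSE)
    if (is.null(cfg)) cfg <- sampling_config(seed = seed %||% 1L)
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    res <- enrich_sampling(matrix, status, catalog, cfg)
  }
  res
}

#' @export
print.enrich_result <- function(x, digits = 3, ...) {
  cat(sprintf("enrichment results (%s method), %d annotation(s), %d associated SNPs\n",
              x$method[1], nrow(x), x$n_assoc[1]))
  fmt_p <- ifelse(x$pvalue_bound, sprintf("<%.3g", x$pvalue),
                  sprintf("%.3g", x$pvalue))
  df <- data.frame(annotation = x$annotation,
                   hits = x$hits_obs,
                   null_mean = signif(x$null_mean, digits),
                   OR = signif(x$odds_ratio, digits),
                   `95% CI` = sprintf("[%.3g-%.3g]", x$ci_low, x$ci_high),
                   p = fmt_p,
                   fold = signif(x$fold_enrichment, digits),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.enrich_result <- function(object, alpha = 0.05,
                                  n_tests = nrow(object), ...) {
  thr <- bonferroni_threshold(alpha, n_tests)
  cat(sprintf("Bonferroni threshold at alpha=%g for %d test(s): %.3g\n",
              alpha, n_tests, thr))
  sig <- !is.na(object$pvalue) & object$pvalue <= thr
  cat(sprintf("%d of %d annotation(s) significant after correction\n",
              sum(sig), nrow(object)))
  out <- as.data.frame(object)
  out$significant_after_bonferroni <- sig
  invisible(out)
}
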