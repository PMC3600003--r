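#' Sampling-null configuration
#'
#' @param n_samples number of random background SNP sets (default 100).
#' @param seed integer seed.
#' @param group_weights named numeric vector of platform-group proportions
#'   (must sum to 1). `NULL` (default) derives them from the real
#'   trait-associated SNP set: each group's share of associated-SNP
#'   memberships (a SNP belonging to several groups counts once per group)
#'   normalized to 1.
#' @param exclude_associated exclude trait-associated SNPs from the background
#'   pool (default `FALSE`: samples may include them).
#' @return list of class `sampling_config`.
#' @export
sampling_config <- function(n_samples = 100, seed = 1L, group_weights = NULL,
                            exclude_associated = FALSE) {
  n_samples <- as_count(n_samples, "n_samples")
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (!is.null(group_weights)) {
    if (is.null(names(group_weights)) || any(group_weights < 0))
      stop("group_weights must be a named non-negative vector", call. = FALSE)
    if (abs(sum(group_weights) - 1) > 1e-9)
      stop("group_weights must sum to 1", call. = FALSE)
  }
  structure(list(n_samples = n_samples, seed = as.integer(seed),
                 group_weights = group_weights,
                 exclude_associated = exclude_associated),
            class = "sampling_config")
}

# Largest-remainder allocation of `size` draws across groups with the given
# proportions; ties broken by group order (alphabetical, fixed).
allocate_counts <- function(weights, size) {
  weights <- weights[order(names(weights))]
  raw <- weights * size
  base <- floor(raw)
  left <- size - sum(base)
  if (left > 0) {
    rem <- raw - base
    extra <- order(-rem, names(weights))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

# Group weights derived from the associated SNPs' platform memberships.
derived_group_weights <- function(pm, assoc) {
  cnt <- colSums(pm[assoc, , drop = FALSE])
  if (sum(cnt) == 0) stop("associated SNPs carry no platform memberships",
                          call. = FALSE)
  cnt / sum(cnt)
}

#' Draw one platform-weighted background SNP set
#'
#' Samples `size` SNPs without replacement, with per-group counts following
#' largest-remainder rounding of `size * proportion`. Groups are processed in
#' fixed (alphabetical) order and sampled disjointly: a SNP already drawn for
#' an earlier group is not eligible again, so multi-platform SNPs are counted
#' once.
#'
#' @param catalog a [snp_catalog()].
#' @param cfg a [sampling_config()]; when `cfg$group_weights` is `NULL` the
#'   weights are derived from the associated SNPs.
#' @param size sample size (the number of trait-associated SNPs, typically).
#' @param status optional logical vector of association labels, needed to
#'   derive weights or to exclude associated SNPs.
#' @param pm optional precomputed [platform_matrix()]; computed from the
#'   catalog when `NULL`.
#' @return character vector of sampled SNP ids.
#' @export
sample_background <- function(catalog, cfg = sampling_config(), size,
                              status = NULL, pm = NULL) {
  size <- as_count(size, "size")
  if (size == 0) return(character(0))
  if (is.null(pm)) pm <- platform_matrix(catalog)
  w <- cfg$group_weights
  if (is.null(w)) {
    if (is.null(status)) stop("status needed to derive group weights", call. = FALSE)
    w <- derived_group_weights(pm, status)
  }
  counts <- allocate_counts(w, size)
  eligible <- rep(TRUE, nrow(catalog))
  if (cfg$exclude_associated && !is.null(status)) eligible <- !status
  chosen <- integer(0)
  for (g in names(counts)) {
    if (counts[[g]] == 0) next
    pool <- which(eligible & pm[, g])
    pool <- setdiff(pool, chosen)
    if (length(pool) < counts[[g]])
      stop(sprintf("platform group '%s' exhausted: need %d, have %d",
                   g, counts[[g]], length(pool)), call. = FALSE)
    chosen <- c(chosen, pool[sample.int(length(pool), counts[[g]])])
  }
  catalog$snp_id[chosen]
}

#' Enrichment inference for the sampling null
#'
#' Contingency table of the observed hits against the mean hit count over the
#' background samples; Wald CI and two-sided normal p-value on log(OR) - the
#' theoretical counterpart to the permutation method's empirical inference.
#'
#' @param observed_hits observed hit count among associated SNPs.
#' @param n_assoc number of associated SNPs.
#' @param sample_hit_counts hit counts of the background samples.
#' @param sample_size size of each background sample.
#' @param annotation annotation name for the report row.
#' @return one-row `enrich_result` data frame.
#' @export
sampling_enrichment <- function(observed_hits, n_assoc, sample_hit_counts,
                                sample_size, annotation = "annotation") {
  if (any(sample_hit_counts < 0 | sample_hit_counts > sample_size))
    stop("sample hit counts must lie in [0, sample_size]", call. = FALSE)
  mu <- mean(sample_hit_counts)
  tab <- contingency_table(observed_hits, n_assoc - observed_hits,
                           mu, sample_size - mu)
  or <- odds_ratio(tab)
  ci <- wald_ci(tab)
  p <- wald_pvalue(tab)
  fe <- if (mu > 0) fold_enrichment(observed_hits, mu) else Inf
  res <- enrichment_result(annotation, tab, or, ci[["low"]], ci[["high"]],
                           p, FALSE, fe, "sampling")
  class(res) <- c("enrich_result", "data.frame")
  res
}

#' Platform-weighted sampling enrichment across all annotations
#'
#' Draws `cfg$n_samples` background sets of the same size as the associated
#' set, ascertains their LD-expanded overlaps through the precomputed matrix
#' rows (exactly as for the real SNPs), and reports Wald inference per
#' annotation.
#'
#' @param matrix an [compute_overlap_matrix()] result.
#' @param status logical association labels per matrix row.
#' @param catalog the [snp_catalog()] behind the matrix.
#' @param cfg a [sampling_config()].
#' @return an `enrich_result` data frame, one row per annotation.
#' @export
enrich_sampling <- function(matrix, status, catalog, cfg = sampling_config()) {
  stopifnot(inherits(matrix, "overlap_matrix"),
            nrow(matrix) == nrow(catalog))
  status <- as.logical(status)
  if (!any(status)) stop("no trait-associated SNPs in status", call. = FALSE)
  size <- sum(status)
  pm <- platform_matrix(catalog)
  set.seed(cfg$seed)
  hit_counts <- base::matrix(0, cfg$n_samples, ncol(matrix),
                             dimnames = list(NULL, colnames(matrix)))
  for (s in seq_len(cfg$n_samples)) {
    ids <- sample_background(catalog, cfg, size, status = status, pm = pm)
    rows <- match(ids, rownames(matrix))
    hit_counts[s, ] <- colSums(matrix[rows, , drop = FALSE])
  }
  observed <- colSums(matrix[status, , drop = FALSE])
  res <- do.call(rbind, lapply(colnames(matrix), function(a)
    sampling_enrichment(observed[[a]], size, hit_counts[, a], size, a)))
  class(res) <- c("enrich_result", "data.frame")
  attr(res, "cfg") <- cfg
  attr(res, "sample_hit_counts") <- hit_counts
  res
}
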