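#' Enrichment contingency table
#'
#' The 2x2 table underlying every odds ratio here: overlaps and non-overlaps
#' of the real trait-associated SNPs against overlaps and non-overlaps of a
#' null (sampled or permuted) set. Null cells may be non-integer, since they
#' are typically means over many samples or permutations.
#'
#' @param hits_real observed overlap count in the real data.
#' @param nonhits_real observed non-overlap count in the real data.
#' @param hits_null null overlap count (possibly a mean, non-integer).
#' @param nonhits_null null non-overlap count.
#' @return a list of class `contingency_table`.
#' @export
contingency_table <- function(hits_real, nonhits_real, hits_null, nonhits_null) {
  cells <- c(hits_real, nonhits_real, hits_null, nonhits_null)
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative", call. = FALSE)
  if (hits_real + nonhits_real <= 0 || hits_null + nonhits_null <= 0)
    stop("each margin of the contingency table must be positive", call. = FALSE)
  structure(list(hits_real = hits_real, nonhits_real = nonhits_real,
                 hits_null = hits_null, nonhits_null = nonhits_null),
            class = "contingency_table")
}

#' Odds ratio of enrichment
#'
#' `(hits_real * nonhits_null) / (nonhits_real * hits_null)`. Values above 1
#' indicate enrichment of trait-associated SNPs in the annotation, below 1
#' depletion. Returns `Inf` when the denominator is zero but the numerator is
#' positive (the "Infinity" entries of sparse annotations); a 0/0 table is a
#' degenerate-table error. With `haldane = TRUE` the Haldane-Anscombe +0.5
#' continuity correction is applied to every cell first (off by default:
#' raw infinite bounds are reported as such).
#'
#' @param t a [contingency_table()].
#' @param haldane apply the +0.5 continuity correction.
#' @return non-negative number, possibly `Inf`.
#' @export
odds_ratio <- function(t, haldane = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$hits_real; b <- t$nonhits_real; c <- t$hits_null; d <- t$nonhits_null
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  num <- a * d; den <- b * c
  if (den == 0 && num == 0)
    stop("degenerate contingency table: 0/0 odds ratio", call. = FALSE)
  if (den == 0) return(Inf)
  num / den
}

#' Wald confidence interval for an odds ratio
#'
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, the unconditional
#' maximum-likelihood (Wald) interval. Any zero cell sends the corresponding
#' bound to 0 or `Inf`.
#'
#' @param t a [contingency_table()].
#' @param level confidence level in (0, 1), default 0.95.
#' @return named numeric vector `c(low, high)`.
#' @export
wald_ci <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1))
    stop("level must lie in (0, 1)", call. = FALSE)
  a <- t$hits_real; b <- t$nonhits_real; c <- t$hits_null; d <- t$nonhits_null
  if (min(a, b, c, d) == 0) {
    # A zero cell carries no Wald information: degenerate interval [0, Inf).
    return(c(low = 0, high = Inf))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lor <- log(a * d / (b * c))
  c(low = exp(lor - z * se), high = exp(lor + z * se))
}

#' Wald two-sided p-value for an odds ratio
#'
#' Asymptotic normal test of log(OR) = 0 - deliberately "theoretical"
#' inference, in contrast to the empirical permutation p-value.
#'
#' @param t a [contingency_table()].
#' @return two-sided p-value, or `NA` when a zero cell makes the statistic
#'   undefined.
#' @export
wald_pvalue <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$hits_real; b <- t$nonhits_real; c <- t$hits_null; d <- t$nonhits_null
  if (min(a, b, c, d) == 0) return(NA_real_)
  z <- log(a * d / (b * c)) / sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  2 * stats::pnorm(-abs(z))
}

#' Fold enrichment
#'
#' Ratio of observed hits in the associated data to the mean hits in the null
#' data. For rare annotations this is approximately equal to the odds ratio.
#'
#' @param hits_obs observed hit count.
#' @param null_mean_hits mean null hit count; must be positive.
#' @return non-negative number.
#' @export
fold_enrichment <- function(hits_obs, null_mean_hits) {
  if (!is.finite(null_mean_hits) || null_mean_hits <= 0)
    stop("fold enrichment undefined: null mean hits must be positive", call. = FALSE)
  hits_obs / null_mean_hits
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, default 0.05.
#' @param n_tests number of tests (annotations studied).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 58)  # 8.62e-4 to 3 significant figures
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  n_tests <- as_count(n_tests, "n_tests")
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  stopifnot(alpha > 0, alpha <= 1)
  alpha / n_tests
}

# Assemble one row of an enrichment report.
enrichment_result <- function(annotation, table, odds_ratio, ci_low, ci_high,
                              pvalue, pvalue_bound, fold_enrichment, method) {
  data.frame(annotation = annotation,
             hits_obs = table$hits_real,
             n_assoc = table$hits_real + table$nonhits_real,
             null_mean = table$hits_null,
             odds_ratio = odds_ratio, ci_low = ci_low, ci_high = ci_high,
             pvalue = pvalue, pvalue_bound = pvalue_bound,
             fold_enrichment = fold_enrichment,
             method = method, stringsAsFactors = FALSE)
}

#' Write an enrichment report as TSV
#'
#' Columns: annotation, hits_obs, n_assoc, null_mean, odds_ratio, ci_low,
#' ci_high, pvalue, fold_enrichment, significant_after_bonferroni. Infinite
#' bounds are rendered as `Infinity`. Numeric values round-trip through
#' [read_enrichment_table()] to at least 6 significant digits.
#'
#' @param results an `enrich_result` object or data frame of results.
#' @param path output path.
#' @param alpha family-wise error rate for the Bonferroni column.
#' @param n_tests family size for the Bonferroni correction (defaults to the
#'   number of rows).
#' @return invisibly, `path`.
#' @export
write_enrichment_table <- function(results, path, alpha = 0.05,
                                   n_tests = nrow(results)) {
  if (!NROW(results)) stop("empty results", call. = FALSE)
  thr <- bonferroni_threshold(alpha, n_tests)
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA"
      else if (is.infinite(v)) if (v > 0) "Infinity" else "-Infinity"
      else format(v, digits = 9, scientific = v != 0 && abs(v) < 1e-4)
    }, character(1))
    out
  }
  df <- data.frame(annotation = results$annotation,
                   hits_obs = results$hits_obs,
                   n_assoc = results$n_assoc,
                   null_mean = fmt(results$null_mean),
                   odds_ratio = fmt(results$odds_ratio),
                   ci_low = fmt(results$ci_low),
                   ci_high = fmt(results$ci_high),
                   pvalue = fmt(results$pvalue),
                   fold_enrichment = fmt(results$fold_enrichment),
                   significant_after_bonferroni =
                     !is.na(results$pvalue) & results$pvalue <= thr,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_table
#' @export
read_enrichment_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  num <- c("null_mean", "odds_ratio", "ci_low", "ci_high", "pvalue",
           "fold_enrichment")
  for (cn in intersect(num, names(df))) {
    v <- df[[cn]]
    v[v == "Infinity"] <- "Inf"; v[v == "-Infinity"] <- "-Inf"
    df[[cn]] <- as.numeric(v)
  }
  df
}
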