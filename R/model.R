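#' Maximum-likelihood logistic fit of association status
#'
#' Fits `status ~ design` by IRLS (via [stats::glm.fit()] with a binomial
#' family). Trait-associated SNPs are coded 1, non-associated 0. For every
#' term the estimate, its standard error, the beta-coefficient (estimate/SE,
#' i.e. the Wald z) and the two-sided Wald p-value are reported. Complete or
#' quasi-complete separation is detected (fitted probabilities numerically 0
#' or 1) and flagged on the result rather than silently returned.
#'
#' @param response logical or 0/1 vector.
#' @param design data frame or numeric matrix of named covariate columns
#'   (binary incidences and/or quantitative covariates). An intercept is added
#'   automatically.
#' @param forced_terms names of terms that selection procedures must never
#'   drop (the intercept and platform indicators, typically).
#' @return object of class `model_fit`: list with `terms` (data frame: term,
#'   estimate, se, beta_coefficient, pvalue), `loglik`, `aic`, `n_obs`,
#'   `n_par`, `forced_terms`, `separation`, `converged`, `fitted`, `eta`.
#' @export
fit_logistic <- function(response, design, forced_terms = "(Intercept)") {
  y <- as.numeric(as.logical(response))
  if (anyNA(y)) stop("response contains NA", call. = FALSE)
  if (all(y == 1) || all(y == 0))
    stop("response needs both classes present", call. = FALSE)
  X <- as.matrix(as.data.frame(design, check.names = FALSE))
  storage.mode(X) <- "double"
  if (ncol(X)) {
    const <- apply(X, 2, function(v) max(v) == min(v))
    if (any(const))
      stop("constant non-intercept column(s): ",
           paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }
  Xm <- cbind(`(Intercept)` = 1, X)
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xm, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop(sprintf("logistic fit failed to converge after %d IRLS iterations",
                 fit$iter), call. = FALSE)
  mu <- fit$fitted.values
  eps <- 1e-8
  separation <- warned_sep || any(mu < eps) || any(mu > 1 - eps)
  # Wald covariance from the weighted cross-product at the solution
  W <- mu * (1 - mu)
  XtWX <- crossprod(Xm * sqrt(W))
  vc <- tryCatch(solve(XtWX), error = function(e)
    stop("singular information matrix in logistic fit", call. = FALSE))
  est <- fit$coefficients
  se <- sqrt(diag(vc))
  beta <- est / se
  ll <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  p <- length(est)
  terms <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), beta_coefficient = unname(beta),
                      pvalue = unname(2 * stats::pnorm(-abs(beta))),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, loglik = ll, aic = 2 * p - 2 * ll,
                 n_obs = length(y), n_par = p,
                 forced_terms = forced_terms, separation = separation,
                 converged = fit$converged,
                 fitted = mu, eta = as.numeric(Xm %*% est),
                 response = y),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("logistic model fit: %d obs, %d parameter(s), AIC %.2f%s\n",
              x$n_obs, x$n_par, x$aic,
              if (x$separation) " [separation flagged]" else ""))
  print(x$terms, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.model_fit <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

#' @export
logLik.model_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, class = "logLik")
}

#' Bidirectional stepwise AIC selection with forced terms
#'
#' Starts from the base model (intercept plus the forced terms - platform
#' indicators in the intended use - which are never candidates for removal)
#' and repeatedly takes the single addition or removal of one candidate
#' annotation that most reduces the AIC. The search halts as soon as no move
#' reduces the AIC, so the final AIC never exceeds the base model's. Ties in
#' AIC reduction are broken lexicographically by term name for determinism.
#'
#' @param response logical or 0/1 vector.
#' @param design data frame/matrix containing both forced and candidate
#'   columns.
#' @param forced names of forced columns (may be empty).
#' @param candidates names of candidate columns.
#' @return a `model_fit` for the selected model with extra fields `selected`
#'   (candidate names in the final model) and `step_log` (data frame of
#'   moves: step, action, term, aic).
#' @export
stepwise_aic <- function(response, design, forced = character(),
                         candidates) {
  X <- as.data.frame(design, check.names = FALSE)
  stopifnot(all(forced %in% names(X)), all(candidates %in% names(X)))
  current <- character(0)
  fit <- fit_logistic(response, X[, forced, drop = FALSE],
                      forced_terms = c("(Intercept)", forced))
  log_rows <- list(data.frame(step = 0L, action = "base", term = "",
                              aic = fit$aic, stringsAsFactors = FALSE))
  step <- 0L
  repeat {
    moves <- rbind(
      if (length(setdiff(candidates, current)))
        data.frame(action = "add", term = setdiff(candidates, current),
                   stringsAsFactors = FALSE),
      if (length(current))
        data.frame(action = "drop", term = current, stringsAsFactors = FALSE))
    if (is.null(moves) || !nrow(moves)) break
    aics <- vapply(seq_len(nrow(moves)), function(i) {
      terms <- if (moves$action[i] == "add") c(current, moves$term[i])
               else setdiff(current, moves$term[i])
      f <- tryCatch(
        fit_logistic(response, X[, c(forced, terms), drop = FALSE],
                     forced_terms = c("(Intercept)", forced)),
        error = function(e) NULL)
      if (is.null(f)) Inf else f$aic
    }, numeric(1))
    best <- order(aics, moves$term)[1]
    if (!(aics[best] < fit$aic)) break  # AIC would increase (or stall): halt
    step <- step + 1L
    current <- if (moves$action[best] == "add") c(current, moves$term[best])
               else setdiff(current, moves$term[best])
    fit <- fit_logistic(response, X[, c(forced, current), drop = FALSE],
                        forced_terms = c("(Intercept)", forced))
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(step = step, action = moves$action[best],
                 term = moves$term[best], aic = fit$aic,
                 stringsAsFactors = FALSE)
  }
  fit$selected <- sort(current)
  fit$step_log <- do.call(rbind, log_rows)
  fit
}

#' Pseudo r-squared values for a logistic model
#'
#' McFadden: `1 - loglik_full / loglik_empty`. McKelvey & Zavoina:
#' `Var(eta) / (Var(eta) + pi^2/3)` where eta are the full model's linear
#' predictors and pi^2/3 is the variance of the standard logistic
#' distribution. Both are 0 when the full model equals the empty model.
#'
#' @param fit_empty the empty (base) `model_fit`.
#' @param fit_full the full `model_fit` on the same response.
#' @return list with `mcfadden` and `mckelvey_zavoina`.
#' @export
pseudo_r2 <- function(fit_empty, fit_full) {
  stopifnot(inherits(fit_empty, "model_fit"), inherits(fit_full, "model_fit"))
  if (fit_empty$n_obs != fit_full$n_obs)
    stop("models must be fit to the same data", call. = FALSE)
  if (fit_empty$loglik == 0)
    stop("empty-model log-likelihood is zero; McFadden undefined", call. = FALSE)
  v <- stats::var(fit_full$eta)
  list(mcfadden = 1 - fit_full$loglik / fit_empty$loglik,
       mckelvey_zavoina = v / (v + pi^2 / 3))
}

#' Likelihood-ratio (deviance) test between nested logistic models
#'
#' `deviance = 2 * (loglik_full - loglik_reduced)`, compared to a chi-squared
#' distribution with degrees of freedom equal to the parameter-count
#' difference. A numerically negative deviance is clipped to 0 with a warning.
#'
#' @param fit_reduced reduced `model_fit` (nested in the full model).
#' @param fit_full full `model_fit`.
#' @return list of class `model_comparison`: `deviance`, `df`, `pvalue`.
#' @export
lr_deviance_test <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "model_fit"), inherits(fit_full, "model_fit"))
  if (fit_reduced$n_obs != fit_full$n_obs)
    stop("models must be fit to the same data", call. = FALSE)
  if (!all(fit_reduced$terms$term %in% fit_full$terms$term))
    stop("models are not nested", call. = FALSE)
  df <- fit_full$n_par - fit_reduced$n_par
  if (df < 1 && fit_full$n_par != fit_reduced$n_par)
    stop("models are not nested", call. = FALSE)
  dev <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (dev < 0) {
    warning("negative deviance clipped to 0 (numerical)", call. = FALSE)
    dev <- 0
  }
  p <- if (df >= 1) stats::pchisq(dev, df, lower.tail = FALSE) else 1
  structure(list(deviance = dev, df = df, pvalue = p),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("deviance test: deviance = %.2f, df = %d, p = %.3g\n",
              x$deviance, x$df, x$pvalue))
  invisible(x)
}

#' Combined-annotation odds ratio
#'
#' How much more likely is a SNP hitting at least one of the given annotations
#' to be trait-associated than a SNP hitting none of them? A 2x2 table of hit
#' status against association status over all SNPs, with Wald CI and p-value.
#'
#' @param matrix an [compute_overlap_matrix()] result.
#' @param positive_set annotation (column) names forming the positive set.
#' @param status logical association labels per matrix row.
#' @return one-row `enrich_result` data frame (method `"combined"`).
#' @export
combined_annotation_or <- function(matrix, positive_set, status) {
  if (!length(positive_set)) stop("positive_set is empty", call. = FALSE)
  stopifnot(all(positive_set %in% colnames(matrix)))
  status <- as.logical(status)
  hit <- rowSums(matrix[, positive_set, drop = FALSE]) > 0
  a <- sum(hit & status); b <- sum(!hit & status)
  c_ <- sum(hit & !status); d <- sum(!hit & !status)
  if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0)
    stop("degenerate 2x2 table for combined annotations", call. = FALSE)
  tab <- contingency_table(a, b, c_, d)
  or <- odds_ratio(tab)
  ci <- wald_ci(tab)
  res <- enrichment_result(paste(positive_set, collapse = "+"), tab, or,
                           ci[["low"]], ci[["high"]], wald_pvalue(tab), FALSE,
                           if (c_ > 0) (a / (a + b)) / (c_ / (c_ + d)) else Inf,
                           "combined")
  class(res) <- c("enrich_result", "data.frame")
  res
}

#' Upstream distance to the nearest transcription start site
#'
#' For each SNP, the minimum over the SNP and (optionally) its LD partners of
#' the distance to the nearest TSS that the position lies upstream of
#' (5-prime of the TSS respecting strand: before a plus-strand TSS, after a
#' minus-strand one), on the same chromosome. SNPs with no upstream TSS on
#' their chromosome get `NA`; model preparation replaces those by a cap.
#'
#' @param catalog a [snp_catalog()].
#' @param ld an [ld_map()]; ignored when `mode = "snp"`.
#' @param tss an [annotation_track()] with a `strand` column; the TSS of a
#'   plus-strand record is its first base (start, 1-based start + 1), of a
#'   minus-strand record its last base (end).
#' @param mode `"ld"` (default; minimum over the LD-expanded set) or `"snp"`
#'   (the SNP alone).
#' @return numeric vector of distances in base pairs (0 when a position
#'   coincides with a TSS), `NA` where no upstream TSS exists.
#' @export
distance_to_tss <- function(catalog, ld, tss, mode = c("ld", "snp")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tss, "annotation_track"), "strand" %in% names(tss))
  if (!nrow(tss)) stop("TSS track is empty", call. = FALSE)
  tss_pos <- ifelse(tss$strand == "+", tss$start + 1, tss$end)
  # per-chromosome sorted TSS positions by strand
  plus <- lapply(split(tss_pos[tss$strand == "+"], tss$chrom[tss$strand == "+"]), sort)
  minus <- lapply(split(tss_pos[tss$strand == "-"], tss$chrom[tss$strand == "-"]), sort)
  dist_one <- function(ch, p) {
    d <- Inf
    tp <- plus[[ch]]
    if (!is.null(tp)) {
      i <- findInterval(p - 1, tp) + 1  # first TSS >= p
      if (i <= length(tp)) d <- min(d, tp[i] - p)
    }
    tm <- minus[[ch]]
    if (!is.null(tm)) {
      i <- findInterval(p, tm)          # last TSS <= p
      if (i >= 1) d <- min(d, p - tm[i])
    }
    d
  }
  n <- nrow(catalog)
  out <- numeric(n)
  for (k in seq_len(n)) {
    ids <- if (mode == "ld") expand_with_ld(catalog$snp_id[k], ld) else catalog$snp_id[k]
    rows <- match(ids, catalog$snp_id)
    rows <- rows[!is.na(rows)]
    d <- min(vapply(rows, function(r) dist_one(catalog$chrom[r], catalog$pos[r]),
                    numeric(1)))
    out[k] <- if (is.finite(d)) d else NA_real_
  }
  out
}

#' Joint logistic model of trait-association status
#'
#' The top-level modelling interface: builds the design from the overlap
#' matrix (candidate annotations) and platform indicators (forced terms, the
#' "empty model" covariates), optionally appends the upstream distance to the
#' nearest TSS as a quantitative covariate, runs [stepwise_aic()], and reports
#' coefficients, beta-coefficients, pseudo r-squared values and the deviance
#' test against the empty model.
#'
#' @param matrix an [compute_overlap_matrix()] result.
#' @param status logical association labels per matrix row.
#' @param catalog the [snp_catalog()] behind the matrix (platform indicators).
#' @param exclude annotation names excluded from the candidate set (for
#'   tautologically trait-associated tracks, e.g. disease-gene catalogs).
#' @param tss_distance optional numeric vector (e.g. from
#'   [distance_to_tss()]); `NA`s are replaced by `tss_cap`.
#' @param tss_cap replacement for missing distances: a number, or `"max"`
#'   (default) for the largest finite observed distance.
#' @param log1p_tss apply `log1p` to the distance covariate (default `FALSE`:
#'   untransformed base pairs).
#' @return object of class `annot_logit`: the selected `model_fit` plus
#'   `empty_fit`, `pseudo_r2`, `deviance_test`, `candidates`, `design`.
#' @export
annotation_model <- function(matrix, status, catalog, exclude = character(),
                             tss_distance = NULL, tss_cap = "max",
                             log1p_tss = FALSE) {
  stopifnot(inherits(matrix, "overlap_matrix"))
  status <- as.logical(status)
  pm <- platform_matrix(catalog)
  # platform indicators: drop one redundant column if any is constant TRUE
  keep <- colnames(pm)[apply(pm, 2, function(v) min(v) != max(v))]
  design <- as.data.frame(cbind(pm[, keep, drop = FALSE] * 1,
                                matrix * 1), check.names = FALSE)
  forced <- keep
  candidates <- setdiff(colnames(matrix), exclude)
  # drop constant candidate columns (uninformative at this scale)
  candidates <- candidates[vapply(candidates, function(cn)
    min(design[[cn]]) != max(design[[cn]]), logical(1))]
  if (!is.null(tss_distance)) {
    d <- tss_distance
    cap <- if (identical(tss_cap, "max")) max(d[is.finite(d)], na.rm = TRUE)
           else as.numeric(tss_cap)
    capped <- is.na(d)
    d[capped] <- cap
    if (log1p_tss) d <- log1p(d)
    design[["tss_distance"]] <- d
    candidates <- c(candidates, "tss_distance")
  }
  empty <- fit_logistic(status, design[, forced, drop = FALSE],
                        forced_terms = c("(Intercept)", forced))
  fit <- stepwise_aic(status, design, forced = forced, candidates = candidates)
  structure(list(fit = fit, empty_fit = empty,
                 pseudo_r2 = pseudo_r2(empty, fit),
                 deviance_test = lr_deviance_test(empty, fit),
                 candidates = candidates, forced = forced,
                 tss_capped = if (!is.null(tss_distance)) sum(is.na(tss_distance)) else 0L),
            class = "annot_logit")
}

#' @export
print.annot_logit <- function(x, ...) {
  cat("joint logistic model of trait-association status\n")
  cat(sprintf("  selected annotations: %s\n",
              if (length(x$fit$selected)) paste(x$fit$selected, collapse = ", ")
              else "(none)"))
  cat(sprintf("  AIC %.2f (empty %.2f); McFadden r2 %.4f, McKelvey-Zavoina r2 %.4f\n",
              x$fit$aic, x$empty_fit$aic,
              x$pseudo_r2$mcfadden, x$pseudo_r2$mckelvey_zavoina))
  cat(sprintf("  deviance vs empty: %.2f on %d df, p = %.3g\n",
              x$deviance_test$deviance, x$deviance_test$df,
              x$deviance_test$pvalue))
  invisible(x)
}

#' @export
summary.annot_logit <- function(object, ...) {
  print(object)
  cat("\ncoefficients:\n")
  print(object$fit$terms, digits = 4, row.names = FALSE)
  invisible(object$fit$terms)
}

#' @export
coef.annot_logit <- function(object, ...) coef(object$fit)

#' Write a joint-model report as TSV
#'
#' Mirrors the shape of a coefficients table (estimate, std. error,
#' beta-coefficient, p-value) followed by the AIC step log as comment lines.
#'
#' @param model an [annotation_model()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model_table <- function(model, path) {
  stopifnot(inherits(model, "annot_logit"))
  tt <- model$fit$terms
  names(tt) <- c("term", "estimate", "std_error", "beta_coefficient", "pvalue")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(tt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# mcfadden_r2\t%.6g", model$pseudo_r2$mcfadden), con)
  writeLines(sprintf("# mckelvey_zavoina_r2\t%.6g",
                     model$pseudo_r2$mckelvey_zavoina), con)
  writeLines(sprintf("# deviance\t%.6g\tdf\t%d\tp\t%.6g",
                     model$deviance_test$deviance, model$deviance_test$df,
                     model$deviance_test$pvalue), con)
  sl <- model$fit$step_log
  for (i in seq_len(nrow(sl)))
    writeLines(sprintf("# step\t%d\t%s\t%s\t%.6f", sl$step[i], sl$action[i],
                       sl$term[i], sl$aic[i]), con)
  invisible(path)
}
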