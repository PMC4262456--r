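#' Area under the ROC curve
#'
#' Rank-based AUC equal to the normalized Mann-Whitney U statistic, with
#' ties counted one half: the probability that a random presence scores
#' above a random absence.
#'
#' @param labels Binary vector (0/1), both classes present.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (length(unique(labels)) < 2) stop("both classes required to compute AUC")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Qualitative AUC category
#'
#' Standard bins for discrimination ability: above 0.9 excellent, 0.9-0.8
#' good, 0.8-0.7 moderate, 0.7-0.6 poor, 0.6-0.5 unsuccessful. Boundary
#' values take the higher category.
#'
#' @param value AUC value.
#' @return One of `"excellent"`, `"good"`, `"moderate"`, `"poor"`,
#'   `"unsuccessful"`.
#' @export
auc_category <- function(value) {
  stopifnot(value >= 0, value <= 1)
  if (value >= 0.9) "excellent"
  else if (value >= 0.8) "good"
  else if (value >= 0.7) "moderate"
  else if (value >= 0.6) "poor"
  else "unsuccessful"
}

## Linear predictor of a fitted/averaged coefficient vector on a table
## whose covariates are already normalized; quadratic terms use the
## matching `<var>_sq` column (created on demand).
ensure_sq_columns <- function(table, terms) {
  for (term in terms[endsWith(terms, "_sq")]) {
    if (!term %in% names(table))
      table[[term]] <- table[[sub("_sq$", "", term)]]^2
  }
  table
}

lp_from_coef <- function(coef, table) {
  lp <- rep(coef[["INT"]], nrow(table))
  for (term in setdiff(names(coef), "INT"))
    lp <- lp + coef[[term]] * table[[term]]
  lp
}

avg_coef <- function(models, weights) {
  all_terms <- unique(unlist(lapply(models, function(f) names(f$coef))))
  coef <- setNames(numeric(length(all_terms)), all_terms)
  for (i in seq_along(models))
    coef[names(models[[i]]$coef)] <-
      coef[names(models[[i]]$coef)] + weights[i] * models[[i]]$coef
  coef
}

#' Repeated-split cross-validation of an averaged model
#'
#' Per replicate: a random 70/30 split (stratified by response so both
#' classes appear on both sides); every model of the confidence set is
#' refitted on the training part, Akaike weights are recomputed from the
#' training AICs and renormalized, and the re-averaged model is scored by
#' AUC on both the training and held-out parts. Replicates where no model
#' converges are redrawn (logged). The model is judged transferable when
#' the lower 95% CI limit of the test AUC does not include 0.5.
#'
#' @param table Normalized occurrence table (as used to fit the set).
#' @param cset A [confidence_set()].
#' @param train_frac Training fraction (default 0.7).
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param nAGQ Quadrature nodes for the refits (default 15).
#' @return Object of class `validation_report`: `auc_full` (averaged
#'   model on all data) with its category, per-side summaries
#'   (mean, sd, percentile 95% CI), `n_reps`, `transferable`.
#' @export
cross_validate <- function(table, cset, train_frac = 0.7, n_reps = 1000,
                           seed = NULL, nAGQ = 15) {
  stopifnot(train_frac > 0, train_frac < 1, n_reps >= 1)
  all_terms <- unique(unlist(lapply(cset$models, function(f) names(f$coef))))
  table <- ensure_sq_columns(table, setdiff(all_terms, "INT"))
  gf <- cset$group_field
  full_scores <- plogis(lp_from_coef(avg_coef(cset$models, cset$weights), table))
  auc_full <- auc(table$response, full_scores)
  with_seed(seed, {
    i1 <- which(table$response == 1); i0 <- which(table$response == 0)
    tr_auc <- te_auc <- rep(NA_real_, n_reps)
    rep_done <- 0L; redraws <- 0L
    while (rep_done < n_reps) {
      tr_idx <- c(sample(i1, round(train_frac * length(i1))),
                  sample(i0, round(train_frac * length(i0))))
      train <- table[tr_idx, , drop = FALSE]
      test <- table[-tr_idx, , drop = FALSE]
      if (length(unique(train[[gf]])) < 2 ||
          length(unique(test$response)) < 2) { redraws <- redraws + 1L; next }
      refits <- lapply(cset$models, function(f)
        tryCatch(fit_glmm(train, f$terms, gf, nAGQ = nAGQ),
                 error = function(e) NULL))
      ok <- !vapply(refits, is.null, TRUE) &
        vapply(refits, function(f) is.null(f) || f$converged, TRUE)
      if (!any(ok)) { redraws <- redraws + 1L; next }
      refits <- refits[ok]
      w <- akaike_weights(vapply(refits, function(f) f$aic, 0))
      coef <- avg_coef(refits, w)
      rep_done <- rep_done + 1L
      tr_auc[rep_done] <- auc(train$response, plogis(lp_from_coef(coef, train)))
      te_auc[rep_done] <- auc(test$response, plogis(lp_from_coef(coef, test)))
    }
    if (redraws > 0) message(redraws, " replicate(s) redrawn")
    summ <- function(x) list(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
                             ci = unname(quantile(x, c(0.025, 0.975))))
    te <- summ(te_auc)
    structure(list(auc_full = auc_full, category = auc_category(auc_full),
                   training = summ(tr_auc), test = te,
                   n_reps = n_reps,
                   transferable = te$ci[1] > 0.5),
              class = "validation_report")
  })
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("AUC average model: %.3f (%s)\n", x$auc_full, x$category))
  cat(sprintf("AUC training: %.3f +/- %.3f [%.3f, %.3f]\n",
              x$training$mean, x$training$sd, x$training$ci[1], x$training$ci[2]))
  cat(sprintf("AUC test:     %.3f +/- %.3f [%.3f, %.3f]  (%d reps)\n",
              x$test$mean, x$test$sd, x$test$ci[1], x$test$ci[2], x$n_reps))
  cat("transferable:", if (x$transferable) "yes" else "no", "\n")
  invisible(x)
}

#' Two-sample z-test for coefficient equality
#'
#' Compares two estimates with standard errors, e.g. the same covariate
#' coefficient fitted at weekly versus monthly resolution:
#' `z = (est1 - est2) / sqrt(se1^2 + se2^2)` with a two-sided normal p.
#'
#' @param est1,se1,est2,se2 Estimates and standard errors (`se > 0`).
#' @return list with `z` and `p`.
#' @export
compare_coefficients <- function(est1, se1, est2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be > 0")
  z <- (est1 - est2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}
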