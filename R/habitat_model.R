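#' Normalize covariates to z-scores
#'
#' Centers and scales each covariate to mean 0, SD 1 so coefficient
#' magnitudes are comparable across variables; the constants are stored
#' for prediction-time reuse on new data.
#'
#' @param table Occurrence table.
#' @param vars Covariate columns to normalize.
#' @return The table with `vars` replaced by z-scores and an attribute
#'   `norm` holding `list(mean, sd)` per variable.
#' @export
normalize_covariates <- function(table, vars) {
  mu <- vapply(table[vars], mean, 0)
  s <- vapply(table[vars], sd, 0)
  zero <- vars[is.na(s) | s == 0]
  if (length(zero))
    stop("zero-variance covariate(s): ", paste(zero, collapse = ", "))
  for (v in vars) table[[v]] <- (table[[v]] - mu[[v]]) / s[[v]]
  attr(table, "norm") <- list(mean = mu, sd = s)
  table
}

glmm_control <- function() {
  lme4::glmerControl(calc.derivs = FALSE, optimizer = "nloptwrap",
                     check.conv.singular = "ignore")
}

#' Fit a random-intercept binomial GLMM
#'
#' Maximum-likelihood logistic regression with a Normal random intercept
#' per group (animal trip or survey campaign), the marginal likelihood
#' integrated by adaptive Gauss-Hermite quadrature. As the random-effect
#' SD goes to 0 the fit coincides with ordinary logistic regression. The
#' variance parameter is counted in the AIC penalty, so
#' `AIC = -2 logLik + 2 (n_fixed + 1)`.
#'
#' @param table Occurrence table with a binary `response` column (both
#'   classes present), the model terms as columns, and the grouping field.
#' @param terms Character vector of term columns (may be empty for the
#'   intercept-only model).
#' @param group_field Name of the grouping column (default `"group"`).
#' @param nAGQ Quadrature nodes (default 15).
#' @param response Name of the response column.
#' @return Object of class `hs_glmm`: `terms`, `coef` (named, `INT` =
#'   intercept), `se`, `sigma` (random-intercept SD), `loglik`, `aic`,
#'   `n`, `n_groups`, `converged`.
#' @export
fit_glmm <- function(table, terms, group_field = "group", nAGQ = 15,
                     response = "response") {
  y <- table[[response]]
  if (is.null(y) || !all(y %in% 0:1)) stop("binary response column required")
  if (length(unique(y)) < 2) stop("response present in one class only")
  g <- table[[group_field]]
  if (length(unique(g)) < 2) stop("need >= 2 groups for a random intercept")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- as.formula(paste(response, "~", rhs, "+ (1 |", group_field, ")"))
  warned <- FALSE
  fit <- withCallingHandlers(
    lme4::glmer(fml, data = table, family = stats::binomial(),
                nAGQ = nAGQ, control = glmm_control()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  names(fe)[1] <- names(se)[1] <- "INT"
  converged <- !warned && isTRUE(fit@optinfo$conv$opt == 0)
  if (any(abs(fe) > 15)) converged <- FALSE  # complete separation guard
  structure(list(
    terms = terms, coef = fe, se = se,
    sigma = sqrt(unlist(lme4::VarCorr(fit))[[1]]),
    loglik = as.numeric(logLik(fit)), aic = AIC(fit),
    n = nrow(table), n_groups = length(unique(g)),
    converged = converged), class = "hs_glmm")
}

## Numerical failures inside the optimizer (e.g. PIRLS non-convergence on
## near-separated subsets) are reported as a non-converged stub rather
## than aborting a whole enumeration.
try_fit_glmm <- function(table, terms, group_field = "group", nAGQ = 15) {
  tryCatch(fit_glmm(table, terms, group_field, nAGQ = nAGQ),
           error = function(e) structure(
             list(terms = terms, coef = c(INT = NA_real_), se = c(INT = NA_real_),
                  sigma = NA_real_, loglik = NA_real_, aic = Inf,
                  n = nrow(table), n_groups = NA_integer_,
                  converged = FALSE, error = conditionMessage(e)),
             class = "hs_glmm"))
}

#' @export
print.hs_glmm <- function(x, ...) {
  cat(sprintf("binomial GLMM (%s): AIC %.2f, sigma %.3f, n %d (%d groups)%s\n",
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "intercept only",
              x$aic, x$sigma, x$n, x$n_groups,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(rbind(estimate = x$coef, se = x$se), 4))
  invisible(x)
}

#' Collinearity screening by Spearman rank correlation
#'
#' Processes variable pairs in decreasing absolute Spearman correlation;
#' for each pair above the threshold where both members are still
#' retained, drops the less informative one, i.e. the variable whose
#' univariate GLMM has the higher AIC. Deterministic.
#'
#' @inheritParams fit_glmm
#' @param vars Candidate covariate columns.
#' @param r_threshold Absolute correlation threshold (default 0.6).
#' @return list with `retained` (character vector) and `dropped`
#'   (data.frame `var`, `because_of`, `r`).
#' @export
collinearity_screen <- function(table, vars, r_threshold = 0.6,
                                group_field = "group") {
  stopifnot(r_threshold > 0, r_threshold < 1)
  cm <- cor(table[vars], method = "spearman")
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  ord <- order(-abs(cm[pairs]))
  pairs <- pairs[ord, , drop = FALSE]
  retained <- vars
  dropped <- list()
  uni_aic <- setNames(rep(NA_real_, length(vars)), vars)
  get_aic <- function(v) {
    if (is.na(uni_aic[[v]]))
      uni_aic[[v]] <<- try_fit_glmm(table, v, group_field)$aic
    uni_aic[[v]]
  }
  for (p in seq_len(nrow(pairs))) {
    v1 <- vars[pairs[p, 1]]; v2 <- vars[pairs[p, 2]]
    r <- cm[pairs[p, 1], pairs[p, 2]]
    if (abs(r) <= r_threshold) break
    if (!(v1 %in% retained) || !(v2 %in% retained)) next
    loser <- if (get_aic(v1) <= get_aic(v2)) v2 else v1
    winner <- setdiff(c(v1, v2), loser)
    retained <- setdiff(retained, loser)
    dropped[[length(dropped) + 1L]] <-
      data.frame(var = loser, because_of = winner, r = r)
  }
  list(retained = retained,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(var = character(), because_of = character(),
                                 r = numeric()))
}

#' Linear-vs-quadratic shape screening
#'
#' Fits, per variable, a univariate GLMM with a linear term and one with
#' linear + quadratic terms; the quadratic form is kept only when it
#' improves AIC by at least `delta_aic` (default 2, boundary inclusive),
#' otherwise the simplest effect is used.
#'
#' @inheritParams collinearity_screen
#' @param delta_aic Improvement required to prefer the quadratic (default 2).
#' @return Named character vector, `"linear"` or `"quadratic"` per variable.
#' @export
shape_screen <- function(table, vars, group_field = "group", delta_aic = 2) {
  out <- setNames(character(length(vars)), vars)
  for (v in vars) {
    sq <- paste0(v, "_sq")
    table[[sq]] <- table[[v]]^2
    a_lin <- try_fit_glmm(table, v, group_field)$aic
    a_quad <- try_fit_glmm(table, c(v, sq), group_field)$aic
    out[[v]] <- if (a_lin - a_quad >= delta_aic) "quadratic" else "linear"
  }
  out
}

terms_for <- function(v, shapes) {
  if (!is.null(shapes) && identical(shapes[[v]], "quadratic"))
    c(v, paste0(v, "_sq")) else v
}

#' Akaike weights from AIC values
#'
#' `A_w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AIC_i - min(AIC)`: the relative likelihood of each
#' candidate model.
#'
#' @param aic Numeric vector of AIC values.
#' @return Weights summing to one.
#' @export
akaike_weights <- function(aic) {
  w <- exp(-(aic - min(aic)) / 2)
  w / sum(w)
}

#' Fit all covariate subsets and rank by AIC
#'
#' Enumerates every subset of the retained variables (2^k models,
#' including the intercept-only model), fits each as a random-intercept
#' binomial GLMM, ranks by AIC and computes Akaike weights
#' `A_w = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`. Non-converged fits
#' are excluded from the ranking with a warning. Quadratic variables
#' (from [shape_screen()]) contribute their linear and squared terms
#' together.
#'
#' @inheritParams fit_glmm
#' @param variables Retained covariate names (at most 12).
#' @param shapes Optional output of [shape_screen()].
#' @param aicc Use small-sample AICc instead of AIC (default FALSE).
#' @return Object of class `model_set`: list with `models` (ranked list
#'   of `hs_glmm`), `table` (data.frame `formula`, `k`, `loglik`, `aic`,
#'   `delta`, `weight`), `variables`, `shapes`, `group_field`.
#' @export
all_subsets <- function(table, variables, group_field = "group",
                        shapes = NULL, nAGQ = 15, aicc = FALSE) {
  k <- length(variables)
  if (k > 12) stop("more than 12 variables: 2^k enumeration refused")
  for (v in variables) {
    if (!is.null(shapes) && identical(shapes[[v]], "quadratic"))
      table[[paste0(v, "_sq")]] <- table[[v]]^2
  }
  models <- vector("list", 2^k)
  for (m in seq_len(2^k)) {
    inc <- variables[bitwAnd(m - 1L, bitwShiftL(1L, seq_len(k) - 1L)) > 0]
    terms <- unlist(lapply(inc, terms_for, shapes = shapes))
    models[[m]] <- try_fit_glmm(table, terms, group_field, nAGQ = nAGQ)
    models[[m]]$subset <- inc
  }
  conv <- vapply(models, function(f) f$converged, TRUE)
  if (any(!conv))
    warning(sum(!conv), " model(s) failed to converge and were excluded")
  models <- models[conv]
  if (!length(models)) stop("no model converged")
  aic <- vapply(models, function(f) {
    if (aicc) {
      kk <- length(f$coef) + 1
      f$aic + 2 * kk * (kk + 1) / (f$n - kk - 1)
    } else f$aic
  }, 0)
  ord <- order(aic)
  models <- models[ord]; aic <- aic[ord]
  delta <- aic - aic[1]
  w <- akaike_weights(aic)
  tab <- data.frame(
    formula = vapply(models, function(f)
      if (length(f$subset)) paste(f$subset, collapse = " + ") else "1", ""),
    k = vapply(models, function(f) length(f$coef) + 1L, 1L),
    loglik = vapply(models, function(f) f$loglik, 0),
    aic = aic, delta = delta, weight = w)
  structure(list(models = models, table = tab, variables = variables,
                 shapes = shapes, group_field = group_field,
                 criterion = if (aicc) "AICc" else "AIC"),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("model set: %d models over {%s}, ranked by %s\n",
              nrow(x$table), paste(x$variables, collapse = ", "), x$criterion))
  print(head(transform(x$table, aic = round(aic, 2), delta = round(delta, 2),
                       loglik = round(loglik, 2), weight = round(weight, 3)), 10))
  invisible(x)
}

#' 95% confidence set of models
#'
#' If the Akaike weight of the best model reaches `single_threshold`
#' (default 0.90) that model is used alone. Otherwise the confidence set
#' is the smallest AIC-ordered prefix of models whose cumulative weight
#' exceeds `cum_threshold` (default 0.95); weights are renormalized to
#' sum to one within the set.
#'
#' @param model_set A [all_subsets()] `model_set`.
#' @param cum_threshold Cumulative-weight threshold (default 0.95).
#' @param single_threshold Top-weight shortcut threshold (default 0.90).
#' @return Object of class `confidence_set`: `models`, `weights`
#'   (renormalized), `orig_weights`, `table`, plus the thresholds used.
#' @export
confidence_set <- function(model_set, cum_threshold = 0.95,
                           single_threshold = 0.90) {
  w <- model_set$table$weight
  if (w[1] >= single_threshold) {
    n_in <- 1L
  } else {
    n_in <- which(cumsum(w) > cum_threshold)[1]
    if (is.na(n_in)) n_in <- length(w)
  }
  idx <- seq_len(n_in)
  structure(list(models = model_set$models[idx],
                 orig_weights = w[idx],
                 weights = w[idx] / sum(w[idx]),
                 table = model_set$table[idx, , drop = FALSE],
                 group_field = model_set$group_field,
                 shapes = model_set$shapes,
                 cum_threshold = cum_threshold,
                 single_threshold = single_threshold),
            class = "confidence_set")
}

#' Model-averaged coefficients and presence-probability prediction
#'
#' Averages each coefficient over the confidence set using the
#' renormalized Akaike weights, substituting zero where a model omits a
#' variable (full-model averaging, which shrinks rarely selected
#' coefficients toward zero). Prediction applies the stored normalization
#' constants to raw covariates, forms the linear predictor and returns
#' `Pr = plogis(lp)`.
#'
#' @param cset A [confidence_set()].
#' @param norm Normalization constants, `list(mean, sd)` per covariate
#'   (e.g. `attr(normalize_covariates(x, vars), "norm")`).
#' @return Object of class `avg_model`: `coef` (named, incl. `INT`),
#'   `weights`, `norm`, `shapes`.
#' @export
average_model <- function(cset, norm) {
  all_terms <- unique(unlist(lapply(cset$models, function(f) names(f$coef))))
  coef <- setNames(numeric(length(all_terms)), all_terms)
  for (i in seq_along(cset$models)) {
    f <- cset$models[[i]]
    coef[names(f$coef)] <- coef[names(f$coef)] + cset$weights[i] * f$coef
  }
  ## unconditional SE (model-selection uncertainty included): absent
  ## coefficients enter as 0 with zero sampling variance
  se <- setNames(numeric(length(all_terms)), all_terms)
  for (i in seq_along(cset$models)) {
    f <- cset$models[[i]]
    bi <- sei <- setNames(numeric(length(all_terms)), all_terms)
    bi[names(f$coef)] <- f$coef
    sei[names(f$coef)] <- f$se
    se <- se + cset$weights[i] * sqrt(sei^2 + (bi - coef)^2)
  }
  structure(list(coef = coef, se = se, weights = cset$weights, norm = norm,
                 shapes = cset$shapes), class = "avg_model")
}

#' @export
print.avg_model <- function(x, ...) {
  cat(sprintf("averaged model over %d model(s)\n", length(x$weights)))
  print(round(x$coef, 4))
  invisible(x)
}

#' @describeIn average_model Predict presence probability from raw
#'   covariates; rows with any missing covariate get `NA`.
#' @param object An `avg_model`.
#' @param newdata data.frame of raw (unnormalized) covariates.
#' @param ... Unused.
#' @export
predict.avg_model <- function(object, newdata, ...) {
  lp <- rep(object$coef[["INT"]], nrow(newdata))
  for (term in setdiff(names(object$coef), "INT")) {
    sq <- endsWith(term, "_sq")
    v <- if (sq) sub("_sq$", "", term) else term
    if (!v %in% names(newdata)) stop("covariate missing from newdata: ", v)
    if (is.null(object$norm$mean[[v]]))
      stop("no normalization constants for covariate ", v)
    z <- (newdata[[v]] - object$norm$mean[[v]]) / object$norm$sd[[v]]
    lp <- lp + object$coef[[term]] * (if (sq) z^2 else z)
  }
  plogis(lp)
}
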