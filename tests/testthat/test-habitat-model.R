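test_that("normalization yields exact z-scores and invertible constants", {
  set.seed(1)
  d <- data.frame(a = rnorm(50, 10, 3), b = runif(50), c = rep(1, 50))
  n <- normalize_covariates(d, c("a", "b"))
  expect_equal(mean(n$a), 0, tolerance = 1e-9)
  expect_equal(sd(n$b), 1, tolerance = 1e-9)
  k <- attr(n, "norm")
  expect_equal(n$a * k$sd[["a"]] + k$mean[["a"]], d$a, tolerance = 1e-12)
  # already-standardized input passes through unchanged
  z <- data.frame(a = as.numeric(scale(rnorm(40))))
  expect_equal(normalize_covariates(z, "a")$a, z$a, tolerance = 1e-9)
  expect_error(normalize_covariates(d, c("a", "c")), "c")
})

test_that("collinearity screen drops the less informative of correlated pairs", {
  d <- make_glmm_data(400, c(-0.2, 0.8, 0, 0), 0.3, 8, seed = 11)
  d$x4 <- d$x1  # exact duplicate, r = 1
  scr <- collinearity_screen(d, c("x1", "x2", "x3", "x4"))
  expect_length(setdiff(c("x1", "x4"), scr$retained), 1)
  expect_true(all(c("x2", "x3") %in% scr$retained))

  # independent noise: everything retained
  scr2 <- collinearity_screen(d, c("x1", "x2", "x3"))
  expect_setequal(scr2$retained, c("x1", "x2", "x3"))

  # three mutually correlated variables: no retained pair above threshold
  set.seed(5)
  base <- rnorm(400)
  d$y1 <- base + rnorm(400, 0, 0.3)
  d$y2 <- base + rnorm(400, 0, 0.3)
  d$y3 <- base + rnorm(400, 0, 0.3)
  scr3 <- collinearity_screen(d, c("y1", "y2", "y3"))
  expect_gte(length(scr3$retained), 1)
  if (length(scr3$retained) > 1) {
    cm <- cor(d[scr3$retained], method = "spearman")
    expect_true(all(abs(cm[upper.tri(cm)]) <= 0.6))
  }
})

test_that("shape screen keeps the simplest effect unless AIC favours curvature", {
  set.seed(21)
  n <- 2000
  g <- factor(rep(1:10, each = n / 10))
  x <- rnorm(n)
  b <- rnorm(10, 0, 0.3)
  lin <- data.frame(response = rbinom(n, 1, plogis(0.8 * x + b[g])),
                    x = x, group = g)
  expect_equal(unname(shape_screen(lin, "x")), "linear")
  hump <- data.frame(response = rbinom(n, 1, plogis(1.5 - 1.2 * x^2 + b[g])),
                     x = x, group = g)
  expect_equal(unname(shape_screen(hump, "x")), "quadratic")
})

test_that("GLMM with vanishing group variance matches the IRLS oracle", {
  # on data generated without group effects the variance estimate hits
  # the boundary in most replicates; at the boundary the marginal
  # likelihood reduces to ordinary logistic regression
  worst <- 0; at_boundary <- 0
  for (r in 1:20) {
    d <- make_glmm_data(400, c(0.3, 0.8, -0.5), sigma = 0, n_groups = 8,
                        seed = 100 + r)
    f <- fit_glmm(d, c("x1", "x2"))
    if (f$sigma < 1e-4) {
      at_boundary <- at_boundary + 1
      ora <- irls_logistic(cbind(1, d$x1, d$x2), d$response)
      worst <- max(worst, max(abs(f$coef - ora)))
    }
  }
  expect_gte(at_boundary, 10)
  expect_lt(worst, 1e-3)
})

test_that("intercept-only GLMM on balanced data estimates INT near zero", {
  set.seed(31)
  d <- data.frame(response = rep(0:1, 250), group = factor(rep(1:5, 100)))
  f <- fit_glmm(d, character(0))
  expect_lt(abs(f$coef[["INT"]]), 0.05)
  expect_equal(f$aic, -2 * f$loglik + 2 * 2, tolerance = 1e-9)
  expect_error(fit_glmm(transform(d, response = 1), character(0)), "one class")
  expect_error(fit_glmm(transform(d, group = factor(1)), character(0)),
               "2 groups")
})

test_that("GLMM recovers known coefficients within Wald coverage", {
  hits <- 0; total <- 0
  for (r in 1:100) {
    d <- make_glmm_data(4000, c(-0.3, 0.6), sigma = 0.5, n_groups = 20,
                        seed = 5000 + r)
    f <- fit_glmm(d, "x1")
    ci <- f$coef[["x1"]] + c(-1.96, 1.96) * f$se[["x1"]]
    total <- total + 1
    if (ci[1] <= 0.6 && 0.6 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / total, 0.90)
})

test_that("all-subsets enumeration ranks models and weights them", {
  d <- make_glmm_data(500, c(-0.2, 0.9, 0, 0), 0.3, 8, seed = 42)
  ms <- all_subsets(d, c("x1", "x2", "x3"))
  expect_equal(nrow(ms$table), 8)  # 2^3 including intercept-only
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-9)
  expect_true(!is.unsorted(ms$table$aic))
  expect_equal(ms$table$delta, ms$table$aic - min(ms$table$aic))
  # the informative variable is in the best model
  expect_true(grepl("x1", ms$table$formula[1]))
  expect_error(all_subsets(d, sprintf("v%02d", 1:13)), "12")
})

test_that("Akaike weights follow the exp(-delta/2) normalization", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.731, 0.269))
  # equal AICs split evenly even with far-worse companions
  w4 <- akaike_weights(c(50, 50, 90, 95))
  expect_equal(w4[1], w4[2], tolerance = 1e-12)
  expect_equal(w4[1], 0.5, tolerance = 1e-6)
  expect_equal(sum(akaike_weights(rnorm(20, 200, 10))), 1, tolerance = 1e-12)
})

fake_model_set <- function(weights) {
  models <- lapply(seq_along(weights), function(i)
    structure(list(terms = letters[i], coef = c(INT = 0), se = c(INT = 1),
                   aic = 0, converged = TRUE), class = "hs_glmm"))
  structure(list(models = models,
                 table = data.frame(formula = letters[seq_along(weights)],
                                    k = 2, loglik = 0, aic = 0,
                                    delta = 0, weight = weights),
                 group_field = "group", shapes = NULL),
            class = "model_set")
}

test_that("confidence set applies the 0.90 shortcut and minimal 0.95 prefix", {
  cs1 <- confidence_set(fake_model_set(c(0.96, 0.03, 0.01)))
  expect_length(cs1$models, 1)
  expect_equal(cs1$weights, 1)

  cs2 <- confidence_set(fake_model_set(c(0.5, 0.3, 0.16, 0.04)))
  expect_length(cs2$models, 3)  # cumulative 0.96 > 0.95
  expect_equal(sum(cs2$weights), 1, tolerance = 1e-12)
  # minimality: dropping the last member leaves cumulative weight <= 0.95
  expect_lte(sum(cs2$orig_weights[-3]), 0.95)

  cs3 <- confidence_set(fake_model_set(c(0.91, 0.09)))
  expect_length(cs3$models, 1)
})

test_that("model averaging uses zero substitution and predicts with plogis", {
  d <- make_glmm_data(600, c(-0.3, 0.9, 0), 0.3, 8, seed = 7)
  nt <- normalize_covariates(d, c("x1", "x2"))
  ms <- all_subsets(nt, c("x1", "x2"))
  cs <- confidence_set(ms)
  avg <- average_model(cs, attr(nt, "norm"))
  expect_equal(sum(avg$weights), 1, tolerance = 1e-12)
  # zero substitution shrinks: averaged magnitude below the per-model max
  for (v in intersect(names(avg$coef), c("x1", "x2"))) {
    per_model <- vapply(cs$models, function(f)
      if (v %in% names(f$coef)) abs(f$coef[[v]]) else 0, 0)
    expect_lte(abs(avg$coef[[v]]), max(per_model) + 1e-12)
  }
  # closed-form checks of the inverse-logit
  flat <- avg; flat$coef[] <- 0
  expect_equal(predict(flat, d[1:5, ]), rep(0.5, 5))
  flat$coef[["INT"]] <- log(3)
  expect_equal(predict(flat, d[1:5, ]), rep(0.75, 5), tolerance = 1e-12)
  # single-model set: averaged predictions equal that model's own
  cs1 <- cs; cs1$models <- cs$models[1]; cs1$weights <- 1
  avg1 <- average_model(cs1, attr(nt, "norm"))
  f1 <- cs$models[[1]]
  lp <- rep(f1$coef[["INT"]], 10)
  for (term in setdiff(names(f1$coef), "INT"))
    lp <- lp + f1$coef[[term]] * nt[[term]][1:10]
  expect_equal(predict(avg1, d[1:10, ]), plogis(lp), tolerance = 1e-9)
})

test_that("the generating covariate subset ranks close to the best model", {
  # three informative plus three independent noise covariates: the true
  # subset should sit within 2 AIC of the best subset in most replicates
  vars <- paste0("x", 1:6)
  true_sub <- c("x1", "x2", "x3")
  gaps <- vapply(1:20, function(r) {
    d <- make_glmm_data(2000, c(-0.4, 0.8, -0.7, 0.5, 0, 0, 0), sigma = 0.5,
                        n_groups = 10, seed = 7100 + r)
    ms <- suppressWarnings(all_subsets(d, vars))
    hit <- vapply(ms$models, function(f) setequal(f$subset, true_sub), TRUE)
    min(vapply(ms$models[hit], function(f) f$aic, 0)) - min(ms$table$aic)
  }, 0)
  expect_gte(mean(gaps <= 2), 0.8)
})
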