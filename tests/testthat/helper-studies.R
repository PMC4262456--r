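# Heavier simulation studies shared across test files; computed once per
# test run and cached. Conditions mirror the package's documented
# recovery design: 3000 survey bins (10 campaigns x 300), six candidate
# covariates of which three informative, campaign sigma = 0.5, bins
# spaced ~40 km so each falls in its own 0.25 degree cell.

recovery_vars <- c("Chloa", "SST", "SLA", "Bathy", "SST_grad", "SLA_grad")
recovery_truth_beta <- c(Chloa = 0.8, SST = -0.7, SLA = 0, Bathy = 0.5,
                         SST_grad = 0, SLA_grad = 0)

recovery_study <- function(n_reps = 20) {
  if (!is.null(fixture_env$recovery)) return(fixture_env$recovery)
  reps <- lapply(seq_len(n_reps), function(r) {
    ss <- generate_seascape(c(40, 50, -24, -14), 2008:2009, 9:12,
                            seed = 300 + r)
    truth <- truth_record(c(INT = -0.5, Chloa = 0.8, SST = -0.7, Bathy = 0.5),
                          sigma = 0.5)
    sv <- simulate_survey(ss, list(tx = truth), n_campaigns = 10,
                          bins_per_campaign = 300, seed = 600 + r,
                          bin_spacing_km = 40)
    occ <- attach_covariates(surveys_to_occurrence(sv, ss$grid, "tx")$rows, ss)
    nt <- normalize_covariates(occ, recovery_vars)
    scr <- collinearity_screen(nt, recovery_vars)
    # linear effects throughout: the generating model is linear and the
    # screened candidate set is exactly the six linear covariates
    ms <- suppressWarnings(all_subsets(nt, scr$retained))
    cs <- confidence_set(ms)
    avg <- average_model(cs, attr(nt, "norm"))
    est <- setNames(rep(0, length(recovery_vars)), recovery_vars)
    for (v in intersect(names(avg$coef), recovery_vars)) est[v] <- avg$coef[[v]]
    # AIC gap between the exact generating subset and the best model
    true_sub <- c("Chloa", "SST", "Bathy")
    hit <- vapply(ms$models, function(f) setequal(f$subset, true_sub), TRUE)
    aic_gap <- if (any(hit))
      min(vapply(ms$models[hit], function(f) f$aic, 0)) - min(ms$table$aic)
    else NA_real_
    list(est = est, aic_gap = aic_gap, retained = scr$retained,
         table = nt, cset = cs)
  })
  fixture_env$recovery <- reps
  reps
}

# Null study: survey responses independent of the covariates offered to
# the model (intercept-only truth with a campaign random intercept).
noise_cv_study <- function(n_runs = 20) {
  if (!is.null(fixture_env$noise_cv)) return(fixture_env$noise_cv)
  vars <- c("Chloa", "SST", "Bathy")
  out <- lapply(seq_len(n_runs), function(r) {
    ss <- generate_seascape(c(42, 46, -22, -18), 2008, 9:12, seed = 40 + r)
    truth <- truth_record(c(INT = -0.2), sigma = 0.3)
    sv <- simulate_survey(ss, list(tx = truth), n_campaigns = 5,
                          bins_per_campaign = 80, seed = 70 + r,
                          bin_spacing_km = 30)
    occ <- attach_covariates(surveys_to_occurrence(sv, ss$grid, "tx")$rows, ss)
    nt <- normalize_covariates(occ, vars)
    ms <- suppressWarnings(all_subsets(nt, vars))
    cs <- confidence_set(ms)
    suppressMessages(
      cross_validate(nt, cs, n_reps = 25, seed = 900 + r))
  })
  fixture_env$noise_cv <- out
  out
}

# Overlap contrast study: taxa A and B share identical truth, taxon C is
# opposed; estimated from survey data, mapped, thresholded and overlapped.
overlap_contrast_study <- function(n_reps = 50) {
  if (!is.null(fixture_env$overlap_contrast)) return(fixture_env$overlap_contrast)
  vars <- c("Chloa", "SST")
  out <- vapply(seq_len(n_reps), function(r) {
    ss <- generate_seascape(c(42, 46, -22, -18), 2008, 9:12, seed = 7000 + r)
    same <- c(INT = 0, Chloa = 1, SST = -0.8)
    opposed <- c(INT = 0, Chloa = -1, SST = 0.8)
    truths <- list(A = truth_record(same, 0.3), B = truth_record(same, 0.3),
                   C = truth_record(opposed, 0.3))
    sv <- simulate_survey(ss, truths, n_campaigns = 4, bins_per_campaign = 90,
                          seed = 8000 + r, bin_spacing_km = 30)
    fits <- lapply(names(truths), function(tx) {
      occ <- attach_covariates(surveys_to_occurrence(sv, ss$grid, tx)$rows, ss)
      nt <- normalize_covariates(occ, vars)
      ms <- suppressWarnings(all_subsets(nt, vars))
      cs <- confidence_set(ms)
      avg <- average_model(cs, attr(nt, "norm"))
      scores <- predict(avg, nt_raw_covariates(nt, attr(nt, "norm"), vars))
      list(avg = avg, p_th = roc_threshold(nt$response, scores)$p_th)
    })
    names(fits) <- names(truths)
    stacks <- lapply(fits, function(f) predict_maps(f$avg, ss))
    p_th <- vapply(fits, function(f) f$p_th, 0)
    sm <- suitability_maps(stacks, p_th)
    sm$overlap_mean["A", "B"] > sm$overlap_mean["A", "C"]
  }, TRUE)
  fixture_env$overlap_contrast <- out
  out
}

# rebuild raw covariates from a normalized table so predict() can be used
nt_raw_covariates <- function(nt, norm, vars) {
  raw <- nt
  for (v in vars) raw[[v]] <- nt[[v]] * norm$sd[[v]] + norm$mean[[v]]
  raw
}
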