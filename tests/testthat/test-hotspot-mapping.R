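test_that("ROC threshold maximizes sensitivity plus specificity", {
  # perfectly separated scores
  r1 <- roc_threshold(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(r1$sensitivity, 1)
  expect_equal(r1$specificity, 1)
  # worked example: threshold lands on the lowest presence score
  r2 <- roc_threshold(c(1, 1, 0, 0), c(0.9, 0.6, 0.55, 0.2))
  expect_equal(r2$p_th, 0.6)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 1)
  # degenerate: all scores equal -> J = 1 at the single candidate
  r3 <- roc_threshold(c(1, 0, 1), c(0.4, 0.4, 0.4))
  expect_equal(r3$sensitivity + r3$specificity, 1)
  expect_error(roc_threshold(c(1, 1), c(0.1, 0.2)), "both classes")
  # exhaustive-scan oracle on random instances, ties to lowest threshold
  set.seed(12)
  for (r in 1:20) {
    n <- sample(10:80, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)
    got <- roc_threshold(labels, scores)
    ora <- roc_scan_oracle(labels, scores)
    expect_equal(got$sensitivity + got$specificity, ora$j, tolerance = 1e-12)
    expect_equal(got$p_th, ora$p_th)
  }
})

test_that("binarization is strict and propagates missing cells", {
  m <- matrix(c(0.4, 0.6, 0.5, NA), 2, 2)
  b <- binarize(m, 0.5)
  expect_equal(b[1, 1], 0L)
  expect_equal(b[2, 1], 1L)
  expect_equal(b[1, 2], 0L)   # exactly at the threshold: unsuitable
  expect_true(is.na(b[2, 2]))
  expect_error(binarize(m, 0), "p_th")
})

test_that("suitability index is the exact per-cell sum of taxon binaries", {
  b1 <- matrix(c(1, 0, 1, 0), 2, 2)
  b2 <- matrix(c(1, 0, 0, 1), 2, 2)
  b3 <- matrix(1, 2, 2)
  b4 <- matrix(0, 2, 2)
  idx <- suitability_index(list(a = b1, b = b2, c = b3, d = b4))
  expect_equal(idx, b1 + b2 + b3 + b4)
  expect_equal(range(idx), c(1, 3))
  expect_equal(suitability_index(list(b3, b3, b3, b3))[1, 1], 4)
  expect_equal(suitability_index(list(b4, b4, b4, b4))[2, 2], 0)
  expect_error(suitability_index(list(b1, matrix(0, 3, 3))), "same grid")
})

test_that("pairwise overlap follows the shared-cell convention", {
  A <- matrix(0L, 4, 4); B <- matrix(0L, 4, 4)
  A[1, 1:3] <- 1L          # |A| = 3
  B[1, 2:3] <- 1L; B[2, 1] <- 1L  # |B| = 3, |A&B| = 2
  expect_equal(pairwise_overlap(A, B), 2 / 6)
  expect_equal(pairwise_overlap(A, B, "jaccard"), 2 / 4)
  expect_equal(pairwise_overlap(A, B), pairwise_overlap(B, A))
  # disjoint and identical layers
  D <- matrix(0L, 4, 4); D[4, 4] <- 1L
  expect_equal(pairwise_overlap(A, D), 0)
  expect_equal(pairwise_overlap(A, A), 0.5)
  expect_equal(pairwise_overlap(A, A, "jaccard"), 1)
  E <- matrix(0L, 4, 4)
  expect_error(pairwise_overlap(E, E), "undefined")
  # monotonicity: adding a shared cell never decreases overlap,
  # adding an unshared cell never increases it
  A2 <- A; B2 <- B; A2[3, 3] <- B2[3, 3] <- 1L
  expect_gte(pairwise_overlap(A2, B2), pairwise_overlap(A, B))
  A3 <- A; A3[4, 1] <- 1L
  expect_lte(pairwise_overlap(A3, B), pairwise_overlap(A, B))
})

test_that("prediction stacks summarize months across years", {
  ss <- small_seascape()
  norm <- hotspotr:::seascape_norm_constants(ss)
  avg <- structure(list(coef = c(INT = -0.3, Chloa = 0.9, SST = -0.5),
                        se = c(INT = 0, Chloa = 0, SST = 0),
                        weights = 1,
                        norm = list(mean = as.list(norm$mean),
                                    sd = as.list(norm$sd)),
                        shapes = NULL), class = "avg_model")
  st <- predict_maps(avg, ss)
  expect_length(st$prob, 8)
  expect_true(all(unlist(st$prob) >= 0 & unlist(st$prob) <= 1))
  # mean layer bounded by the yearly layers cell-wise
  for (mm in names(st$monthly_mean)) {
    keys <- grep(paste0("-", mm, "$"), names(st$prob), value = TRUE)
    lo <- pmin(st$prob[[keys[1]]], st$prob[[keys[2]]])
    hi <- pmax(st$prob[[keys[1]]], st$prob[[keys[2]]])
    expect_true(all(st$monthly_mean[[mm]] >= lo - 1e-12))
    expect_true(all(st$monthly_mean[[mm]] <= hi + 1e-12))
    expect_true(all(st$monthly_sd[[mm]] >= 0))
  }
  # intercept-only model: spatially flat probability layer
  flat <- avg; flat$coef <- c(INT = 0.4)
  stf <- predict_maps(flat, ss)
  expect_equal(max(stf$prob[[1]]) - min(stf$prob[[1]]), 0)
  expect_equal(stf$monthly_sd[["09"]], matrix(0, ss$grid$nlat, ss$grid$nlon))
  expect_error(predict_maps(avg, ss, months = 9, years = 1999), "1999")
})

test_that("suitability maps combine taxa into index and overlap summaries", {
  ss <- small_seascape()
  norm <- hotspotr:::seascape_norm_constants(ss)
  mk <- function(coef) structure(
    list(coef = coef, se = coef * 0, weights = 1,
         norm = list(mean = as.list(norm$mean), sd = as.list(norm$sd)),
         shapes = NULL), class = "avg_model")
  stacks <- list(
    frig = predict_maps(mk(c(INT = 0, Chloa = 1)), ss),
    tern = predict_maps(mk(c(INT = 0, Chloa = 1)), ss),       # same truth
    booby = predict_maps(mk(c(INT = 0, Chloa = -1)), ss),     # opposed
    sub = predict_maps(mk(c(INT = 0, SST = 0.8)), ss))
  p_th <- c(frig = 0.5, tern = 0.5, booby = 0.5, sub = 0.5)
  sm <- suitability_maps(stacks, p_th)
  yr <- names(sm$binary)[1]
  expect_equal(sm$index[[yr]],
               Reduce(`+`, sm$binary[[yr]]))
  expect_true(all(unlist(sm$index) %in% 0:4))
  # overlap matrix symmetric, in [0, 0.5] under the literal rule
  expect_equal(sm$overlap_mean, t(sm$overlap_mean))
  off <- sm$overlap_mean[upper.tri(sm$overlap_mean)]
  expect_true(all(off >= 0 & off <= 0.5))
  # identical truths overlap maximally; opposed truths much less
  expect_equal(sm$overlap_mean["frig", "tern"], 0.5)
  expect_gt(sm$overlap_mean["frig", "tern"], sm$overlap_mean["frig", "booby"])
})
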