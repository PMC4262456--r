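#' Monthly presence-probability maps with across-year mean and SD
#'
#' Applies an averaged model cell-wise to every requested (month, year)
#' layer of the seascape, then summarizes each month across years: the
#' mean layer is the expected seasonal pattern and the cell-wise SD is an
#' index of habitat stability (low SD = persistent habitat).
#'
#' @param avg_model An [average_model()] object.
#' @param seascape A `seascape`.
#' @param months,years Periods to predict; default all in the seascape.
#' @return Object of class `prediction_stack`: `prob[[key]]` probability
#'   matrices per `"YYYY-MM"`, `monthly_mean[[mm]]` and `monthly_sd[[mm]]`
#'   across years, plus `grid`, `months`, `years`.
#' @export
predict_maps <- function(avg_model, seascape, months = seascape$months,
                         years = seascape$years) {
  grid <- seascape$grid
  prob <- list()
  for (yr in years) for (mo in months) {
    key <- seascape_key(yr, mo)
    if (!key %in% names(seascape$dynamic))
      stop("missing environmental layer for period ", key)
    cov <- seascape_covariates(seascape, mo, yr)
    p <- predict(avg_model, cov)
    prob[[key]] <- layer_from_cells(grid, cov$cell, p)
  }
  monthly_mean <- monthly_sd <- list()
  for (mo in months) {
    keys <- seascape_key(years, mo)
    stack <- simplify2array(prob[keys])
    mm <- sprintf("%02d", mo)
    strip <- function(m) { dimnames(m) <- NULL; m }
    monthly_mean[[mm]] <- strip(apply(stack, 1:2, mean))
    monthly_sd[[mm]] <- if (length(keys) > 1) strip(apply(stack, 1:2, sd))
                        else matrix(0, grid$nlat, grid$nlon)
  }
  structure(list(prob = prob, monthly_mean = monthly_mean,
                 monthly_sd = monthly_sd, grid = grid,
                 months = months, years = years),
            class = "prediction_stack")
}

layer_from_cells <- function(grid, cells, values) {
  m <- matrix(NA_real_, grid$nlat, grid$nlon)
  ri <- (cells - 1L) %/% grid$nlon + 1L   # cell ids are row-major from SW
  ci <- (cells - 1L) %% grid$nlon + 1L
  m[cbind(ri, ci)] <- values
  m
}

#' ROC threshold maximizing sensitivity + specificity
#'
#' Scans every distinct score as a candidate threshold (a prediction
#' greater than or equal to the threshold counts as presence) and picks
#' the one maximizing Youden's J = sensitivity + specificity - 1;
#' ties go to the lowest threshold.
#'
#' @param labels Binary vector (both classes present).
#' @param scores Predicted probabilities.
#' @return list with `p_th`, `sensitivity`, `specificity`.
#' @export
roc_threshold <- function(labels, scores) {
  if (length(unique(labels)) < 2) stop("both classes required")
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- NULL
  for (t in cand) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / n1
    spec <- sum(!pred & labels == 0) / n0
    if (is.null(best) || sens + spec > best$sensitivity + best$specificity + 1e-12)
      best <- list(p_th = t, sensitivity = sens, specificity = spec)
  }
  best
}

#' Binarize a probability layer at a threshold
#'
#' Cells with probability strictly greater than `p_th` are suitable (1),
#' cells at or below are unsuitable (0); missing cells stay missing. Note
#' the strict inequality, which differs from the `>=` rule used when the
#' threshold itself is selected.
#'
#' @param prob_layer Numeric matrix of probabilities.
#' @param p_th Threshold in (0, 1).
#' @return Integer matrix of 0/1 with `NA` preserved.
#' @export
binarize <- function(prob_layer, p_th) {
  stopifnot(p_th > 0, p_th < 1)
  out <- ifelse(prob_layer > p_th, 1L, 0L)
  out[is.na(prob_layer)] <- NA_integer_
  out
}

#' Multi-taxa suitability index
#'
#' Cell-wise count of taxa for which a cell is suitable: the sum of the
#' per-taxon binary layers, ranging from 0 (suitable for none) to the
#' number of taxa (suitable for all).
#'
#' @param binaries Named list of 0/1 matrices on a shared grid.
#' @return Integer matrix (NA where any taxon layer is NA).
#' @export
suitability_index <- function(binaries) {
  dims <- lapply(binaries, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("taxon layers are not on the same grid")
  Reduce(`+`, binaries)
}

#' Pairwise spatial overlap of two suitability layers
#'
#' Literal convention (default): cells suitable for both taxa divided by
#' the sum of cells suitable for each, `|A&B| / (|A| + |B|)`, which lies
#' in `[0, 0.5]` (0.5 = identical ranges). `method = "jaccard"` uses the
#' union denominator `|A&B| / |A|B|` instead (range `[0, 1]`). Cells
#' missing in either layer are excluded.
#'
#' @param bin_a,bin_b 0/1 matrices on a shared grid.
#' @param method `"literal"` (default) or `"jaccard"`.
#' @return Overlap proportion.
#' @export
pairwise_overlap <- function(bin_a, bin_b, method = c("literal", "jaccard")) {
  method <- match.arg(method)
  if (!identical(dim(bin_a), dim(bin_b))) stop("layers are not on the same grid")
  ok <- !is.na(bin_a) & !is.na(bin_b)
  a <- bin_a[ok] == 1; b <- bin_b[ok] == 1
  if (!any(a | b)) stop("overlap undefined: no suitable cell in either layer")
  both <- sum(a & b)
  if (method == "literal") both / (sum(a) + sum(b)) else both / sum(a | b)
}

#' Per-year suitability maps, index and overlap matrix
#'
#' For each year, takes the seasonal mean probability over the breeding
#' months, binarizes it at each taxon's threshold, sums the binaries into
#' the multi-taxa index and computes all pairwise overlaps; then
#' summarizes the index (cell-wise mean and SD across years) and each
#' pair's overlap (mean and SD across years).
#'
#' @param stacks Named list of [predict_maps()] stacks, one per taxon.
#' @param p_th Named numeric vector of per-taxon thresholds.
#' @param overlap_method Passed to [pairwise_overlap()].
#' @return Object of class `suitability_maps`: `binary[[year]][[taxon]]`,
#'   `index[[year]]`, `index_mean`, `index_sd`, `overlap_mean`,
#'   `overlap_sd` (symmetric matrices), `overlap_by_year`, `p_th`.
#' @export
suitability_maps <- function(stacks, p_th, overlap_method = "literal") {
  taxa <- names(stacks)
  stopifnot(length(taxa) >= 2, all(taxa %in% names(p_th)))
  years <- stacks[[1]]$years; months <- stacks[[1]]$months
  binary <- index <- list()
  n_pair <- choose(length(taxa), 2)
  ov_year <- array(NA_real_, c(length(taxa), length(taxa), length(years)),
                   dimnames = list(taxa, taxa, years))
  for (yi in seq_along(years)) {
    yr <- years[yi]
    bins <- list()
    for (tx in taxa) {
      keys <- seascape_key(yr, months)
      seasonal <- apply(simplify2array(stacks[[tx]]$prob[keys]), 1:2, mean)
      bins[[tx]] <- binarize(seasonal, p_th[[tx]])
    }
    binary[[as.character(yr)]] <- bins
    index[[as.character(yr)]] <- suitability_index(bins)
    for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
      if (i < j) {
        ov <- pairwise_overlap(bins[[i]], bins[[j]], overlap_method)
        ov_year[i, j, yi] <- ov_year[j, i, yi] <- ov
      }
    }
  }
  idx_stack <- simplify2array(index)
  structure(list(
    binary = binary, index = index,
    index_mean = apply(idx_stack, 1:2, mean),
    index_sd = if (length(years) > 1) apply(idx_stack, 1:2, sd)
               else matrix(0, nrow(idx_stack), ncol(idx_stack)),
    overlap_by_year = ov_year,
    overlap_mean = apply(ov_year, 1:2, mean),
    overlap_sd = if (length(years) > 1) apply(ov_year, 1:2, sd)
                 else matrix(0, length(taxa), length(taxa),
                             dimnames = dimnames(ov_year)[1:2]),
    p_th = p_th, method = overlap_method), class = "suitability_maps")
}

#' @export
print.suitability_maps <- function(x, ...) {
  cat(sprintf("suitability maps: %d taxa x %d year(s); index range %d..%d\n",
              dim(x$overlap_mean)[1], length(x$index),
              min(x$index_mean, na.rm = TRUE), max(unlist(x$index), na.rm = TRUE)))
  cat("mean pairwise overlap (", x$method, "):\n", sep = "")
  print(round(x$overlap_mean, 3))
  invisible(x)
}
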