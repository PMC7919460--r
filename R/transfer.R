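#' Mobility-oriented parity (MOP) extrapolation analysis
#'
#' Quantifies how environmentally similar each projection cell is to the
#' calibration region. Covariates are standardized by the reference mean
#' and standard deviation; each projection cell's mean Euclidean distance
#' to its nearest `reference_fraction` of reference points is rescaled to
#' a [0, 1] similarity (1 = inside the reference cloud). Cells outside
#' the univariate reference range of any covariate are flagged as strict
#' extrapolation and forced to similarity 0.
#'
#' @param reference Numeric matrix of calibration-region covariate
#'   vectors (named columns), e.g. `land_matrix(calibration_env)`.
#' @param projection [env_stack()] to assess (same covariate set).
#' @param reference_fraction Fraction of reference points defining the
#'   nearest set (default 0.1).
#' @param max_reference Reference subsample cap (seed-fixed) keeping the
#'   distance computation tractable.
#' @return A `mop_map` grid map with fields `values` (similarity) and
#'   `strict` (logical matrix).
#' @export
mop <- function(reference, projection, reference_fraction = 0.1,
                max_reference = 2000) {
  stopifnot(is.matrix(reference), inherits(projection, "env_stack"))
  miss <- setdiff(colnames(reference), layer_names(projection))
  if (length(miss))
    stop("projection stack lacks covariate(s): ", paste(miss, collapse = ", "))
  if (nrow(reference) < ceiling(1 / reference_fraction))
    stop("reference has ", nrow(reference), " points; need at least ",
         ceiling(1 / reference_fraction), " for fraction ",
         reference_fraction)
  ref_lo <- apply(reference, 2, min)
  ref_hi <- apply(reference, 2, max)
  mu <- colMeans(reference)
  sdev <- pmax(apply(reference, 2, stats::sd), 1e-12)
  ref_all <- reference
  if (nrow(reference) > max_reference) {
    keep <- withr::with_seed(1L, sample(nrow(reference), max_reference))
    reference <- reference[keep, , drop = FALSE]
  }
  refz <- sweep(sweep(reference, 2, mu), 2, sdev, `/`)
  k <- max(1L, ceiling(reference_fraction * nrow(refz)))

  cells <- land_cells(projection)
  pv <- land_matrix(projection, cells)[, colnames(ref_all), drop = FALSE]
  strict_v <- rowSums(sweep(pv, 2, ref_lo, `<`) |
                      sweep(pv, 2, ref_hi, `>`)) > 0
  pz <- sweep(sweep(pv, 2, mu), 2, sdev, `/`)

  dists <- numeric(nrow(pz))
  ref_sq <- rowSums(refz^2)
  chunk <- 1000L
  for (s in seq(1, nrow(pz), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pz))
    block <- pz[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), ref_sq, `+`) - 2 * block %*% t(refz)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    dists[s:e] <- apply(d, 1, function(r) mean(sort.int(r,
                                                        partial = k)[1:k]))
  }
  dmax <- max(dists[!strict_v], 0)
  sim <- if (dmax > 0) 1 - dists / dmax else rep(1, length(dists))
  sim <- pmin(pmax(sim, 0), 1)
  sim[strict_v] <- 0

  v <- matrix(NA_real_, projection$grid$rows, projection$grid$cols)
  v[cells] <- sim
  st <- matrix(FALSE, projection$grid$rows, projection$grid$cols)
  st[cells] <- strict_v
  grid_map(v, projection$grid, "mop_map", strict = st)
}

#' Occurrence-based restriction (OBR) of a binary map
#'
#' Converts a niche estimate toward a realized distribution: connected
#' suitable patches (8-neighbor connectivity) are kept only if they
#' contain at least one occurrence or lie within the cutoff distance of
#' one, where the cutoff is the maximum nearest-neighbor distance among
#' the occurrence points. Contractive and idempotent. With fewer than
#' two occurrences the cutoff is undefined and the map is returned
#' unchanged with a warning.
#'
#' @param binary A `binary_map`.
#' @param occ Occurrence tibble (`x`, `y`).
#' @return The restricted `binary_map`.
#' @export
obr_restrict <- function(binary, occ) {
  if (nrow(occ) < 2) {
    warning("OBR skipped: cutoff undefined with fewer than 2 occurrences")
    return(binary)
  }
  d <- pair_dist(as.matrix(occ[, c("x", "y")]))
  diag(d) <- Inf
  cutoff <- max(apply(d, 1, min))
  lab <- label_patches(binary$values == 1L, connectivity = 8)
  npatch <- max(lab)
  if (npatch == 0) return(binary)
  nr <- binary$grid$rows
  rc <- coord_cell(binary$grid, occ$x, occ$y)
  occ_idx <- (rc$col - 1L) * nr + rc$row
  occ_patch <- rep(0L, nrow(occ))
  on_grid <- !is.na(occ_idx)
  occ_patch[on_grid] <- lab[occ_idx[on_grid]]
  keep <- logical(npatch)
  for (pch in seq_len(npatch)) {
    if (any(occ_patch == pch)) {
      keep[pch] <- TRUE
      next
    }
    cells <- which(lab == pch)
    ctr <- cell_center(binary$grid, ((cells - 1L) %% nr) + 1L,
                       ((cells - 1L) %/% nr) + 1L)
    dmin2 <- min(vapply(seq_len(nrow(occ)), function(i) {
      min((ctr$x - occ$x[i])^2 + (ctr$y - occ$y[i])^2)
    }, numeric(1)))
    keep[pch] <- sqrt(dmin2) <= cutoff
  }
  out <- binary$values
  drop_cells <- lab > 0 & !keep[pmax(lab, 1L)]
  out[drop_cells] <- 0L
  binary_map(out, binary$grid, species = binary$species,
             scenario = binary$scenario)
}

#' Project a fitted model onto a (future) stack as a binary map
#'
#' Predicts suitability on the new stack and thresholds it at the
#' calibration-derived maxTSS value — the threshold is reused, never
#' re-derived on the projection, so no scenario information leaks into
#' the cut.
#'
#' @param model A `maxent_model`.
#' @param env Projection [env_stack()].
#' @param threshold Calibration maxTSS threshold in [0, 1].
#' @param scenario Scenario label for the output.
#' @param transform Suitability scale (must match the scale the
#'   threshold was derived on).
#' @return A `binary_map`.
#' @export
project_model <- function(model, env, threshold, scenario = "future",
                          transform = "cloglog") {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  suit <- stats::predict(model, env, transform = transform)
  binarize(suit, threshold, scenario = scenario)
}
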