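#' Feature-class configuration for maximum-entropy models
#'
#' The classic Maxent feature classes: per-covariate linear terms,
#' squares, all pairwise products, step ("threshold") functions at
#' equally spaced knots, and forward/reverse hinges at the same knots.
#' All features are min-max scaled to [0, 1] using the training bounds,
#' which makes the fit invariant to affine rescaling of covariates.
#'
#' @param classes Subset of `c("linear", "quadratic", "product",
#'   "threshold", "hinge")`.
#' @param n_knots Knot count per covariate for threshold and hinge
#'   expansions.
#' @param regularization_multiplier Positive scale on the class-specific
#'   default regularization (1 reproduces the published defaults).
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(classes = c("linear", "quadratic", "product",
                                     "threshold", "hinge"),
                         n_knots = 10, regularization_multiplier = 1) {
  classes <- match.arg(classes, several.ok = TRUE)
  stopifnot(length(classes) >= 1, n_knots >= 1,
            regularization_multiplier >= 0)
  structure(list(classes = classes, n_knots = as.integer(n_knots),
                 regularization_multiplier = regularization_multiplier),
            class = "feature_spec")
}

#' Expand covariate vectors into Maxent features
#'
#' @param values Numeric matrix of covariate values (rows = points,
#'   named columns = layers).
#' @param spec A [feature_spec()].
#' @param bounds Training bounds: tibble with `layer`, `min`, `max`
#'   (from the calibration data). Values are clamped to the bounds
#'   before expansion.
#' @return A list: `x` (design matrix in [0, 1]) and `map` (tibble
#'   describing each column: `feature`, `class`, `layer`, `layer2`,
#'   `knot`).
#' @export
build_features <- function(values, spec, bounds) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  layers <- colnames(values)
  b <- stats::setNames(split(bounds, seq_len(nrow(bounds))), bounds$layer)
  scaled <- vapply(layers, function(nm) {
    lo <- b[[nm]]$min; hi <- b[[nm]]$max
    v <- pmin(pmax(values[, nm], lo), hi)
    if (hi > lo) (v - lo) / (hi - lo) else v * 0
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) scaled <- matrix(scaled, nrow = 1,
                                           dimnames = list(NULL, layers))
  cols <- list(); map <- list()
  add <- function(v, feature, class, layer, layer2 = NA, knot = NA) {
    cols[[length(cols) + 1L]] <<- v
    map[[length(map) + 1L]] <<- tibble::tibble(
      feature = feature, class = class, layer = layer,
      layer2 = layer2, knot = knot)
  }
  if ("linear" %in% spec$classes)
    for (nm in layers) add(scaled[, nm], nm, "linear", nm)
  if ("quadratic" %in% spec$classes)
    for (nm in layers) add(scaled[, nm]^2, paste0(nm, "^2"), "quadratic", nm)
  if ("product" %in% spec$classes) {
    if (length(layers) < 2) {
      message("product features skipped: single covariate")
    } else {
      for (i in seq_len(length(layers) - 1))
        for (j in seq(i + 1, length(layers)))
          add(scaled[, i] * scaled[, j],
              paste0(layers[i], ":", layers[j]), "product",
              layers[i], layers[j])
    }
  }
  knots <- seq(0, 1, length.out = spec$n_knots + 2L)[-c(1L, spec$n_knots + 2L)]
  if ("threshold" %in% spec$classes)
    for (nm in layers) for (k in knots)
      add(as.numeric(scaled[, nm] > k),
          sprintf("thr(%s,%.3f)", nm, k), "threshold", nm, knot = k)
  if ("hinge" %in% spec$classes)
    for (nm in layers) for (k in knots) {
      add(pmax(scaled[, nm] - k, 0) / (1 - k),
          sprintf("hinge(%s,%.3f)", nm, k), "hinge", nm, knot = k)
      add(pmax(k - scaled[, nm], 0) / k,
          sprintf("rhinge(%s,%.3f)", nm, k), "hinge", nm, knot = k)
    }
  x <- do.call(cbind, cols)
  map <- dplyr::bind_rows(map)
  colnames(x) <- map$feature
  list(x = x, map = map)
}

# Sample-size-dependent default regularization per feature class
# (published Maxent defaults), scaled by the feature's presence-sample
# standard deviation, floored by a small range-based minimum.
default_regularization <- function(x, map, presence_rows) {
  np <- length(presence_rows)
  tab <- list(
    linear = list(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    quadratic = list(c(0, 10, 17, 30, 100), c(1.3, 0.8, 0.5, 0.25, 0.05)),
    product = list(c(0, 10, 17, 30, 100), c(2.6, 1.6, 0.9, 0.55, 0.05)),
    threshold = list(c(0, 100), c(2, 1)),
    hinge = list(c(0, 1), c(0.5, 0.5))
  )
  base <- vapply(map$class, function(cl) {
    t <- tab[[cl]]
    stats::approx(t[[1]], t[[2]], np, rule = 2)$y
  }, numeric(1))
  xp <- x[presence_rows, , drop = FALSE]
  sds <- apply(xp, 2, stats::sd)
  sds[map$class == "hinge"] <- pmax(sds[map$class == "hinge"], 1 / sqrt(np))
  pmax(sds * base / sqrt(np),
       0.001 * (apply(x, 2, max) - apply(x, 2, min)))
}

#' Delimit a species' accessible area (M)
#'
#' The movement component of the BAM diagram: the union of discs of
#' `dispersal_radius` around the occurrence points, intersected with
#' non-nodata cells. Background sampling and prediction are restricted
#' to this region.
#'
#' @param occ Occurrence tibble (`x`, `y`) for one species.
#' @param env An [env_stack()].
#' @param dispersal_radius Disc radius in map units (> 0).
#' @return A logical matrix (`TRUE` = accessible).
#' @export
define_accessible_area <- function(occ, env, dispersal_radius) {
  if (dispersal_radius <= 0) stop("dispersal_radius must be positive")
  grid <- env$grid
  acc <- matrix(FALSE, grid$rows, grid$cols)
  rows <- seq_len(grid$rows); colsq <- seq_len(grid$cols)
  cy <- grid$ymin + (grid$rows - rows + 0.5) * grid$cell_size
  cx <- grid$xmin + (colsq - 0.5) * grid$cell_size
  for (i in seq_len(nrow(occ))) {
    dx2 <- (cx - occ$x[i])^2
    dy2 <- (cy - occ$y[i])^2
    hit <- outer(dy2, dx2, `+`) <= dispersal_radius^2
    acc <- acc | hit
  }
  acc & !env$nodata
}

#' Sample background points from the accessible area
#'
#' Uniform sampling without replacement over accessible cells (with
#' replacement, and a warning, when `n` exceeds the cells available);
#' points are placed at cell centers.
#'
#' @param accessible Logical matrix from [define_accessible_area()].
#' @param env The [env_stack()] supplying the grid.
#' @param n Number of background points.
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `y`.
#' @export
sample_background <- function(accessible, env, n, seed = 1) {
  cells <- which(accessible & !env$nodata)
  if (!length(cells)) stop("accessible area is empty")
  withr::with_seed(seed, {
    if (n > length(cells)) {
      warning("background n (", n, ") exceeds accessible cells (",
              length(cells), "); sampling with replacement")
      picked <- safe_sample(cells, n, replace = TRUE)
    } else {
      picked <- safe_sample(cells, n)
    }
    nr <- env$grid$rows
    cell_center(env$grid, ((picked - 1L) %% nr) + 1L,
                ((picked - 1L) %/% nr) + 1L)
  })
}

#' Fit a maximum-entropy presence-background niche model
#'
#' The Maxent estimator in its penalized-likelihood form: an
#' infinitely-weighted logistic lasso over the expanded feature space,
#' with class-specific default regularization scaled by the spec's
#' multiplier. Presences are added to the background (the standard
#' convention), background rows get weight 100. With all penalties zero
#' the fit falls back to an unpenalized weighted logistic regression.
#' The raw Maxent distribution is normalized over the background, from
#' which the cloglog/logistic output scales are derived.
#'
#' @param occ Occurrence tibble (`x`, `y`) for one species.
#' @param env Calibration [env_stack()].
#' @param spec A [feature_spec()].
#' @param background Tibble of background points (`x`, `y`), e.g. from
#'   [sample_background()].
#' @param species Species label stored on the model.
#' @param accessible Optional accessible-area matrix stored on the model.
#' @return A `maxent_model` object (see [tidy.maxent_model()] /
#'   [glance.maxent_model()]).
#' @export
fit_maxent <- function(occ, env, spec = feature_spec(), background,
                       species = occ$species[1] %||% "species",
                       accessible = NULL) {
  stopifnot(nrow(occ) >= 2, nrow(background) >= 2)
  vp <- extract_values(env, occ$x, occ$y)
  vb <- extract_values(env, background$x, background$y)
  keep_p <- stats::complete.cases(vp); keep_b <- stats::complete.cases(vb)
  vp <- vp[keep_p, , drop = FALSE]; vb <- vb[keep_b, , drop = FALSE]
  vals <- rbind(vp, vb, vp)  # presences, background, presences-in-background
  p <- c(rep(1, nrow(vp)), rep(0, nrow(vb) + nrow(vp)))
  bounds <- tibble::tibble(
    layer = colnames(vals),
    min = apply(vals, 2, min),
    max = apply(vals, 2, max)
  )
  feats <- build_features(vals, spec, bounds)
  x <- feats$x
  reg <- default_regularization(x, feats$map, which(p == 1)) *
    spec$regularization_multiplier
  w <- ifelse(p == 1, 1, 100)

  if (max(reg) <= 0) {
    fit <- stats::glm.fit(cbind(1, x), p, weights = w,
                          family = stats::binomial())
    beta <- fit$coefficients[-1]
    beta[is.na(beta)] <- 0
    intercept <- fit$coefficients[1]
    converged <- fit$converged
    lambda <- 0
    dev_ratio <- 1 - fit$deviance / fit$null.deviance
  } else {
    glmnet::glmnet.control(pmin = 1e-8, fdev = 0)
    lambdas <- 10^seq(4, 0, length.out = 200) *
      sum(reg) / length(reg) * sum(p) / sum(w)
    gfit <- glmnet::glmnet(x, p, family = "binomial", weights = w,
                           standardize = FALSE, penalty.factor = reg,
                           lambda = lambdas)
    nl <- length(gfit$lambda)
    if (nl < length(lambdas))
      warning("glmnet stopped after ", nl, " of ", length(lambdas),
              " lambda steps")
    beta <- as.numeric(gfit$beta[, nl])
    names(beta) <- rownames(gfit$beta)
    intercept <- gfit$a0[nl]
    converged <- nl == length(lambdas)
    lambda <- gfit$lambda[nl]
    dev_ratio <- gfit$dev.ratio[nl]
  }

  # Maxent normalization over the background distribution
  bg_rows <- which(p == 0)
  eta_bg <- as.numeric(x[bg_rows, , drop = FALSE] %*% beta)
  alpha <- -log_sum_exp(eta_bg)
  raw_bg <- exp(eta_bg + alpha)
  entropy <- -sum(raw_bg * log(pmax(raw_bg, 1e-300)))

  structure(
    list(species = species, beta = beta, alpha = alpha, entropy = entropy,
         intercept = intercept, feature_map = feats$map, spec = spec,
         bounds = bounds, accessible = accessible,
         n_presence = nrow(vp), n_background = nrow(vb),
         lambda = lambda, dev_ratio = dev_ratio, converged = converged),
    class = "maxent_model"
  )
}

log_sum_exp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %s: %d presences, %d background, %d/%d active features\n",
    x$species, x$n_presence, x$n_background, sum(x$beta != 0),
    length(x$beta)))
  if (!x$converged) cat("  warning: fit did not complete the lambda path\n")
  invisible(x)
}

#' Tidy a fitted niche model
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return A tibble with one row per expanded feature: `term`, `class`,
#'   `layer`, `layer2`, `knot`, `estimate`.
#' @importFrom generics tidy
#' @export
tidy.maxent_model <- function(x, ...) {
  dplyr::mutate(
    dplyr::rename(x$feature_map, term = "feature"),
    estimate = unname(x$beta)
  )
}

#' One-row summary of a fitted niche model
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @importFrom generics glance
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    species = x$species, n_presence = x$n_presence,
    n_background = x$n_background, n_features = length(x$beta),
    n_active = sum(x$beta != 0), entropy = x$entropy,
    lambda = x$lambda, dev_ratio = x$dev_ratio, converged = x$converged
  )
}

# Linear predictor (plus alpha) for a matrix of covariate values,
# clamped to training bounds; returns list(link, clamped).
model_link <- function(model, values) {
  b <- model$bounds
  clamped <- rep(FALSE, nrow(values))
  for (i in seq_len(nrow(b))) {
    v <- values[, b$layer[i]]
    clamped <- clamped | (!is.na(v) & (v < b$min[i] | v > b$max[i]))
  }
  feats <- build_features(values, model$spec, b)
  list(link = as.numeric(feats$x %*% model$beta) + model$alpha,
       clamped = clamped)
}

#' Predict suitability over a stack
#'
#' Applies the fitted model to every non-nodata cell. Covariates outside
#' the training bounds are clamped and the affected cells recorded in
#' the result's `clamped` matrix. Output scales: `"cloglog"` (default)
#' and `"logistic"` lie in [0, 1]; `"raw"` is the Maxent probability
#' distribution normalized to sum to one over the predicted cells.
#'
#' @param object A `maxent_model`.
#' @param env An [env_stack()] containing every layer the model uses.
#' @param transform `"cloglog"`, `"logistic"` or `"raw"`.
#' @param ... Unused.
#' @return A `suitability_map` grid map.
#' @export
predict.maxent_model <- function(object, env,
                                 transform = c("cloglog", "logistic", "raw"),
                                 ...) {
  transform <- match.arg(transform)
  missing_layers <- setdiff(object$bounds$layer, layer_names(env))
  if (length(missing_layers))
    stop("stack lacks layer(s) used by the model: ",
         paste(missing_layers, collapse = ", "))
  cells <- land_cells(env)
  vals <- land_matrix(env, cells)[, object$bounds$layer, drop = FALSE]
  ml <- model_link(object, vals)
  out <- switch(transform,
                cloglog = 1 - exp(-exp(object$entropy + ml$link)),
                logistic = stats::plogis(object$entropy + ml$link),
                raw = {
                  r <- exp(ml$link)
                  r / sum(r)
                })
  v <- matrix(NA_real_, env$grid$rows, env$grid$cols)
  v[cells] <- out
  cl <- matrix(FALSE, env$grid$rows, env$grid$cols)
  cl[cells] <- ml$clamped
  grid_map(v, env$grid, "suitability_map", species = object$species,
           scenario = "prediction", transform = transform, clamped = cl)
}

#' Suitability scores at point locations
#'
#' @param model A `maxent_model`.
#' @param env An [env_stack()].
#' @param x,y Point coordinates.
#' @param transform Output scale (see [predict.maxent_model()];
#'   `"raw"` here returns the unnormalized exponential).
#' @return Numeric vector of scores (NA off-grid).
#' @export
score_points <- function(model, env, x, y, transform = "cloglog") {
  vals <- extract_values(env, x, y)[, model$bounds$layer, drop = FALSE]
  ok <- stats::complete.cases(vals)
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    ml <- model_link(model, vals[ok, , drop = FALSE])
    out[ok] <- switch(transform,
                      cloglog = 1 - exp(-exp(model$entropy + ml$link)),
                      logistic = stats::plogis(model$entropy + ml$link),
                      raw = exp(ml$link))
  }
  out
}

#' Estimate a covariate's fitted response optimum
#'
#' Sweeps one covariate across its training bounds with the others held
#' at their land means, evaluates the fitted Maxent density along the
#' sweep, and returns the density-weighted mean of the covariate — the
#' expectation of the covariate under the fitted 1-D profile. For a
#' symmetric (e.g. Gaussian) response this estimates the response
#' optimum and is robust to the flat-topped piecewise-linear profiles
#' hinge features produce.
#'
#' @param model A `maxent_model`.
#' @param env The calibration [env_stack()].
#' @param layer Covariate name to profile.
#' @param n Sweep resolution.
#' @return A list: `optimum`, `profile` (tibble with `value`, `link`,
#'   `density`).
#' @export
profile_optimum <- function(model, env, layer, n = 400) {
  stopifnot(layer %in% model$bounds$layer)
  lm_ <- land_matrix(env)[, model$bounds$layer, drop = FALSE]
  sweep_v <- seq(min(lm_[, layer]), max(lm_[, layer]), length.out = n)
  prof <- matrix(rep(colMeans(lm_), each = n), nrow = n,
                 dimnames = list(NULL, colnames(lm_)))
  prof[, layer] <- sweep_v
  eta <- model_link(model, prof)$link
  w <- exp(eta - max(eta))
  list(optimum = sum(sweep_v * w) / sum(w),
       profile = tibble::tibble(value = sweep_v, link = eta,
                                density = w / sum(w)))
}

#' Permutation importance of each covariate
#'
#' For each layer, its values across the combined presence/background
#' training points are permuted and the drop in training AUC recorded,
#' averaged over `n_permutations`; drops are floored at zero and
#' normalized to sum to 100.
#'
#' @param model A `maxent_model`.
#' @param occ Presence tibble (`x`, `y`).
#' @param background Background tibble (`x`, `y`).
#' @param env An [env_stack()].
#' @param n_permutations Permutations per layer.
#' @param seed Integer seed.
#' @return A tibble with `layer`, `auc_drop`, `importance` (percent,
#'   summing to 100), sorted by importance.
#' @export
variable_importance <- function(model, occ, background, env,
                                n_permutations = 5, seed = 1) {
  vp <- extract_values(env, occ$x, occ$y)[, model$bounds$layer, drop = FALSE]
  vb <- extract_values(env, background$x, background$y)[, model$bounds$layer,
                                                        drop = FALSE]
  vp <- vp[stats::complete.cases(vp), , drop = FALSE]
  vb <- vb[stats::complete.cases(vb), , drop = FALSE]
  np <- nrow(vp)
  all_vals <- rbind(vp, vb)
  base_link <- model_link(model, all_vals)$link
  base_auc <- auc_score(base_link[seq_len(np)], base_link[-seq_len(np)])
  layers <- model$bounds$layer
  drops <- withr::with_seed(seed, vapply(layers, function(nm) {
    mean(vapply(seq_len(n_permutations), function(i) {
      perm <- all_vals
      perm[, nm] <- perm[sample(nrow(perm)), nm]
      l <- model_link(model, perm)$link
      base_auc - auc_score(l[seq_len(np)], l[-seq_len(np)])
    }, numeric(1)))
  }, numeric(1)))
  drops <- pmax(drops, 0)
  imp <- if (sum(drops) > 0) 100 * drops / sum(drops)
         else rep(100 / length(drops), length(drops))
  dplyr::arrange(
    tibble::tibble(layer = layers, auc_drop = unname(drops),
                   importance = unname(imp)),
    dplyr::desc(.data$importance))
}
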