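#' Configuration for a synthetic study region
#'
#' Defines the virtual landscape the pipeline is exercised on: a planar
#' grid of spatially autocorrelated, inter-correlated environmental
#' layers with a contiguous "sea" of nodata cells. The nominal cell size
#' of 1 map unit mirrors a ~1 km analysis resolution.
#'
#' @param grid_rows,grid_cols Grid dimensions, each at least 10.
#' @param cell_size Cell side length in map units.
#' @param n_layers Number of environmental layers.
#' @param layer_correlation Target inter-layer correlation matrix
#'   (symmetric, unit diagonal, positive semi-definite). Defaults to the
#'   identity (independent layers).
#' @param autocorrelation_range Gaussian smoothing scale in cells; larger
#'   values give smoother, more spatially autocorrelated layers.
#' @param sea_fraction Fraction of cells masked as a contiguous nodata
#'   region (at least 0.05).
#' @param roles Per-layer role tags; defaults to half `"temperature"`,
#'   half `"precipitation"`.
#' @param seed Integer seed controlling every random draw.
#' @return A `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(grid_rows = 100, grid_cols = 100,
                                   cell_size = 1, n_layers = 6,
                                   layer_correlation = diag(n_layers),
                                   autocorrelation_range = 4,
                                   sea_fraction = 0.08,
                                   roles = NULL, seed = 1) {
  stopifnot(grid_rows >= 10, grid_cols >= 10, n_layers >= 1,
            sea_fraction >= 0.05, sea_fraction < 0.5)
  layer_correlation <- as.matrix(layer_correlation)
  if (nrow(layer_correlation) != n_layers ||
      ncol(layer_correlation) != n_layers)
    stop("layer_correlation must be ", n_layers, " x ", n_layers)
  if (max(abs(layer_correlation - t(layer_correlation))) > 1e-8)
    stop("layer_correlation must be symmetric")
  if (max(abs(diag(layer_correlation) - 1)) > 1e-8)
    stop("layer_correlation must have unit diagonal")
  ev <- eigen(layer_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("layer_correlation is not positive semi-definite (minimum ",
         "eigenvalue ", format(min(ev)), ")")
  if (is.null(roles)) {
    roles <- rep(c("temperature", "precipitation"),
                 c(ceiling(n_layers / 2), floor(n_layers / 2)))
  }
  roles <- rep_len(roles, n_layers)
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         cell_size = cell_size, n_layers = as.integer(n_layers),
         layer_correlation = layer_correlation,
         autocorrelation_range = autocorrelation_range,
         sea_fraction = sea_fraction, roles = roles, seed = as.integer(seed)),
    class = "synthetic_world_config"
  )
}

# Marginal target ranges by role; layers are rank-mapped onto these so
# temperature layers look like degrees C and precipitation like mm.
role_range <- function(role) {
  switch(role,
         temperature = c(5, 30),
         precipitation = c(0, 3000),
         c(0, 1))
}

#' Generate a synthetic environmental stack
#'
#' White noise per layer is linearly mixed through the matrix square root
#' of the target correlation, smoothed with a Gaussian kernel of scale
#' `autocorrelation_range`, and rank-mapped onto role-specific marginal
#' ranges. A contiguous circular "sea" is masked as nodata. Empirical
#' inter-layer correlations approach the target as the grid grows.
#'
#' @param config A [synthetic_world_config()].
#' @return An [env_stack()] with `config$n_layers` layers.
#' @export
generate_env_stack <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  withr::with_seed(config$seed, {
    nr <- config$grid_rows; nc <- config$grid_cols
    p <- config$n_layers
    grid <- env_grid(nr, nc, cell_size = config$cell_size)

    es <- eigen(config$layer_correlation, symmetric = TRUE)
    sqrtC <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), p) %*% t(es$vectors)
    fields <- lapply(seq_len(p), function(j) {
      smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                    config$autocorrelation_range)
    })

    # Contiguous sea: a disc centered on a random border-adjacent point.
    sea <- matrix(FALSE, nr, nc)
    radius <- sqrt(config$sea_fraction * nr * nc / pi) * 1.02
    ctr_r <- sample(seq_len(nr), 1)
    ctr_c <- sample(c(1L, nc), 1)  # anchored at a lateral border: one blob
    dist2 <- outer(seq_len(nr), seq_len(nc),
                   function(r, cc) (r - ctr_r)^2 + (cc - ctr_c)^2)
    sea[dist2 <= radius^2] <- TRUE
    if (mean(sea) < 0.05) {  # border-clipped disc: grow until >= 5%
      ord <- order(dist2)
      sea[ord[seq_len(ceiling(0.05 * nr * nc) + 1L)]] <- TRUE
    }

    # Whiten the smoothed fields empirically over land, then color with
    # the matrix square root of the target, so the realized land-cell
    # correlations hit the target at any grid size; smoothing alone
    # would leave O(1/sqrt(effective n)) sampling noise on top.
    land <- !sea
    z <- vapply(fields, function(m) m[land], numeric(sum(land)))
    z <- scale(z)
    ez <- eigen(stats::cov(z), symmetric = TRUE)
    white <- ez$vectors %*% diag(1 / sqrt(pmax(ez$values, 1e-12)), p) %*%
      t(ez$vectors)
    y <- z %*% white %*% sqrtC

    layers <- list()
    for (j in seq_len(p)) {
      m <- matrix(NA_real_, nr, nc)
      rng <- role_range(config$roles[j])
      r <- rank(y[, j], ties.method = "first")
      m[land] <- rng[1] + (r - 1) / (length(r) - 1) * (rng[2] - rng[1])
      layers[[paste0("bio", j)]] <- m
    }
    env_stack(layers, grid, nodata = sea,
              roles = stats::setNames(config$roles, names(layers)))
  })
}

#' Shift a stack toward a warmer, wetter future
#'
#' Temperature-role layers are offset by `delta_temperature` (plus small
#' smooth noise); precipitation-role layers are multiplied by
#' `precip_scale` (with matching multiplicative noise). With
#' `noise_sd = 0` the transformation is exact, so `delta_temperature = 0`,
#' `precip_scale = 1` returns the input unchanged. The nodata mask and
#' grid are preserved.
#'
#' @param current An [env_stack()].
#' @param delta_temperature Additive offset applied to temperature layers
#'   (map-layer units, e.g. degrees C).
#' @param precip_scale Multiplicative factor applied to precipitation layers.
#' @param noise_sd Standard deviation of the smooth perturbation field
#'   (additive for temperature, log-scale for precipitation).
#' @param seed Integer seed.
#' @return An [env_stack()] on the same grid.
#' @export
generate_future_env <- function(current, delta_temperature = 1.4,
                                precip_scale = 1.1, noise_sd = 0.05,
                                seed = 1) {
  stopifnot(inherits(current, "env_stack"))
  withr::with_seed(seed, {
    nr <- current$grid$rows; nc <- current$grid$cols
    layers <- purrr::imap(current$layers, function(m, nm) {
      role <- current$roles[[nm]]
      if (noise_sd > 0) {
        eps <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), 3)
        eps <- noise_sd * eps / stats::sd(eps)
      } else {
        eps <- matrix(0, nr, nc)
      }
      out <- switch(role,
                    temperature = m + delta_temperature + eps,
                    precipitation = m * precip_scale * exp(eps),
                    m)
      out
    })
    env_stack(layers, current$grid, nodata = current$nodata,
              roles = current$roles)
  })
}

#' Define a virtual species with a known response to the environment
#'
#' The species' suitability is a parametric function of the stack's
#' covariates with known ground truth, enabling parameter-recovery tests
#' of the whole modeling chain. Each response term is one of
#' `"linear"` (`slope`, optional `center`), `"gaussian"` (`opt`, `sd`,
#' optional `height`), or `"hinge"` (`knot`, `slope`, `direction` of
#' `"up"`/`"down"`). Terms are summed into a linear predictor and passed
#' through the link.
#'
#' @param name Species identifier.
#' @param response Named list (by layer name) of response terms.
#' @param link `"logistic"` (default) or `"identity"` (clamped to [0, 1]).
#' @param prevalence Fraction of land cells occupied: the top
#'   `prevalence` fraction of land cells by suitability is occupied
#'   (ties broken deterministically by cell order).
#' @param dispersal_radius Radius (map units) for the accessible-area
#'   ("M") emulation around occurrences.
#' @return A `virtual_species` object.
#' @export
virtual_species <- function(name, response, link = "logistic",
                            prevalence = 0.25, dispersal_radius = 25) {
  stopifnot(is.list(response), length(response) >= 1,
            !is.null(names(response)),
            prevalence > 0, prevalence < 1, dispersal_radius > 0)
  link <- match.arg(link, c("logistic", "identity"))
  structure(list(name = name, response = response, link = link,
                 prevalence = prevalence,
                 dispersal_radius = dispersal_radius),
            class = "virtual_species")
}

response_term <- function(term, v) {
  switch(term$type,
         linear = term$slope * (v - (term$center %||% 0)),
         gaussian = (term$height %||% 4) * exp(-(v - term$opt)^2 / (2 * term$sd^2)),
         hinge = {
           d <- if ((term$direction %||% "up") == "up") pmax(v - term$knot, 0)
                else pmax(term$knot - v, 0)
           term$slope * d
         },
         stop("unknown response type: ", term$type))
}

#' True suitability of a virtual species on a stack
#'
#' @param species A [virtual_species()].
#' @param env An [env_stack()] containing every layer the species responds to.
#' @return A `suitability_map` with values in [0, 1] (NA on nodata).
#' @export
true_suitability <- function(species, env) {
  stopifnot(inherits(species, "virtual_species"), inherits(env, "env_stack"))
  missing_layers <- setdiff(names(species$response), layer_names(env))
  if (length(missing_layers))
    stop("stack lacks layers: ", paste(missing_layers, collapse = ", "))
  eta <- matrix(0, env$grid$rows, env$grid$cols)
  for (nm in names(species$response)) {
    eta <- eta + response_term(species$response[[nm]], env$layers[[nm]])
  }
  suit <- if (species$link == "logistic") stats::plogis(eta - mean(eta[!env$nodata]))
          else pmin(pmax(eta, 0), 1)
  suit[env$nodata] <- NA_real_
  grid_map(suit, env$grid, "suitability_map", species = species$name,
           scenario = "truth", transform = species$link)
}

#' True occupancy of a virtual species
#'
#' Deterministic thresholding of true suitability at the species'
#' prevalence: the top `prevalence` fraction of land cells is occupied,
#' with ties broken by cell order so the map is reproducible.
#'
#' @inheritParams true_suitability
#' @return A `binary_map` (1 occupied, 0 not, NA nodata).
#' @export
true_occupancy <- function(species, env) {
  suit <- true_suitability(species, env)
  v <- suit$values
  cells <- land_cells(env)
  k <- max(1L, round(species$prevalence * length(cells)))
  top <- cells[order(v[cells], decreasing = TRUE)[seq_len(k)]]
  occ <- matrix(NA_integer_, env$grid$rows, env$grid$cols)
  occ[cells] <- 0L
  occ[top] <- 1L
  binary_map(occ, env$grid, species = species$name, scenario = "truth")
}

#' Sample biased occurrence records for a virtual species
#'
#' Presence points are drawn (with replacement) from the species' true
#' occupied cells with probability proportional to `bias_surface`
#' (uniform when absent), then jittered uniformly within their cell —
#' emulating opportunistic human-observation records.
#'
#' @inheritParams true_suitability
#' @param n Number of records to draw (>= 1).
#' @param bias_surface Optional non-negative matrix of sampling weights
#'   on the same grid.
#' @param seed Integer seed.
#' @return A tibble with columns `species`, `x`, `y`.
#' @export
sample_occurrences <- function(species, env, n, bias_surface = NULL, seed = 1) {
  stopifnot(n >= 1)
  occ <- true_occupancy(species, env)
  cells <- which(occ$values == 1L)
  if (!length(cells))
    stop("virtual species '", species$name, "' occupies no cells")
  w <- if (is.null(bias_surface)) rep(1, length(cells)) else {
    stopifnot(all(dim(bias_surface) == dim(occ$values)))
    pmax(bias_surface[cells], 0)
  }
  if (sum(w) <= 0) stop("bias surface is zero over all occupied cells")
  withr::with_seed(seed, {
    picked <- safe_sample(cells, n, replace = TRUE, prob = w)
    nr <- env$grid$rows
    row <- ((picked - 1L) %% nr) + 1L
    col <- ((picked - 1L) %/% nr) + 1L
    ctr <- cell_center(env$grid, row, col)
    half <- env$grid$cell_size / 2
    tibble::tibble(
      species = species$name,
      x = ctr$x + stats::runif(n, -half, half) * 0.999,
      y = ctr$y + stats::runif(n, -half, half) * 0.999
    )
  })
}

#' Generate a current/future native-vegetation pair
#'
#' Current vegetation covers roughly `veg_fraction` of land as a smooth
#' patchwork; the future map removes a spatially clustered `loss_fraction`
#' of the vegetated cells (grown from a few random foci), with no
#' spontaneous gain.
#'
#' @param env An [env_stack()] supplying grid and nodata mask.
#' @param loss_fraction Fraction of vegetated cells converted to
#'   non-vegetation, in [0, 1].
#' @param veg_fraction Fraction of land vegetated in the current map.
#' @param n_foci Number of deforestation foci the loss grows from.
#' @param seed Integer seed.
#' @return A list with `binary_map`s `current` and `future`.
#' @export
generate_landuse_pair <- function(env, loss_fraction = 0.3,
                                  veg_fraction = 0.7, n_foci = 3, seed = 1) {
  if (loss_fraction < 0 || loss_fraction > 1)
    stop("loss_fraction must lie in [0, 1]")
  withr::with_seed(seed, {
    nr <- env$grid$rows; nc <- env$grid$cols
    f <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), 5)
    land <- !env$nodata
    thr <- stats::quantile(f[land], 1 - veg_fraction, names = FALSE)
    cur <- matrix(0L, nr, nc)
    cur[land & f >= thr] <- 1L
    veg_cells <- which(cur == 1L)
    target <- round(loss_fraction * length(veg_cells))
    lost <- grow_patches(cur == 1L, n_seeds = n_foci, total = target)
    fut <- cur
    fut[lost > 0L] <- 0L
    cur[env$nodata] <- NA_integer_; fut[env$nodata] <- NA_integer_
    list(current = binary_map(cur, env$grid, scenario = "current"),
         future = binary_map(fut, env$grid, scenario = "future"))
  })
}

# Grow n_seeds clustered patches over `mask` until `total` cells are
# claimed; returns an integer label matrix (0 unclaimed). Frontier cells
# are consumed in randomized order so patches are compact but irregular.
grow_patches <- function(mask, n_seeds, total) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  avail <- which(mask)
  if (total <= 0 || !length(avail)) return(lab)
  total <- min(total, length(avail))
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  seeds <- safe_sample(avail, min(n_seeds, length(avail)))
  frontier <- lapply(seeds, function(s) s)
  claimed <- 0L
  for (k in seq_along(seeds)) {
    if (claimed >= total) break
    lab[seeds[k]] <- k
    claimed <- claimed + 1L
  }
  active <- seq_along(seeds)
  while (claimed < total && length(active)) {
    for (k in active) {
      if (claimed >= total) break
      fr <- frontier[[k]]
      new_fr <- integer(0)
      for (cur in fr) {
        r <- ((cur - 1L) %% nr) + 1L
        cc <- ((cur - 1L) %/% nr) + 1L
        nb <- expand_neighbors(r, cc, dr, dc, nr, nc)
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          nb <- safe_sample(nb, length(nb))
          take <- min(length(nb), total - claimed)
          nb <- nb[seq_len(take)]
          lab[nb] <- k
          claimed <- claimed + take
          new_fr <- c(new_fr, nb)
          if (claimed >= total) break
        }
      }
      frontier[[k]] <- new_fr
    }
    active <- active[vapply(frontier[active], length, integer(1)) > 0]
    if (!length(active) && claimed < total) {
      # disconnected shortfall: reseed on remaining cells
      rest <- which(mask & lab == 0L)
      if (!length(rest)) break
      s <- safe_sample(rest, 1)
      k <- max(lab) + 1L
      lab[s] <- k
      claimed <- claimed + 1L
      frontier[[k]] <- s
      active <- k
    }
  }
  lab
}

expand_neighbors <- function(r, cc, dr, dc, nr, nc) {
  r2 <- r + dr; c2 <- cc + dc
  ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
  (c2[ok] - 1L) * nr + r2[ok]
}

#' Generate a patchy protected-area mask
#'
#' Grows `n_patches` disjoint connected patches over land until they
#' jointly cover about `coverage` of the non-nodata cells; each patch
#' carries a unique positive integer identifier.
#'
#' @param env An [env_stack()].
#' @param n_patches Number of patches (>= 1).
#' @param coverage Target fraction of land covered, in (0, 0.9].
#' @param seed Integer seed.
#' @return A `pa_mask` grid map: 0 = unprotected land, k > 0 = patch id,
#'   NA = nodata.
#' @export
generate_protected_areas <- function(env, n_patches = 10, coverage = 0.12,
                                     seed = 1) {
  if (coverage > 0.9) stop("coverage > 0.9 is degenerate; refusing")
  stopifnot(coverage > 0, n_patches >= 1)
  withr::with_seed(seed, {
    land <- !env$nodata
    total <- round(coverage * sum(land))
    lab <- grow_patches(land, n_seeds = n_patches, total = total)
    lab[env$nodata] <- NA_integer_
    grid_map(lab, env$grid, "pa_mask")
  })
}

#' Build a complete synthetic study system
#'
#' Convenience wrapper producing everything one pipeline run needs:
#' current and future climate, a community of virtual species with
#' ground truth, land-use change, and protected areas. Species respond
#' to randomly chosen driver layers with Gaussian niches.
#'
#' @param config A [synthetic_world_config()].
#' @param n_species Number of virtual species.
#' @param delta_temperature,precip_scale Future climate shift (see
#'   [generate_future_env()]).
#' @param pa_coverage,pa_patches Protected-area extent and patchiness.
#' @param loss_fraction Native-vegetation loss fraction.
#' @return A list: `current`, `future`, `species` (list of
#'   [virtual_species()]), `landuse`, `pa`.
#' @export
synthetic_study_system <- function(config, n_species = 5,
                                   delta_temperature = 1.4,
                                   precip_scale = 1.1,
                                   pa_coverage = 0.12, pa_patches = 12,
                                   loss_fraction = 0.3) {
  env <- generate_env_stack(config)
  fut <- generate_future_env(env, delta_temperature, precip_scale,
                             seed = child_seed(config$seed, "future"))
  lu <- generate_landuse_pair(env, loss_fraction = loss_fraction,
                              seed = child_seed(config$seed, "landuse"))
  pa <- generate_protected_areas(env, n_patches = pa_patches,
                                 coverage = pa_coverage,
                                 seed = child_seed(config$seed, "pa"))
  lm <- land_matrix(env)
  species <- withr::with_seed(child_seed(config$seed, "species"), {
    lapply(seq_len(n_species), function(i) {
      drivers <- safe_sample(layer_names(env), min(2, length(env$layers)))
      resp <- stats::setNames(lapply(drivers, function(nm) {
        v <- lm[, nm]
        list(type = "gaussian",
             opt = stats::quantile(v, stats::runif(1, 0.25, 0.75), names = FALSE),
             sd = (max(v) - min(v)) * stats::runif(1, 0.1, 0.25),
             height = 5)
      }), drivers)
      virtual_species(sprintf("species_%02d", i), resp,
                      prevalence = stats::runif(1, 0.15, 0.35),
                      dispersal_radius = 0.25 * config$grid_cols *
                        config$cell_size)
    })
  })
  list(current = env, future = fut, species = species, landuse = lu, pa = pa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
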