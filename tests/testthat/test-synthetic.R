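test_that("independent layers come out uncorrelated, targeted pairs correlated", {
  env <- generate_env_stack(synthetic_world_config(64, 64, n_layers = 6,
                                                   seed = 1))
  cm <- cor(land_matrix(env))
  diag(cm) <- 0
  expect_lt(max(abs(cm)), 0.3)

  C <- diag(6); C[1, 2] <- C[2, 1] <- 0.95
  env2 <- generate_env_stack(synthetic_world_config(64, 64, n_layers = 6,
                                                    layer_correlation = C,
                                                    seed = 1))
  r12 <- cor(land_matrix(env2))[1, 2]
  expect_gt(abs(r12), 0.7)
  scr <- collinearity_screen(env2)
  expect_equal(nrow(scr$dropped), 1)
  expect_true(scr$dropped$dropped %in% c("bio1", "bio2"))
})

test_that("degenerate and invalid world configs are handled", {
  env1 <- generate_env_stack(synthetic_world_config(20, 20, n_layers = 1,
                                                    seed = 2))
  expect_length(env1$layers, 1)
  expect_error(synthetic_world_config(20, 20, n_layers = 2,
                                      layer_correlation = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
  expect_error(synthetic_world_config(5, 20), "grid_rows")
})

test_that("world generation is deterministic and masks a contiguous sea", {
  cfg <- synthetic_world_config(48, 48, n_layers = 3, seed = 11)
  e1 <- generate_env_stack(cfg)
  e2 <- generate_env_stack(cfg)
  expect_identical(e1, e2)
  expect_gte(mean(e1$nodata), 0.05)
  # contiguity: the sea is one 8-connected patch
  lab <- stacksdm:::label_patches(e1$nodata)
  expect_equal(max(lab), 1)
  # nodata propagates to every layer
  for (m in e1$layers) expect_true(all(is.na(m[e1$nodata])))
})

test_that("future climate shifts temperature additively and precipitation multiplicatively", {
  env <- small_world(seed = 4)
  same <- generate_future_env(env, delta_temperature = 0, precip_scale = 1,
                              noise_sd = 0, seed = 1)
  for (nm in layer_names(env))
    expect_equal(same$layers[[nm]], env$layers[[nm]])

  fut <- generate_future_env(env, delta_temperature = 1.4,
                             precip_scale = 1.2, noise_sd = 0.02, seed = 1)
  temps <- names(env$roles)[env$roles == "temperature"]
  for (nm in temps) {
    shift <- mean(fut$layers[[nm]] - env$layers[[nm]], na.rm = TRUE)
    expect_equal(shift, 1.4, tolerance = 0.05)
  }
  precs <- names(env$roles)[env$roles == "precipitation"]
  for (nm in precs) {
    ratio <- mean(fut$layers[[nm]] / env$layers[[nm]], na.rm = TRUE)
    expect_equal(ratio, 1.2, tolerance = 0.05)
  }
  expect_identical(fut$nodata, env$nodata)
})

test_that("virtual species ground truth is closed and well-formed", {
  env <- small_world(seed = 6)
  vsp <- driven_species(env, "bio2", prevalence = 0.3)
  suit <- true_suitability(vsp, env)
  v <- suit$values[!env$nodata]
  expect_true(all(v >= 0 & v <= 1))
  occ <- true_occupancy(vsp, env)
  expect_equal(mean(occ$values[!env$nodata] == 1L), 0.3, tolerance = 0.01)
  # deterministic thresholding: every occupied cell is at least as
  # suitable as every unoccupied one
  expect_gte(min(v[occ$values[!env$nodata] == 1L]),
             max(v[occ$values[!env$nodata] == 0L]))
})

test_that("occurrence sampling respects support, count, bias, and seed", {
  env <- small_world(seed = 7)
  vsp <- driven_species(env, "bio1", prevalence = 0.25)
  occ10 <- sample_occurrences(vsp, env, 10, seed = 3)
  expect_equal(nrow(occ10), 10)
  expect_identical(occ10, sample_occurrences(vsp, env, 10, seed = 3))

  # single occupied cell forces every point into it
  m <- matrix(0, 12, 12); m[5, 7] <- 10
  env1 <- manual_stack(a = m)
  sp1 <- virtual_species("one", list(a = list(type = "linear", slope = 1)),
                         prevalence = 1 / 144, dispersal_radius = 3)
  pts <- sample_occurrences(sp1, env1, 5, seed = 1)
  rc <- coord_cell(env1$grid, pts$x, pts$y)
  expect_true(all(rc$row == 5 & rc$col == 7))

  # zero bias over the occupied cells is an explicit failure
  expect_error(sample_occurrences(vsp, env, 5,
                                  bias_surface = matrix(0, 40, 40)),
               "bias")
})

test_that("uniform sampling frequencies match the occupancy distribution", {
  env <- small_world(24, 24, n_layers = 2, seed = 8)
  vsp <- driven_species(env, "bio1", prevalence = 0.09)
  occ_map <- true_occupancy(vsp, env)
  cells <- which(occ_map$values == 1L)
  pts <- sample_occurrences(vsp, env, 500, seed = 9)
  rc <- coord_cell(env$grid, pts$x, pts$y)
  idx <- (rc$col - 1L) * env$grid$rows + rc$row
  counts <- table(factor(idx, levels = cells))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("land-use pair loses the stated fraction in clusters", {
  env <- small_world(seed = 10)
  lu0 <- generate_landuse_pair(env, loss_fraction = 0, seed = 2)
  expect_identical(lu0$future$values, lu0$current$values)
  expect_error(generate_landuse_pair(env, loss_fraction = 1.2), "loss_fraction")

  lu <- generate_landuse_pair(env, loss_fraction = 0.3, seed = 2)
  n_cur <- sum(lu$current$values == 1L, na.rm = TRUE)
  n_fut <- sum(lu$future$values == 1L, na.rm = TRUE)
  expect_lte(abs((n_cur - n_fut) - round(0.3 * n_cur)), 1)
  # no spontaneous gain
  expect_false(any(lu$future$values == 1L & lu$current$values == 0L,
                   na.rm = TRUE))

  # clustering: lost cells form larger patches than a random scatter
  lost <- !is.na(lu$current$values) & lu$current$values == 1L &
    lu$future$values == 0L
  lab <- stacksdm:::label_patches(lost)
  mean_patch <- sum(lost) / max(lab)
  scatter <- matrix(FALSE, nrow(lost), ncol(lost))
  scatter[withr::with_seed(1, sample(which(lu$current$values == 1L),
                                     sum(lost)))] <- TRUE
  lab_s <- stacksdm:::label_patches(scatter)
  expect_gt(mean_patch, sum(scatter) / max(lab_s))
})

test_that("protected areas are disjoint patches at the requested coverage", {
  env <- small_world(seed = 12)
  pa1 <- generate_protected_areas(env, n_patches = 1, coverage = 0.1,
                                  seed = 3)
  ids <- pa1$values[!is.na(pa1$values) & pa1$values > 0]
  expect_equal(length(unique(ids)), 1)
  frac <- length(ids) / n_land(env)
  expect_lte(abs(frac - 0.1), 0.02)
  lab <- stacksdm:::label_patches(!is.na(pa1$values) & pa1$values > 0)
  expect_equal(max(lab), 1)

  pa <- generate_protected_areas(env, n_patches = 8, coverage = 0.12,
                                 seed = 4)
  cov <- mean(pa$values[!is.na(pa$values)] > 0)
  expect_gte(cov, 0.10); expect_lte(cov, 0.14)
  expect_error(generate_protected_areas(env, 3, coverage = 0.95),
               "degenerate")
})
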