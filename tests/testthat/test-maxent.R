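test_that("feature expansion produces the expected feature sets", {
  vals <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  b <- tibble::tibble(layer = c("a", "b"), min = c(0, 0), max = c(1, 1))

  f1 <- build_features(vals, feature_spec("linear"), b)
  expect_equal(ncol(f1$x), 2)
  f2 <- build_features(vals, feature_spec(c("linear", "quadratic",
                                            "product")), b)
  expect_equal(ncol(f2$x), 5)
  f3 <- build_features(vals, feature_spec("hinge", n_knots = 4), b)
  expect_equal(ncol(f3$x), 2 * 2 * 4)
  f4 <- build_features(vals, feature_spec("threshold", n_knots = 3), b)
  expect_equal(ncol(f4$x), 2 * 3)
  expect_true(all(f2$x >= 0 & f2$x <= 1))

  # single covariate: product silently skipped
  v1 <- vals[, 1, drop = FALSE]
  expect_message(
    f5 <- build_features(v1, feature_spec(c("linear", "product")), b[1, ]),
    "product")
  expect_equal(ncol(f5$x), 1)
})

test_that("accessible area is the union of dispersal discs on land", {
  env <- manual_stack(a = matrix(0, 15, 15))
  occ <- tibble::tibble(x = 7.5, y = 7.5)  # center of cell (8, 8)
  acc <- define_accessible_area(occ, env, 1)
  expect_true(acc[8, 8])
  expect_equal(sum(acc), 5)  # rook neighbors at distance 1, diagonals at sqrt 2

  expect_true(all(define_accessible_area(occ, env, 100)))
  expect_error(define_accessible_area(occ, env, 0), "positive")

  two <- tibble::tibble(x = c(2.5, 12.5), y = c(2.5, 12.5))
  acc2 <- define_accessible_area(two, env, 1.5)
  expect_equal(max(stacksdm:::label_patches(acc2)), 2)
})

test_that("background sampling is uniform, reproducible, and warns on overdraw", {
  env <- small_world(20, 20, n_layers = 2, seed = 41)
  acc <- !env$nodata
  b1 <- sample_background(acc, env, 50, seed = 5)
  expect_identical(b1, sample_background(acc, env, 50, seed = 5))
  expect_equal(nrow(b1), 50)

  one <- matrix(FALSE, 20, 20)
  one[which(!env$nodata)[1]] <- TRUE
  expect_warning(b3 <- sample_background(one, env, 3, seed = 1),
                 "replacement")
  expect_equal(nrow(unique(b3)), 1)

  # inclusion frequencies consistent with uniform sampling
  small_acc <- matrix(FALSE, 20, 20)
  cells <- which(!env$nodata)[1:40]
  small_acc[cells] <- TRUE
  draws <- purrr::map_dfr(1:150, function(i)
    suppressWarnings(sample_background(small_acc, env, 41, seed = i)))
  rc <- coord_cell(env$grid, draws$x, draws$y)
  idx <- (rc$col - 1L) * env$grid$rows + rc$row
  counts <- table(factor(idx, levels = cells))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("pure linear response yields a monotone fitted suitability", {
  env <- small_world(40, 40, n_layers = 2, seed = 42)
  vsp <- virtual_species("lin",
                         list(bio1 = list(type = "linear", slope = 0.5)),
                         prevalence = 0.4, dispersal_radius = 60)
  truth <- true_suitability(vsp, env)
  occ <- sample_occurrences(vsp, env, 200, bias_surface = truth$values,
                            seed = 2)
  bg <- sample_background(!env$nodata, env, 1000, seed = 3)
  m <- fit_maxent(occ, env, feature_spec("linear"), bg)
  prof <- profile_optimum(m, env, "bio1")$profile
  expect_true(all(diff(prof$link) > -1e-12))
})

test_that("with zero regularization the fit matches an independent optimizer", {
  env <- small_world(20, 20, n_layers = 2, seed = 43)
  withr::with_seed(4, {
    occ <- tibble::tibble(species = "s", x = runif(20, 3, 17),
                          y = runif(20, 3, 17))
    bg <- tibble::tibble(x = runif(30, 3, 17), y = runif(30, 3, 17))
  })
  spec <- feature_spec("linear", regularization_multiplier = 0)
  m <- fit_maxent(occ, env, spec, bg)

  # oracle: BFGS on the weighted logistic log-likelihood, written out
  vp <- stacksdm:::extract_values(env, occ$x, occ$y)
  vb <- stacksdm:::extract_values(env, bg$x, bg$y)
  vp <- vp[stats::complete.cases(vp), , drop = FALSE]
  vb <- vb[stats::complete.cases(vb), , drop = FALSE]
  vals <- rbind(vp, vb, vp)
  p <- c(rep(1, nrow(vp)), rep(0, nrow(vb) + nrow(vp)))
  bounds <- tibble::tibble(layer = colnames(vals),
                           min = apply(vals, 2, min),
                           max = apply(vals, 2, max))
  X <- cbind(1, build_features(vals, spec, bounds)$x)
  w <- ifelse(p == 1, 1, 100)
  nll <- function(beta) {
    eta <- X %*% beta
    -sum(w * (p * eta - log1p(exp(eta))))
  }
  o <- optim(rep(0, ncol(X)), nll, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(max(abs(o$par[-1] - m$beta)), 1e-4)
})

test_that("refits and affine covariate rescaling leave predictions unchanged", {
  env <- small_world(30, 30, n_layers = 3, seed = 44)
  vsp <- driven_species(env, "bio2", prevalence = 0.4)
  occ <- sample_occurrences(vsp, env, 80, seed = 5)
  bg <- sample_background(!env$nodata, env, 500, seed = 6)
  spec <- feature_spec(c("linear", "quadratic", "hinge"), n_knots = 4)
  m1 <- fit_maxent(occ, env, spec, bg)
  m2 <- fit_maxent(occ, env, spec, bg)
  expect_identical(m1$beta, m2$beta)  # convex objective, deterministic path

  scaled_env <- env
  scaled_env$layers$bio2 <- env$layers$bio2 * 10 + 3
  m3 <- fit_maxent(occ, scaled_env, spec, bg)
  p1 <- predict(m1, env)$values
  p3 <- predict(m3, scaled_env)$values
  expect_lt(max(abs(p1 - p3), na.rm = TRUE), 1e-8)
})

test_that("prediction transforms behave: bounds, constancy, raw normalization", {
  env <- small_world(30, 30, n_layers = 3, seed = 45)
  vsp <- driven_species(env, "bio1", prevalence = 0.35)
  occ <- sample_occurrences(vsp, env, 60, seed = 7)
  bg <- sample_background(!env$nodata, env, 400, seed = 8)
  m <- fit_maxent(occ, env, feature_spec(c("linear", "quadratic")), bg)

  s <- predict(m, env)
  v <- s$values[!env$nodata]
  expect_true(all(v >= 0 & v <= 1))

  raw <- predict(m, env, transform = "raw")
  expect_equal(sum(raw$values, na.rm = TRUE), 1)

  const <- manual_stack(bio1 = matrix(10, 30, 30),
                        bio2 = matrix(20, 30, 30),
                        bio3 = matrix(1500, 30, 30))
  pc <- predict(m, const)
  expect_equal(length(unique(as.vector(pc$values))), 1)

  expect_error(predict(m, exclude_layers(env, "bio1")), "bio1")
})

test_that("permutation importance isolates the covariates a model uses", {
  env1 <- small_world(25, 25, n_layers = 1, seed = 46)
  vsp <- driven_species(env1, "bio1", prevalence = 0.4)
  occ <- sample_occurrences(vsp, env1, 50, seed = 9)
  bg <- sample_background(!env1$nodata, env1, 300, seed = 10)
  m <- fit_maxent(occ, env1, feature_spec(c("linear", "quadratic")), bg)
  vi <- variable_importance(m, occ, bg, env1, seed = 1)
  expect_equal(vi$importance, 100)
})

test_that("model accessors tidy and glance return well-formed tables", {
  env <- small_world(25, 25, n_layers = 2, seed = 47)
  vsp <- driven_species(env, "bio1", prevalence = 0.4)
  occ <- sample_occurrences(vsp, env, 50, seed = 11)
  bg <- sample_background(!env$nodata, env, 300, seed = 12)
  m <- fit_maxent(occ, env, feature_spec(c("linear", "hinge"), n_knots = 3),
                  bg)
  td <- tidy(m)
  expect_tibble(td)
  expect_equal(nrow(td), length(m$beta))
  gl <- glance(m)
  expect_equal(gl$n_presence, 50)
  expect_true(gl$converged)
})
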