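# Naive MOP oracle: full distance matrix, mean of the k nearest
# reference points, same rescaling rule.
mop_brute <- function(reference, projection, fraction) {
  mu <- colMeans(reference)
  sdev <- pmax(apply(reference, 2, sd), 1e-12)
  refz <- sweep(sweep(reference, 2, mu), 2, sdev, `/`)
  cells <- which(!projection$nodata)
  pv <- land_matrix(projection, cells)[, colnames(reference), drop = FALSE]
  pz <- sweep(sweep(pv, 2, mu), 2, sdev, `/`)
  k <- max(1, ceiling(fraction * nrow(refz)))
  d <- vapply(seq_len(nrow(pz)), function(i) {
    di <- sqrt(colSums((t(refz) - pz[i, ])^2))
    mean(sort(di)[1:k])
  }, numeric(1))
  strict <- rowSums(sweep(pv, 2, apply(reference, 2, min), `<`) |
                    sweep(pv, 2, apply(reference, 2, max), `>`)) > 0
  dmax <- max(d[!strict], 0)
  sim <- if (dmax > 0) pmin(pmax(1 - d / dmax, 0), 1) else rep(1, length(d))
  sim[strict] <- 0
  sim
}

test_that("MOP similarity matches a brute-force nearest-set computation", {
  withr::with_seed(5, {
    ref <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
    proj <- manual_stack(a = matrix(runif(4), 2, 2),
                         b = matrix(runif(4), 2, 2))
  })
  m <- mop(ref, proj, reference_fraction = 0.3)
  expect_equal(m$values[!proj$nodata], mop_brute(ref, proj, 0.3))
})

test_that("MOP flags strict extrapolation and scores analog cells as similar", {
  withr::with_seed(6, {
    ref <- matrix(runif(40, 0, 1), 20, 2,
                  dimnames = list(NULL, c("a", "b")))
  })
  # first cell coincides with a reference point; last is far outside
  av <- matrix(c(ref[1, 1], 0.5, 0.5, 50), 2, 2)
  bv <- matrix(c(ref[1, 2], 0.5, 0.5, 50), 2, 2)
  proj <- manual_stack(a = av, b = bv)
  m <- mop(ref, proj, reference_fraction = 0.05)  # nearest set of size 1
  expect_equal(m$values[1, 1], 1)
  expect_true(m$strict[2, 2])
  expect_equal(m$values[2, 2], 0)
  expect_error(mop(ref[1:5, ], proj, reference_fraction = 0.1),
               "at least")
})

test_that("MOP similarity does not decrease toward the reference centroid", {
  withr::with_seed(7, {
    ref <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  })
  ctr <- colMeans(ref)
  start <- c(6, -6)  # outside the cloud
  lambda <- seq(0, 1, length.out = 9)
  pts <- t(vapply(lambda, function(l) start + l * (ctr - start),
                  numeric(2)))
  proj <- manual_stack(a = matrix(pts[, 1], 3, 3),
                       b = matrix(pts[, 2], 3, 3))
  m <- mop(ref, proj, reference_fraction = 0.1)
  sims <- m$values[cbind(((seq_len(9) - 1) %% 3) + 1,
                         ((seq_len(9) - 1) %/% 3) + 1)]
  expect_true(all(diff(sims) >= -1e-12))
})

test_that("OBR keeps occupied or nearby patches and removes far islands", {
  m <- matrix(0L, 20, 20)
  m[3:6, 3:6] <- 1L      # patch with occurrences
  m[15:17, 15:17] <- 1L  # far island
  bmap <- manual_binary(m)
  occ <- tibble::tibble(x = c(3.5, 4.5, 5.5), y = c(16.5, 16.5, 15.5))
  # nearest-neighbor distances are all 1 -> cutoff 1
  out <- obr_restrict(bmap, occ)
  expect_true(all(out$values[3:6, 3:6] == 1L))
  expect_true(all(out$values[15:17, 15:17] == 0L))

  # three collinear points spacing d = 2: patch at 1.5 d removed, 0.5 d kept
  m2 <- matrix(0L, 20, 20)
  m2[10, 3:7] <- 1L
  m2[10, 10] <- 1L   # 1 cell away from x = 7.5 edge: within 0.5 d of nothing?
  bmap2 <- manual_binary(m2)
  occ2 <- tibble::tibble(x = c(3.5, 5.5, 7.5), y = rep(10.5, 3))
  near <- matrix(0L, 20, 20); near[10, 3:7] <- 1L; near[10, 9] <- 1L
  far <- matrix(0L, 20, 20); far[10, 3:7] <- 1L; far[10, 11] <- 1L
  out_near <- obr_restrict(manual_binary(near), occ2)
  expect_equal(sum(out_near$values == 1L), 6)   # 1.5 map units <= cutoff 2
  out_far <- obr_restrict(manual_binary(far), occ2)
  expect_equal(sum(out_far$values == 1L), 5)    # 3 map units > cutoff 2

  expect_warning(obr_restrict(bmap, occ[1, ]), "fewer than 2")
})

test_that("OBR is contractive and idempotent on random maps", {
  withr::with_seed(8, {
    for (i in 1:25) {
      m <- matrix(rbinom(400, 1, 0.25), 20, 20)
      occ <- tibble::tibble(x = runif(4, 0, 20), y = runif(4, 0, 20))
      b <- manual_binary(m)
      r1 <- obr_restrict(b, occ)
      expect_true(all(r1$values <= b$values))
      r2 <- obr_restrict(r1, occ)
      expect_identical(r2$values, r1$values)
    }
  })
})

test_that("projection reuses the calibration threshold and handles extremes", {
  env <- small_world(30, 30, n_layers = 2, seed = 52)
  vsp <- driven_species(env, "bio1", prevalence = 0.35)
  occ <- sample_occurrences(vsp, env, 80, seed = 17)
  bg <- sample_background(!env$nodata, env, 500, seed = 18)
  m <- fit_maxent(occ, env, feature_spec(c("linear", "quadratic")), bg)
  sp <- score_points(m, env, occ$x, occ$y)
  sb <- score_points(m, env, bg$x, bg$y)
  thr <- max_tss_threshold(sp, sb)$threshold

  cur <- binarize(predict(m, env), thr, scenario = "current")
  same <- project_model(m, env, thr, scenario = "future")
  expect_identical(same$values, cur$values)

  hostile <- manual_stack(bio1 = matrix(-100, 30, 30),
                          bio2 = matrix(-100, 30, 30))
  empty <- project_model(m, hostile, thr)
  expect_equal(sum(empty$values, na.rm = TRUE), 0)

  all_in <- project_model(m, env, 0)
  expect_true(all(all_in$values[!env$nodata] == 1L))
  expect_error(project_model(m, env, 1.5), "threshold")
})
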