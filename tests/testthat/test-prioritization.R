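mk_delta <- function(m) stacksdm:::grid_map(m, env_grid(nrow(m), ncol(m)),
                                            "delta_richness_map")

test_that("vegetation change classes follow the transition rules", {
  cur <- manual_binary(matrix(c(1L, 1L, 0L, 0L), 2, 2))
  fut <- manual_binary(matrix(c(0L, 1L, 1L, 0L), 2, 2))
  vc <- vegetation_change_class(cur, fut)
  expect_equal(vc$values[1, 1], "less_vegetation")  # 1 -> 0 lost
  expect_equal(vc$values[2, 1], "more_vegetation")  # 1 -> 1 retained
  expect_equal(vc$values[1, 2], "more_vegetation")  # 0 -> 1 gained
  expect_true(is.na(vc$values[2, 2]))               # never vegetated
})

test_that("the four priority regions partition the classified cells", {
  ds <- mk_delta(matrix(c(-3L, 2L, -1L, 4L, 0L, -2L), 2, 3))
  veg <- vegetation_change_class(
    manual_binary(matrix(c(1L, 1L, 1L, 1L, 1L, 0L), 2, 3)),
    manual_binary(matrix(c(0L, 0L, 1L, 1L, 1L, 0L), 2, 3)))
  pm <- classify_regions(ds, veg)
  expect_equal(pm$values[1, 1], 1L)  # loss + less vegetation: restoration
  expect_equal(pm$values[2, 1], 2L)  # gain + less vegetation
  expect_equal(pm$values[1, 2], 3L)  # loss + more vegetation
  expect_equal(pm$values[2, 2], 4L)  # gain + more vegetation: refugia
  expect_true(is.na(pm$values[1, 3]))  # dS = 0 excluded by default
  expect_true(is.na(pm$values[2, 3]))  # vegetation never present

  pm0 <- classify_regions(ds, veg, zero_to = "low_risk")
  expect_equal(pm0$values[1, 3], 4L)

  # partition: each classified cell carries exactly one region label
  counts <- table(pm$values)
  expect_equal(sum(counts), 4)
})

test_that("engineered region proportions are recovered within one cell", {
  # 40 / 10 / 20 / 30 % of 100 analyzed cells
  regions <- rep(1:4, c(40, 10, 20, 30))
  ds_m <- matrix(ifelse(regions %in% c(1, 3), -1L, 1L), 10, 10)
  veg_cur <- matrix(1L, 10, 10)
  veg_fut <- matrix(ifelse(regions %in% c(1, 2), 0L, 1L), 10, 10)
  pm <- classify_regions(mk_delta(ds_m),
                         vegetation_change_class(manual_binary(veg_cur),
                                                 manual_binary(veg_fut)))
  got <- as.vector(table(factor(pm$values, levels = 1:4)))
  expect_true(all(abs(got - c(40, 10, 20, 30)) <= 1))
})

test_that("protected-area summaries recommend by fraction and split additively", {
  regions <- rep(1:4, c(40, 10, 20, 30))
  ds_m <- matrix(ifelse(regions %in% c(1, 3), -1L, 1L), 10, 10)
  veg_fut <- matrix(ifelse(regions %in% c(1, 2), 0L, 1L), 10, 10)
  pm <- classify_regions(mk_delta(ds_m),
                         vegetation_change_class(
                           manual_binary(matrix(1L, 10, 10)),
                           manual_binary(veg_fut)))
  g <- env_grid(10, 10)

  # one PA 60% region 1 / 40% region 4 -> both lists at fraction 0.25
  pa_v <- matrix(0L, 10, 10)
  pa_v[which(regions == 1)[1:15]] <- 1L
  pa_v[which(regions == 4)[1:10]] <- 1L
  pa <- stacksdm:::grid_map(pa_v, g, "pa_mask")
  ps <- summarize_protected_areas(pm, pa, reporting_fraction = 0.25)
  expect_equal(nrow(ps$per_pa), 1)
  recs <- ps$per_pa$recommendations
  expect_match(recs, "restoration")
  expect_match(recs, "refugia")
  expect_false(grepl("management", recs))

  # fully region-4 PA -> refugia only
  pa4 <- matrix(0L, 10, 10); pa4[which(regions == 4)] <- 1L
  ps4 <- summarize_protected_areas(pm, stacksdm:::grid_map(pa4, g, "pa_mask"))
  expect_equal(ps4$per_pa$recommendations, "habitat refugia")

  # additivity: splitting a PA reproduces the merged per-region areas
  split_v <- pa_v
  split_v[which(regions == 1)[1:8]] <- 2L
  split_pa <- stacksdm:::grid_map(split_v, g, "pa_mask")
  ps_split <- summarize_protected_areas(pm, split_pa)
  merged <- colSums(ps_split$per_pa[, paste0("cells_region_", 1:4)])
  expect_equal(unname(merged),
               unname(unlist(ps$per_pa[, paste0("cells_region_", 1:4)])))
})

test_that("KS effectiveness test matches a brute-force ECDF scan", {
  g <- env_grid(6, 10)
  rv <- matrix(0L, 6, 10)
  withr::with_seed(11, {
    inside_vals <- sample(0:8, 30, replace = TRUE)
    outside_vals <- sample(0:5, 30, replace = TRUE)
  })
  rv[1:30] <- inside_vals; rv[31:60] <- outside_vals
  rich <- stacksdm:::grid_map(rv, g, "richness_map")
  pa_v <- matrix(0L, 6, 10); pa_v[1:30] <- 1L
  pa <- stacksdm:::grid_map(pa_v, g, "pa_mask")
  res <- pa_effectiveness_test(rich, pa)

  brks <- sort(unique(c(inside_vals, outside_vals)))
  d_brute <- max(vapply(brks, function(b)
    abs(mean(inside_vals <= b) - mean(outside_vals <= b)), numeric(1)))
  expect_equal(res$d_statistic, d_brute)

  same <- pa_effectiveness_test(
    stacksdm:::grid_map(matrix(rep(inside_vals, 2), 6, 10), g,
                        "richness_map"), pa)
  expect_equal(same$d_statistic, 0)

  disjoint <- matrix(0L, 6, 10)
  disjoint[1:30] <- 100L; disjoint[31:60] <- 1L
  expect_equal(pa_effectiveness_test(
    stacksdm:::grid_map(disjoint, g, "richness_map"), pa)$d_statistic, 1)

  # invariance under strictly monotone transforms
  res2 <- pa_effectiveness_test(
    stacksdm:::grid_map(rv * 10L + 3L, g, "richness_map"), pa)
  expect_equal(res2$d_statistic, res$d_statistic)

  all_pa <- stacksdm:::grid_map(matrix(1L, 6, 10), g, "pa_mask")
  expect_error(pa_effectiveness_test(rich, all_pa), "empty")
})
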