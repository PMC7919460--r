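#' Classify native-vegetation change per cell
#'
#' A cell is `"less_vegetation"` if native vegetation is lost (1 to 0),
#' `"more_vegetation"` if retained or gained (1 to 1, 0 to 1), and
#' unclassified (`NA`) if never vegetated — those cells fall outside the
#' 2x2 prioritization.
#'
#' @param current_veg,future_veg Binary vegetation `binary_map`s on one
#'   grid.
#' @return A `veg_change_map` grid map with character values.
#' @export
vegetation_change_class <- function(current_veg, future_veg) {
  if (!grids_equal(current_veg$grid, future_veg$grid))
    stop("vegetation maps are on different grids")
  cur <- current_veg$values; fut <- future_veg$values
  out <- matrix(NA_character_, nrow(cur), ncol(cur))
  out[!is.na(cur) & !is.na(fut) & cur == 1L & fut == 0L] <- "less_vegetation"
  out[!is.na(cur) & !is.na(fut) & fut == 1L] <- "more_vegetation"
  grid_map(out, current_veg$grid, "veg_change_map")
}

#' Four-region conservation prioritization
#'
#' Crosses richness change with vegetation change into the standard 2x2:
#' region 1 (habitat restoration) = richness loss and vegetation loss;
#' region 2 (low priority, habitat management) = richness gain and
#' vegetation loss; region 3 (low priority, species management) =
#' richness loss and vegetation kept; region 4 (habitat refugia) =
#' richness gain and vegetation kept. Cells with dS = 0 are excluded by
#' default (`zero_to = "none"`) since the rule names only gains and
#' losses; they may instead be mapped to the low-risk side.
#'
#' @param delta_s A `delta_richness_map` from [richness_change()].
#' @param veg_class A `veg_change_map` from [vegetation_change_class()].
#' @param zero_to `"none"` (default) or `"low_risk"`: how to treat
#'   dS = 0 cells.
#' @return A `priority_map` grid map with integer regions 1-4 (NA where
#'   unclassified).
#' @export
classify_regions <- function(delta_s, veg_class, zero_to = c("none",
                                                             "low_risk")) {
  zero_to <- match.arg(zero_to)
  if (!grids_equal(delta_s$grid, veg_class$grid))
    stop("inputs are on different grids")
  ds <- delta_s$values
  vc <- veg_class$values
  gain <- !is.na(ds) & (ds > 0 | (zero_to == "low_risk" & ds == 0))
  loss <- !is.na(ds) & ds < 0
  region <- matrix(NA_integer_, nrow(ds), ncol(ds))
  region[loss & !is.na(vc) & vc == "less_vegetation"] <- 1L
  region[gain & !is.na(vc) & vc == "less_vegetation"] <- 2L
  region[loss & !is.na(vc) & vc == "more_vegetation"] <- 3L
  region[gain & !is.na(vc) & vc == "more_vegetation"] <- 4L
  grid_map(region, delta_s$grid, "priority_map")
}

#' Human-readable names of the four priority regions
#' @return A tibble with `region`, `label`.
#' @export
region_labels <- function() {
  tibble::tibble(
    region = 1:4,
    label = c("habitat restoration", "low priority (habitat management)",
              "low priority (species management)", "habitat refugia")
  )
}

#' Summarize priority regions within protected areas
#'
#' Per protected area: cell counts and fractions by region, mean current
#' and future richness, and the recommendation list — every region whose
#' within-PA fraction (of classified cells) reaches `reporting_fraction`
#' (so one PA may carry several recommendations). Also computes
#' aggregate region fractions over all PAs, both area-based and
#' PA-count-based.
#'
#' @param priority A `priority_map`.
#' @param pa_mask A `pa_mask` grid map (patch ids > 0).
#' @param reporting_fraction Fraction of a PA's classified area a region
#'   must reach to be recommended (default 0.25).
#' @param richness_current,richness_future Optional `richness_map`s for
#'   per-PA mean richness columns.
#' @return A list: `per_pa` (tibble: `pa_id`, `cells`, `cells_region_1..4`,
#'   `fraction_region_1..4`, `recommendations`, optional mean richness),
#'   `aggregate` (tibble: `region`, `label`, `area_fraction`,
#'   `pa_count_fraction`).
#' @export
summarize_protected_areas <- function(priority, pa_mask,
                                      reporting_fraction = 0.25,
                                      richness_current = NULL,
                                      richness_future = NULL) {
  if (!grids_equal(priority$grid, pa_mask$grid))
    stop("priority map and PA mask are on different grids")
  ids <- sort(unique(pa_mask$values[!is.na(pa_mask$values) &
                                      pa_mask$values > 0]))
  labels <- region_labels()
  per_pa <- purrr::map_dfr(ids, function(id) {
    in_pa <- !is.na(pa_mask$values) & pa_mask$values == id
    if (!any(in_pa)) {
      warning("protected area ", id, " is empty; skipped")
      return(NULL)
    }
    reg <- priority$values[in_pa]
    n_class <- sum(!is.na(reg))
    counts <- vapply(1:4, function(r) sum(reg == r, na.rm = TRUE),
                     integer(1))
    fr <- if (n_class > 0) counts / n_class else rep(NA_real_, 4)
    rec <- labels$label[!is.na(fr) & fr >= reporting_fraction]
    row <- tibble::tibble(
      pa_id = id, cells = sum(in_pa), cells_classified = n_class,
      cells_region_1 = counts[1], cells_region_2 = counts[2],
      cells_region_3 = counts[3], cells_region_4 = counts[4],
      fraction_region_1 = fr[1], fraction_region_2 = fr[2],
      fraction_region_3 = fr[3], fraction_region_4 = fr[4],
      recommendations = paste(rec, collapse = "; ")
    )
    if (!is.null(richness_current))
      row$richness_current <- mean(richness_current$values[in_pa],
                                   na.rm = TRUE)
    if (!is.null(richness_future))
      row$richness_future <- mean(richness_future$values[in_pa],
                                  na.rm = TRUE)
    row
  })
  total_class <- sum(per_pa$cells_classified)
  aggregate <- dplyr::mutate(
    labels,
    area_fraction = vapply(1:4, function(r)
      sum(per_pa[[paste0("cells_region_", r)]]) / max(total_class, 1),
      numeric(1)),
    pa_count_fraction = vapply(1:4, function(r)
      mean(per_pa[[paste0("fraction_region_", r)]] >= reporting_fraction,
           na.rm = TRUE), numeric(1))
  )
  list(per_pa = per_pa, aggregate = aggregate)
}

#' Protected-area effectiveness test on richness
#'
#' Two-sample Kolmogorov-Smirnov test comparing per-cell species
#' richness inside versus outside protected areas; D is the maximum
#' absolute gap between the two empirical CDFs, with the p-value from
#' the asymptotic KS distribution. D is invariant to any strictly
#' monotone transform of richness.
#'
#' @param richness A `richness_map`.
#' @param pa_mask A `pa_mask` grid map.
#' @return A tibble with `d_statistic`, `p_value`, `n_inside`,
#'   `n_outside`.
#' @export
pa_effectiveness_test <- function(richness, pa_mask) {
  if (!grids_equal(richness$grid, pa_mask$grid))
    stop("richness map and PA mask are on different grids")
  land <- !is.na(pa_mask$values) & !is.na(richness$values)
  inside <- richness$values[land & pa_mask$values > 0]
  outside <- richness$values[land & pa_mask$values == 0]
  if (!length(inside) || !length(outside))
    stop("one of the samples (inside/outside protected areas) is empty")
  kt <- suppressWarnings(stats::ks.test(inside, outside, exact = FALSE))
  tibble::tibble(d_statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 n_inside = length(inside), n_outside = length(outside))
}

#' @export
autoplot.priority_map <- function(object, ...) {
  df <- as_tibble.grid_map(object)
  df$label <- factor(df$value, levels = 1:4, labels = region_labels()$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(
      values = c("#d7301f", "#fdae61", "#abd9e9", "#1a9850"),
      na.value = "grey90", name = NULL, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL)
}
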