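#' Stack binary maps into species richness
#'
#' Per-cell alpha diversity: the sum over species of the binary
#' presence/absence maps (S at a cell = number of species present
#' there).
#'
#' @param binaries List of `binary_map`s on one grid.
#' @param scenario Scenario label stored on the result.
#' @return A `richness_map` grid map with `n_species` attached.
#' @export
stack_richness <- function(binaries, scenario = "current") {
  stopifnot(length(binaries) >= 1)
  ref <- binaries[[1]]
  bad <- which(!vapply(binaries, function(b) grids_equal(b$grid, ref$grid),
                       logical(1)))
  if (length(bad))
    stop("binary map(s) on a different grid: ",
         paste(vapply(binaries[bad],
                      function(b) b$species %||% "?", character(1)),
               collapse = ", "))
  s <- Reduce(`+`, lapply(binaries, function(b) {
    v <- b$values
    v[is.na(v)] <- 0L
    v
  }))
  nodata <- Reduce(`&`, lapply(binaries, function(b) is.na(b$values)))
  s[nodata] <- NA_integer_
  grid_map(s, ref$grid, "richness_map", scenario = scenario,
           n_species = length(binaries))
}

#' Per-species range shift between two scenarios
#'
#' The percent variation in the suitable-cell count,
#' R = (A_future - A_current) / A_current * 100. Negative values are
#' contractions, positive expansions, future area zero a projected
#' extinction; species with no current area are flagged `not_modeled`.
#'
#' @param current,future `binary_map`s for one species on one grid.
#' @param cell_area Area of one cell (for the km2-style columns);
#'   defaults to cell_size squared.
#' @return A one-row tibble: `species`, `area_current`, `area_future`
#'   (cell counts), `area_current_km2`, `area_future_km2`,
#'   `shift_percent`, `status`.
#' @export
range_shift <- function(current, future, cell_area = NULL) {
  if (!grids_equal(current$grid, future$grid))
    stop("current and future maps are on different grids")
  if (is.null(cell_area)) cell_area <- current$grid$cell_size^2
  a0 <- map_area(current)
  a1 <- map_area(future)
  if (a0 == 0) {
    r <- NA_real_
    status <- "not_modeled"
  } else {
    r <- (a1 - a0) / a0 * 100
    status <- if (a1 == 0) "extinct"
              else if (r < 0) "contraction"
              else if (r > 0) "expansion"
              else "stable"
  }
  tibble::tibble(
    species = current$species %||% NA_character_,
    area_current = a0, area_future = a1,
    area_current_km2 = a0 * cell_area, area_future_km2 = a1 * cell_area,
    shift_percent = r, status = status
  )
}

#' Species-richness change between scenarios
#'
#' Per-cell difference dS = S_future - S_current, with a companion
#' risk classification: dS > 0 low risk, dS < 0 high risk, dS = 0
#' neutral.
#'
#' @param current,future `richness_map`s on one grid.
#' @return A `delta_richness_map` grid map; its `risk` field is a
#'   character matrix (`"low"`, `"high"`, `"neutral"`, NA on nodata).
#' @export
richness_change <- function(current, future) {
  if (!grids_equal(current$grid, future$grid))
    stop("richness maps are on different grids")
  if (identical(current$scenario, future$scenario))
    warning("both richness maps carry scenario '", current$scenario,
            "'; is this intended?")
  ds <- future$values - current$values
  risk <- matrix(NA_character_, nrow(ds), ncol(ds))
  risk[!is.na(ds) & ds > 0] <- "low"
  risk[!is.na(ds) & ds < 0] <- "high"
  risk[!is.na(ds) & ds == 0] <- "neutral"
  grid_map(ds, current$grid, "delta_richness_map", risk = risk)
}

#' Cohort summary of range shifts
#'
#' Counts and group statistics over a table of per-species shifts.
#' Extinct species (future area 0) are members of the contracting group
#' (shift -100) and are also counted separately.
#'
#' @param shifts Tibble from [range_shift()] rows.
#' @return A tibble with one row per group (`contraction`, `expansion`,
#'   `extinct`, `stable`, `not_modeled`): `n`, `mean_shift`, `se_shift`.
#' @export
summarize_shifts <- function(shifts) {
  if (!nrow(shifts))
    return(tibble::tibble(group = character(), n = integer(),
                          mean_shift = numeric(), se_shift = numeric()))
  grp <- function(df, name) {
    v <- df$shift_percent
    tibble::tibble(group = name, n = nrow(df),
                   mean_shift = if (nrow(df)) mean(v) else NA_real_,
                   se_shift = if (nrow(df) > 1) stats::sd(v) / sqrt(nrow(df))
                              else NA_real_)
  }
  dplyr::bind_rows(
    grp(dplyr::filter(shifts, .data$status %in% c("contraction", "extinct")),
        "contraction"),
    grp(dplyr::filter(shifts, .data$status == "expansion"), "expansion"),
    grp(dplyr::filter(shifts, .data$status == "extinct"), "extinct"),
    grp(dplyr::filter(shifts, .data$status == "stable"), "stable"),
    grp(dplyr::filter(shifts, .data$status == "not_modeled"), "not_modeled")
  )
}
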