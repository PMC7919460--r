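#' Clean occurrence records against a calibration stack
#'
#' Collapses exact-duplicate coordinates (within species) to a single
#' record and drops points falling off-grid or on nodata cells. Removal
#' counts by reason are attached as the `"cleaning_report"` attribute and
#' returned tidily by [cleaning_report()].
#'
#' @param raw A data frame with columns `species`, `x`, `y` (planar
#'   coordinates in the grid's units); extra columns are kept.
#' @param env The calibration [env_stack()].
#' @return A tibble of surviving records (possibly zero rows).
#' @export
clean_occurrences <- function(raw, env) {
  stopifnot(all(c("species", "x", "y") %in% names(raw)),
            inherits(env, "env_stack"))
  raw <- tibble::as_tibble(raw)
  n0 <- nrow(raw)
  dedup <- dplyr::distinct(raw, .data$species, .data$x, .data$y,
                           .keep_all = TRUE)
  n_dup <- n0 - nrow(dedup)
  rc <- coord_cell(env$grid, dedup$x, dedup$y)
  off <- is.na(rc$row)
  idx <- (rc$col - 1L) * env$grid$rows + rc$row
  on_nodata <- !off & env$nodata[idx]
  out <- dedup[!off & !on_nodata, , drop = FALSE]
  report <- tibble::tibble(
    reason = c("duplicate", "off_grid", "nodata"),
    removed = c(n_dup, sum(off), sum(on_nodata))
  )
  attr(out, "cleaning_report") <- report
  out
}

#' Removal counts from the last cleaning
#' @param occ Output of [clean_occurrences()].
#' @return A tibble with columns `reason`, `removed`.
#' @export
cleaning_report <- function(occ) {
  attr(occ, "cleaning_report") %||%
    tibble::tibble(reason = character(), removed = integer())
}

#' Drop species with too few records
#'
#' Species whose record count is below `minimum` are excluded from
#' modeling (the conventional floor is 10; a species with exactly
#' `minimum` records is retained).
#'
#' @param occ Occurrence tibble with a `species` column.
#' @param minimum Minimum record count to retain a species.
#' @return A list: `kept` (tibble of retained records) and `excluded`
#'   (tibble of `species`, `n` for dropped species).
#' @export
min_records_filter <- function(occ, minimum = 10) {
  occ <- tibble::as_tibble(occ)
  counts <- dplyr::count(occ, .data$species)
  excluded <- dplyr::filter(counts, .data$n < minimum)
  kept <- dplyr::anti_join(occ, excluded, by = "species")
  list(kept = kept, excluded = excluded)
}

# Pairwise squared Euclidean distances among points in a two-column matrix.
pair_dist <- function(xy) as.matrix(stats::dist(xy))

#' Spatially thin occurrence records
#'
#' Enforces a minimum pairwise distance by repeated randomized removal:
#' in each of `reps` attempts, points violating the distance are removed
#' one at a time (the point with the most too-close neighbors first, ties
#' broken at random) until no violation remains; the attempt keeping the
#' most points wins, ties broken by attempt order. This mirrors the
#' standard spThin contract and is reproducible under `seed`. Thinning is
#' per species when several are present.
#'
#' @param occ Occurrence tibble (`species`, `x`, `y`).
#' @param min_distance Minimum allowed pairwise distance (map units, > 0).
#' @param seed Integer seed.
#' @param reps Number of randomized attempts.
#' @return A thinned tibble (a subset of the input rows).
#' @export
thin_occurrences <- function(occ, min_distance, seed = 1, reps = 100) {
  stopifnot(min_distance > 0, reps >= 1)
  occ <- tibble::as_tibble(occ)
  if (nrow(occ) <= 1) return(occ)
  dplyr::group_by(occ, .data$species) |>
    dplyr::group_modify(function(df, key) {
      keep <- thin_one(as.matrix(df[, c("x", "y")]), min_distance,
                       child_seed(seed, "thin", key$species[[1]]), reps)
      df[keep, , drop = FALSE]
    }) |>
    dplyr::ungroup()
}

thin_one <- function(xy, min_distance, seed, reps) {
  n <- nrow(xy)
  if (n <= 1) return(seq_len(n))
  d <- pair_dist(xy)
  conflict <- d < min_distance & upper.tri(d) | d < min_distance & lower.tri(d)
  diag(conflict) <- FALSE
  if (!any(conflict)) return(seq_len(n))
  withr::with_seed(seed, {
    best <- integer(0)
    for (r in seq_len(reps)) {
      alive <- rep(TRUE, n)
      cm <- conflict
      repeat {
        deg <- rowSums(cm[, alive, drop = FALSE]) * alive
        if (max(deg) == 0) break
        worst <- which(deg == max(deg))
        drop1 <- safe_sample(worst, 1)
        alive[drop1] <- FALSE
        cm[drop1, ] <- FALSE
        cm[, drop1] <- FALSE
      }
      if (sum(alive) > length(best)) best <- which(alive)
    }
    best
  })
}

# Helper: suggest a thinning distance as the first lag at which a
# Moran's-I correlogram of presence indicators drops below `threshold`.
# Offered as guidance only; never auto-applied.
#' Suggest a thinning distance from a Moran's-I correlogram
#'
#' Computes Moran's I of the presence/absence indicator over land cells
#' in distance bins and returns the center of the first bin where I
#' falls below `threshold` — a data-driven candidate for
#' [thin_occurrences()]'s `min_distance`.
#'
#' @param occ Occurrence tibble for a single species.
#' @param env Calibration [env_stack()].
#' @param n_bins Number of distance bins.
#' @param threshold Moran's-I cutoff.
#' @param max_cells Cap on land cells used (subsampled deterministically).
#' @return A single suggested distance (map units), or the largest bin
#'   center if the correlogram never drops below the threshold.
#' @export
suggest_thinning_distance <- function(occ, env, n_bins = 12,
                                      threshold = 0.1, max_cells = 3000) {
  cells <- land_cells(env)
  if (length(cells) > max_cells)
    cells <- cells[round(seq(1, length(cells), length.out = max_cells))]
  nr <- env$grid$rows
  ctr <- cell_center(env$grid, ((cells - 1L) %% nr) + 1L,
                     ((cells - 1L) %/% nr) + 1L)
  rc <- coord_cell(env$grid, occ$x, occ$y)
  occ_idx <- unique((rc$col - 1L) * nr + rc$row)
  z <- as.numeric(cells %in% occ_idx)
  z <- z - mean(z)
  d <- pair_dist(cbind(ctr$x, ctr$y))
  breaks <- seq(0, max(d), length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  n <- length(z)
  moran <- vapply(seq_len(n_bins), function(b) {
    w <- d > breaks[b] & d <= breaks[b + 1]
    s0 <- sum(w)
    if (s0 == 0) return(NA_real_)
    (n / s0) * sum(w * outer(z, z)) / sum(z^2)
  }, numeric(1))
  below <- which(!is.na(moran) & moran < threshold)
  if (length(below)) centers[below[1]] else centers[n_bins]
}

#' Assign k-fold labels to occurrence records
#'
#' Random partition into `k` folds of as-equal-as-possible size (sizes
#' differ by at most one), per species, reproducible under `seed`. With
#' fewer records than folds every record becomes its own fold and a
#' warning is raised.
#'
#' @param occ Occurrence tibble (`species`, `x`, `y`).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return The tibble with an integer `fold` column added.
#' @export
assign_folds <- function(occ, k = 5, seed = 1) {
  stopifnot(k >= 1)
  occ <- tibble::as_tibble(occ)
  dplyr::group_by(occ, .data$species) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < k) {
        warning("species '", key$species[[1]], "' has ", n,
                " records for ", k, " folds; one record per fold")
        df$fold <- seq_len(n)
      } else {
        df$fold <- withr::with_seed(
          child_seed(seed, "folds", key$species[[1]]),
          sample(rep_len(seq_len(k), n))
        )
      }
      df
    }) |>
    dplyr::ungroup()
}
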