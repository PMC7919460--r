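#' Screen covariate layers for collinearity
#'
#' Pairwise Pearson correlations are computed over non-nodata cells
#' (subsampled to at most `max_cells`, seed-fixed, when the grid is
#' large). Offending pairs (|r| above `threshold`) are resolved in
#' descending |r| order; within a pair the layer appearing later in
#' `preference` is dropped. Zero-variance layers are dropped first with
#' a warning. Re-screening the kept stack changes nothing.
#'
#' @param env An [env_stack()] with at least two layers.
#' @param threshold Absolute-correlation cutoff (the conventional screen
#'   is 0.7).
#' @param preference Character vector ordering layers from most to least
#'   preferred; defaults to stack order.
#' @param max_cells Cell cap for the correlation estimate.
#' @return A list: `kept` ([env_stack()]), `dropped` (tibble of
#'   `dropped`, `against`, `r`), and `correlations` (matrix over the
#'   input layers).
#' @export
collinearity_screen <- function(env, threshold = 0.7,
                                preference = layer_names(env),
                                max_cells = 50000) {
  stopifnot(inherits(env, "env_stack"), length(env$layers) >= 2)
  if (!setequal(preference, layer_names(env)))
    stop("preference must order exactly the stack's layers")
  m <- land_matrix(env)
  if (nrow(m) > max_cells) {
    keep <- withr::with_seed(1L, sample(nrow(m), max_cells))
    m <- m[keep, , drop = FALSE]
  }
  sds <- apply(m, 2, stats::sd)
  dropped <- tibble::tibble(dropped = character(), against = character(),
                            r = numeric())
  flat <- names(sds)[sds == 0]
  if (length(flat)) {
    warning("dropping constant layer(s): ", paste(flat, collapse = ", "))
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      dropped = flat, against = NA_character_, r = NA_real_))
  }
  alive <- setdiff(layer_names(env), flat)
  cm <- suppressWarnings(stats::cor(m))
  pref_rank <- stats::setNames(seq_along(preference), preference)
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    diag(sub) <- 0
    worst <- max(abs(sub), na.rm = TRUE)
    if (length(alive) < 2 || worst <= threshold) break
    ij <- which(abs(sub) == worst, arr.ind = TRUE)[1, ]
    a <- alive[ij[1]]; b <- alive[ij[2]]
    loser <- if (pref_rank[a] > pref_rank[b]) a else b
    winner <- setdiff(c(a, b), loser)
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      dropped = loser, against = winner, r = cm[a, b]))
    alive <- setdiff(alive, loser)
  }
  if (!length(alive)) stop("screening removed every layer")
  list(kept = subset_layers(env, alive), dropped = dropped,
       correlations = cm)
}

subset_layers <- function(env, keep) {
  env_stack(env$layers[keep], env$grid, nodata = env$nodata,
            roles = env$roles[keep])
}

#' Remove named layers from a stack
#'
#' Used for covariates known a priori to carry spatial artefacts; the
#' order of the remaining layers is preserved. Removing every layer is
#' refused.
#'
#' @param env An [env_stack()].
#' @param names Layer names to drop.
#' @return The reduced [env_stack()].
#' @export
exclude_layers <- function(env, names) {
  unknown <- setdiff(names, layer_names(env))
  if (length(unknown))
    stop("unknown layer(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(layer_names(env), collapse = ", "))
  keep <- setdiff(layer_names(env), names)
  if (!length(keep)) stop("cannot exclude every layer (empty stack)")
  subset_layers(env, keep)
}

#' Simple-average ensemble of climate-model members
#'
#' Cell-wise, layer-wise arithmetic mean across members sharing one grid
#' and layer set; a cell is nodata in the ensemble if it is nodata in any
#' member.
#'
#' @param members A list of [env_stack()]s.
#' @return The ensemble [env_stack()].
#' @export
ensemble_mean <- function(members) {
  stopifnot(is.list(members), length(members) >= 1)
  ref <- members[[1]]
  for (i in seq_along(members)) {
    m <- members[[i]]
    if (!grids_equal(m$grid, ref$grid))
      stop("member ", i, " grid differs: ", m$grid$rows, "x", m$grid$cols,
           " vs ", ref$grid$rows, "x", ref$grid$cols)
    if (!identical(sort(layer_names(m)), sort(layer_names(ref))))
      stop("member ", i, " layer set differs: {",
           paste(layer_names(m), collapse = ","), "} vs {",
           paste(layer_names(ref), collapse = ","), "}")
  }
  nodata <- Reduce(`|`, lapply(members, `[[`, "nodata"))
  layers <- stats::setNames(lapply(layer_names(ref), function(nm) {
    Reduce(`+`, lapply(members, function(m) {
      v <- m$layers[[nm]]
      v[is.na(v)] <- 0  # masked below via ensemble nodata
      v
    })) / length(members)
  }), layer_names(ref))
  env_stack(layers, ref$grid, nodata = nodata, roles = ref$roles)
}
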