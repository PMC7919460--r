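#' Environmental raster stack
#'
#' The covariate container for calibration and transfer: a set of named,
#' aligned layers (matrices) on one [env_grid()], sharing a single nodata
#' mask (the "sea"). Each layer carries a role tag — `"temperature"`,
#' `"precipitation"` or `"other"` — used by the synthetic climate-shift
#' generator and by reporting.
#'
#' @param layers Named list of numeric matrices, all of identical dimension.
#' @param grid An [env_grid()] matching the matrix dimensions.
#' @param nodata Logical matrix, `TRUE` where cells are nodata; defaults to
#'   cells that are `NA` in any layer.
#' @param roles Character vector (recycled or named by layer) of per-layer
#'   role tags.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, grid, nodata = NULL, roles = "other") {
  stopifnot(is.list(layers), length(layers) >= 1)
  nms <- names(layers)
  if (is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms))
    stop("layers must have unique, non-empty names")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != grid$rows) || any(dims[2, ] != grid$cols))
    stop("all layers must match the grid dimensions")
  if (is.null(nodata)) {
    nodata <- Reduce(`|`, lapply(layers, is.na))
  }
  stopifnot(is.logical(nodata), all(dim(nodata) == c(grid$rows, grid$cols)))
  if (!is.null(names(roles))) {
    roles <- roles[nms]
  } else {
    roles <- rep_len(roles, length(layers))
    names(roles) <- nms
  }
  roles[is.na(roles)] <- "other"
  layers <- lapply(layers, function(m) {
    m[nodata] <- NA_real_
    m
  })
  structure(
    list(layers = layers, grid = grid, nodata = nodata, roles = roles),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layer(s) on a %d x %d grid (%.1f%% nodata)\n",
              length(x$layers), x$grid$rows, x$grid$cols,
              100 * mean(x$nodata)))
  for (nm in names(x$layers)) {
    v <- x$layers[[nm]]
    cat(sprintf("  %-12s [%s] range %.3g .. %.3g\n", nm, x$roles[[nm]],
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
layer_names <- function(env) names(env$layers)

#' Number of non-nodata (land) cells
#' @param env An `env_stack`.
#' @export
n_land <- function(env) sum(!env$nodata)

# Linear indices of land cells (column-major, stable ordering).
land_cells <- function(env) which(!env$nodata)

#' Covariate values at land cells
#'
#' @param env An `env_stack`.
#' @param cells Optional linear cell indices; defaults to all land cells.
#' @return A numeric matrix, one row per cell, one column per layer.
#' @export
land_matrix <- function(env, cells = land_cells(env)) {
  out <- vapply(env$layers, function(m) m[cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, layer_names(env)))
  out
}

# Covariate values at arbitrary (x, y) points; NA off-grid or on nodata.
extract_values <- function(env, x, y) {
  rc <- coord_cell(env$grid, x, y)
  idx <- ifelse(is.na(rc$row), NA_integer_, (rc$col - 1L) * env$grid$rows + rc$row)
  out <- matrix(NA_real_, length(x), length(env$layers),
                dimnames = list(NULL, layer_names(env)))
  ok <- !is.na(idx)
  if (any(ok)) out[ok, ] <- vapply(env$layers, function(m) m[idx[ok]],
                                   numeric(sum(ok)))
  out
}

#' Long-format view of a stack
#'
#' @param x An `env_stack`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `x`, `y`, `layer`, `value`
#'   (nodata cells carry `NA`).
#' @export
as_tibble.env_stack <- function(x, ...) {
  grid <- x$grid
  base <- tidyr::expand_grid(col = seq_len(grid$cols), row = seq_len(grid$rows))
  ctr <- cell_center(grid, base$row, base$col)
  purrr::imap_dfr(x$layers, function(m, nm) {
    tibble::tibble(row = base$row, col = base$col, x = ctr$x, y = ctr$y,
                   layer = nm, value = as.vector(m))
  })
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.env_stack <- function(object, ...) {
  df <- as_tibble.env_stack(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

# Single-layer gridded results share one light S3 shape.
grid_map <- function(values, grid, class, ...) {
  stopifnot(all(dim(values) == c(grid$rows, grid$cols)))
  structure(list(values = values, grid = grid, ...), class = c(class, "grid_map"))
}

#' @export
print.grid_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("<%s> %d x %d grid; value range %s .. %s\n", class(x)[1],
              x$grid$rows, x$grid$cols,
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

#' @export
as_tibble.grid_map <- function(x, ...) {
  grid <- x$grid
  base <- tidyr::expand_grid(col = seq_len(grid$cols), row = seq_len(grid$rows))
  ctr <- cell_center(grid, base$row, base$col)
  tibble::tibble(row = base$row, col = base$col, x = ctr$x, y = ctr$y,
                 value = as.vector(x$values))
}

#' @export
autoplot.grid_map <- function(object, ...) {
  df <- as_tibble.grid_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL)
}

binary_map <- function(values, grid, species = NA_character_,
                       scenario = "current") {
  mode(values) <- "integer"
  grid_map(values, grid, "binary_map", species = species, scenario = scenario)
}

#' Suitable-cell count of a binary map
#' @param map A `binary_map`.
#' @export
map_area <- function(map) sum(map$values == 1L, na.rm = TRUE)
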