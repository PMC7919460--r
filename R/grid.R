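#' Grid geometry for raster layers
#'
#' All rasters in stacksdm live on a planar, north-up, row-major grid:
#' row 1 is the northernmost row, cells are squares of side `cell_size`
#' in abstract map units, and a cell's coordinate is its center. Cell
#' intervals are half-open so every point maps to exactly one cell.
#'
#' @param rows,cols Grid dimensions (each at least 1).
#' @param xmin,ymin Coordinates of the grid's lower-left corner.
#' @param cell_size Side length of a cell in map units.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(rows, cols, xmin = 0, ymin = 0, cell_size = 1) {
  stopifnot(rows >= 1, cols >= 1, cell_size > 0)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         xmin = xmin, ymin = ymin, cell_size = cell_size),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %d x %d cells, cell size %g, origin (%g, %g)\n",
              x$rows, x$cols, x$cell_size, x$xmin, x$ymin))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

#' Cell centers for (row, col) indices
#' @param grid An `env_grid`.
#' @param row,col Integer vectors of equal length.
#' @return A tibble with columns `x`, `y`.
#' @export
cell_center <- function(grid, row, col) {
  tibble::tibble(
    x = grid$xmin + (col - 0.5) * grid$cell_size,
    y = grid$ymin + (grid$rows - row + 0.5) * grid$cell_size
  )
}

#' Map planar coordinates to (row, col); NA outside the grid
#' @param grid An `env_grid`.
#' @param x,y Coordinate vectors.
#' @return A tibble with integer columns `row`, `col` (NA if off-grid).
#' @export
coord_cell <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$cell_size) + 1L
  row <- grid$rows - floor((y - grid$ymin) / grid$cell_size)
  bad <- col < 1L | col > grid$cols | row < 1L | row > grid$rows |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

# Gaussian smoothing by separable band-matrix convolution with edge
# renormalization; sigma in cell units, sigma = 0 is the identity.
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  kernel_1d <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) i - j)
    k <- exp(-d^2 / (2 * sigma^2))
    k[abs(d) > ceiling(3 * sigma)] <- 0
    k / rowSums(k)
  }
  kr <- kernel_1d(nrow(m))
  kc <- kernel_1d(ncol(m))
  kr %*% m %*% t(kc)
}

# 8- (or 4-) connected component labeling of a logical matrix.
# Returns an integer matrix: 0 off-mask, 1..n_patches on-mask.
label_patches <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  }
  mask[is.na(mask)] <- FALSE
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- integer(length(idx)); queue[1L] <- start; qh <- 1L; qt <- 1L
    lab[start] <- nxt
    while (qh <= qt) {
      cur <- queue[qh]; qh <- qh + 1L
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- cc + dc[k]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        j <- (c2 - 1L) * nr + r2
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          qt <- qt + 1L; queue[qt] <- j
        }
      }
    }
  }
  lab
}

# sample() that never falls into the length-1 "sample from 1:x" trap.
safe_sample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Deterministic per-stage/per-species child seed below 2^31.
child_seed <- function(master, ...) {
  tag <- paste(..., sep = "/")
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 131 + v) %% 2147483629
  as.integer((as.numeric(master) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}
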