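#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text interchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by the value
#' matrix north-up. Round-trips through [read_ascii_grid()] preserve
#' grid, nodata and values.
#'
#' @param values Numeric matrix (NA = nodata).
#' @param grid The [env_grid()].
#' @param path Output file path.
#' @param nodata_value Sentinel written for NA cells.
#' @export
write_ascii_grid <- function(values, grid, path, nodata_value = -9999) {
  stopifnot(all(dim(values) == c(grid$rows, grid$cols)))
  header <- c(
    paste("ncols", grid$cols), paste("nrows", grid$rows),
    paste("xllcorner", format(grid$xmin, digits = 15)),
    paste("yllcorner", format(grid$ymin, digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", nodata_value)
  )
  v <- values
  v[is.na(v)] <- nodata_value
  lines <- apply(v, 1, function(r) paste(format(r, digits = 15,
                                                trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(header, lines), path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any conforming
#'   ASCII grid).
#' @return A list: `values` (matrix, NA at nodata) and `grid`
#'   ([env_grid()]).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, character(1), 2),
                        tolower(vapply(hdr, `[`, character(1), 1)))
  grid <- env_grid(as.integer(kv[["nrows"]]), as.integer(kv[["ncols"]]),
                   xmin = as.numeric(kv[["xllcorner"]]),
                   ymin = as.numeric(kv[["yllcorner"]]),
                   cell_size = as.numeric(kv[["cellsize"]]))
  nodata <- as.numeric(kv[["nodata_value"]])
  body <- lines[-(1:6)]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l),
                                                       "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m[m == nodata] <- NA_real_
  list(values = m, grid = grid)
}

#' Write an environmental stack to a directory
#'
#' One ASCII grid per layer plus a JSON manifest recording layer names,
#' roles, and grid geometry.
#'
#' @param env An [env_stack()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_env_stack <- function(env, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in layer_names(env))
    write_ascii_grid(env$layers[[nm]], env$grid,
                     file.path(dir, paste0(nm, ".asc")))
  manifest <- list(
    layers = as.list(stats::setNames(paste0(layer_names(env), ".asc"),
                                     layer_names(env))),
    roles = as.list(env$roles),
    grid = unclass(env$grid)
  )
  mp <- file.path(dir, "stack.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read an environmental stack written by [write_env_stack()]
#'
#' @param dir Directory containing `stack.json` and the layer files.
#' @return An [env_stack()].
#' @export
read_env_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "stack.json"),
                                  simplifyVector = TRUE)
  layers <- lapply(manifest$layers, function(f)
    read_ascii_grid(file.path(dir, f))$values)
  g <- manifest$grid
  grid <- env_grid(g$rows, g$cols, g$xmin, g$ymin, g$cell_size)
  env_stack(layers, grid, roles = unlist(manifest$roles))
}

#' Read an occurrence CSV
#'
#' Expects columns `species`, `x`, `y`; extra columns (`source`, `year`,
#' ...) are preserved.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("species", "x", "y"), names(df))
  if (length(need))
    stop("occurrence file lacks column(s): ", paste(need, collapse = ", "))
  tibble::as_tibble(df)
}

#' Write occurrences to CSV
#' @param occ Occurrence tibble.
#' @param path Output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
}
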