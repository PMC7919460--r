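# Shared fixture builders; everything is generated in code at test time.

small_world <- function(rows = 40, cols = 40, n_layers = 4, seed = 1, ...) {
  generate_env_stack(synthetic_world_config(rows, cols,
                                            n_layers = n_layers,
                                            seed = seed, ...))
}

# A stack built from explicit matrices (no randomness), sea-free.
manual_stack <- function(..., cell_size = 1, roles = "other") {
  layers <- list(...)
  g <- env_grid(nrow(layers[[1]]), ncol(layers[[1]]),
                cell_size = cell_size)
  env_stack(layers, g, roles = roles)
}

manual_binary <- function(m, species = "sp", scenario = "current") {
  stacksdm:::binary_map(m, env_grid(nrow(m), ncol(m)), species = species,
                        scenario = scenario)
}

# Gaussian-niche virtual species driven by one named layer.
driven_species <- function(env, layer, q_opt = 0.6, sd_frac = 0.16,
                           prevalence = 0.5, name = "vsp",
                           dispersal_radius = NULL) {
  v <- land_matrix(env)[, layer]
  if (is.null(dispersal_radius))
    dispersal_radius <- 0.6 * max(env$grid$rows, env$grid$cols) *
      env$grid$cell_size
  virtual_species(
    name,
    stats::setNames(list(list(type = "gaussian",
                              opt = unname(stats::quantile(v, q_opt)),
                              sd = sd_frac * (max(v) - min(v)),
                              height = 6)), layer),
    prevalence = prevalence, dispersal_radius = dispersal_radius)
}

# Uniform presences over land, ignoring every covariate (a pure-noise
# "species" for null calibration).
noise_presences <- function(env, n, seed) {
  cells <- which(!env$nodata)
  withr::with_seed(seed, {
    picked <- sample(cells, n, replace = TRUE)
    nr <- env$grid$rows
    ctr <- cell_center(env$grid, ((picked - 1L) %% nr) + 1L,
                       ((picked - 1L) %/% nr) + 1L)
    tibble::tibble(species = "noise", x = ctr$x, y = ctr$y)
  })
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
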