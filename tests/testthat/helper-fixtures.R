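# Shared fixtures: one small landscape and the packaged tables, built once
# per test run.

small_landscape <- local({
  cache <- NULL
  function(seed = 7) {
    if (is.null(cache) || cache$config$seed != seed)
      cache <<- generate_landscape(
        landscape_config(grid_rows = 40, grid_cols = 40, seed = seed))
    cache
  }
})

fx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- scenario_fixtures()
    cache
  }
})

# a toy 3x3 layer with known values
toy_layer <- function(values = matrix(1:9, 3, 3), ...) {
  grid_layer(values, cellsize = 1000, ...)
}

mask_layer <- function(m) grid_layer(m * 1, cellsize = 1000)
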