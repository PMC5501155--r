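# Shared in-code fixtures. Everything is generated at test time; grids are
# kept small so the whole suite stays quick.

# constant-valued layer on an n x n grid
const_layer <- function(value, n = 4, cell = 250, name = "const") {
  layer(name, matrix(value, n, n), grid_spec(n, n, cell))
}

# a small stack whose layers are analytic functions of the cell center
analytic_stack <- function(n = 10, cell = 100) {
  spec <- grid_spec(n, n, cell)
  ctr <- expand.grid(row = seq_len(n), col = seq_len(n))
  x <- spec$origin_x + (ctr$col - 0.5) * cell
  y <- spec$origin_y - (ctr$row - 0.5) * cell
  mk <- function(v, nm) layer(nm, matrix(v, n, n), spec)
  raster_stack(list(
    mk(x, "xcoord"), mk(y, "ycoord"), mk(ctr$col, "colidx")))
}

# a tiny synthetic landscape for fast model-level tests
small_landscape <- function(seed = 101, n = 60, n_presences = 80,
                            sigma = 0.3, n_noise = 1, n_duplicates = 0) {
  build_landscape(landscape_config(
    n_cols = n, n_rows = n, cell_size = 250, length_scale = 1500,
    responses = list(
      list(name = "env_a", form = "gaussian", mu = 0.5, sigma = sigma),
      list(name = "env_b", form = "gaussian", mu = -0.25, sigma = sigma)),
    n_duplicates = n_duplicates, n_noise = n_noise,
    n_presences = n_presences, seed = seed))
}

# rectangular zone whose boundary follows cell edges exactly
rect_zone <- function(name, role, x0, y0, x1, y1) {
  list(name = name, role = role,
       rings = list(matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0),
                           ncol = 2, byrow = TRUE)))
}
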