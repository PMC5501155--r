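## Grid data model: a GridSpec describes a regular projected raster grid
## (row 1 at the top), a layer is a named matrix on that grid with an NA
## nodata mask, and a raster stack is an ordered set of layers sharing one
## spec. All coordinates are planar meters in a projected CRS.

#' Define a raster grid
#'
#' @param n_cols,n_rows grid dimensions (cells).
#' @param cell_size cell edge length in meters.
#' @param origin_x,origin_y coordinates of the top-left corner of the grid
#'   (meters). Rows increase downwards (row 1 is the northernmost row).
#' @param nodata_flag sentinel value used for nodata when writing files;
#'   in-memory layers use `NA`.
#' @param crs_label free-text CRS tag (e.g. `"UTM48N"`); informational only,
#'   all distances are planar Euclidean.
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(n_cols, n_rows, cell_size, origin_x = 0, origin_y = NULL,
                      nodata_flag = -9999, crs_label = "") {
  if (n_cols < 1 || n_rows < 1) stopf("grid must have at least one row and column")
  if (cell_size <= 0) stopf("cell_size must be positive")
  if (is.null(origin_y)) origin_y <- n_rows * cell_size
  structure(
    list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         cell_size = cell_size, origin_x = origin_x, origin_y = origin_y,
         nodata_flag = nodata_flag, crs_label = crs_label),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cols x %d rows @ %g m, origin (%g, %g)\n",
              x$n_cols, x$n_rows, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell area in square kilometers
#' @param spec a [grid_spec()].
#' @return scalar km^2 per cell.
#' @export
cell_area_km2 <- function(spec) (spec$cell_size / 1000)^2

spec_equal <- function(a, b, rtol = 1e-6) {
  num_eq <- function(u, v) abs(u - v) <= rtol * pmax(1, abs(u), abs(v))
  a$n_cols == b$n_cols && a$n_rows == b$n_rows &&
    num_eq(a$cell_size, b$cell_size) &&
    num_eq(a$origin_x, b$origin_x) && num_eq(a$origin_y, b$origin_y)
}

#' Construct a raster layer
#'
#' @param name layer name (unique within a stack).
#' @param values numeric matrix `n_rows x n_cols`; `NA` marks nodata.
#' @param kind `"continuous"` or `"categorical"`. Categorical layers hold
#'   integer class codes and enter models only through indicator features.
#' @param spec the [grid_spec()] the matrix lives on.
#' @return a `hab_layer` object.
#' @export
layer <- function(name, values, spec, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stopf("layer '%s': matrix is %dx%d but spec is %dx%d",
          name, nrow(values), ncol(values), spec$n_rows, spec$n_cols)
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (any(v != round(v))) stopf("layer '%s': categorical codes must be integers", name)
  } else if (any(!is.finite(values[!is.na(values)]))) {
    stopf("layer '%s': continuous values must be finite where unmasked", name)
  }
  structure(list(name = name, kind = kind, values = values, spec = spec),
            class = "hab_layer")
}

#' Bundle aligned layers into a raster stack
#'
#' All layers must share one grid. Cells masked (`NA`) in any layer are
#' treated as masked stack-wide for modeling.
#'
#' @param layers list of [layer()] objects with unique names.
#' @return a `raster_stack` with elements `spec` and `layers` (named list).
#' @export
raster_stack <- function(layers) {
  if (length(layers) == 0) stopf("empty stack")
  spec <- layers[[1]]$spec
  nms <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("duplicate layer names: %s",
                                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  for (l in layers) {
    if (!spec_equal(spec, l$spec))
      stopf("layer '%s' is not aligned with the first layer's grid", l$name)
  }
  names(layers) <- nms
  structure(list(spec = spec, layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d layers on %dx%d grid @ %g m\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols, x$spec$cell_size))
  cat("  ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Stack-wide unmasked mask
#'
#' @param stack a [raster_stack()].
#' @return logical matrix, `TRUE` where every layer has data.
#' @export
stack_mask <- function(stack) {
  m <- !is.na(stack$layers[[1]]$values)
  for (l in stack$layers[-1]) m <- m & !is.na(l$values)
  m
}

## ---- cell geometry ---------------------------------------------------------

## Half-open cell ownership: a point on a shared vertical edge belongs to the
## cell on its right, on a shared horizontal edge to the cell below
## (col = floor(dx)+1, row = floor(dy)+1 in cell units from the top-left).
point_to_cell <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1
  row <- floor((spec$origin_y - y) / spec$cell_size) + 1
  inside <- col >= 1 & col <= spec$n_cols & row >= 1 & row <= spec$n_rows
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

cell_centers <- function(spec, rows, cols) {
  data.frame(x = spec$origin_x + (cols - 0.5) * spec$cell_size,
             y = spec$origin_y - (rows - 0.5) * spec$cell_size)
}

## all cell centers in matrix (column-major) order
all_cell_centers <- function(spec) {
  rows <- rep(seq_len(spec$n_rows), times = spec$n_cols)
  cols <- rep(seq_len(spec$n_cols), each = spec$n_rows)
  cell_centers(spec, rows, cols)
}

#' Extract layer values at occurrence points
#'
#' Each point is assigned the value of the cell containing it (points on
#' shared edges belong to the right/lower cell). Rows whose cell is masked in
#' any layer are flagged.
#'
#' @param stack a [raster_stack()].
#' @param points an [occurrence_set()] or data frame with `x`, `y` (and
#'   optionally `id`) columns.
#' @return data frame with `id`, one column per layer, and logical `masked`.
#' @export
extract_values <- function(stack, points) {
  pts <- if (inherits(points, "occurrence_set")) points$records else as.data.frame(points)
  if (is.null(pts$id)) pts$id <- seq_len(nrow(pts))
  cl <- point_to_cell(stack$spec, pts$x, pts$y)
  if (any(!cl$inside))
    stopf("points outside grid extent: %s",
          paste(pts$id[!cl$inside], collapse = ", "))
  idx <- cbind(cl$row, cl$col)
  out <- data.frame(id = pts$id)
  for (nm in names(stack$layers)) out[[nm]] <- stack$layers[[nm]]$values[idx]
  out$masked <- !stack_mask(stack)[idx]
  out
}

## ---- derived layers --------------------------------------------------------

#' Fold aspect into an adret index
#'
#' Compass aspect in degrees is folded to `|aspect - 180|`, so 0 means due
#' south (sun-facing in the northern hemisphere) and 180 due north; the index
#' measures how far a slope faces from the sun.
#'
#' @param aspect_degrees numeric in `[0, 360)`.
#' @return degrees in `[0, 180]`.
#' @export
aspect_index <- function(aspect_degrees) {
  bad <- !is.na(aspect_degrees) & (aspect_degrees < 0 | aspect_degrees >= 360)
  if (any(bad)) stopf("aspect out of [0, 360): %s",
                      paste(utils::head(aspect_degrees[bad], 5), collapse = ", "))
  abs(aspect_degrees - 180)
}

#' Euclidean distance-to-feature layer
#'
#' Per-cell planar distance (meters, cell center to cell center) to the
#' nearest target cell; target cells get 0. Targets are given either as a
#' logical matrix on the grid or as a two-column `row`,`col` matrix.
#'
#' @param targets logical matrix (`TRUE` = target) or integer matrix/data
#'   frame of target `row`, `col` indices.
#' @param spec the [grid_spec()].
#' @param name layer name.
#' @return a continuous [layer()] of distances in meters.
#' @export
distance_layer <- function(targets, spec, name = "distance") {
  if (is.logical(targets)) {
    idx <- which(targets, arr.ind = TRUE)
  } else {
    idx <- as.matrix(as.data.frame(targets)[, 1:2])
  }
  if (nrow(idx) == 0) stopf("distance_layer: no target cells")
  tc <- cell_centers(spec, idx[, 1], idx[, 2])
  ctr <- all_cell_centers(spec)
  n <- nrow(ctr)
  d2 <- rep(Inf, n)
  ## chunk over targets to bound memory on large grids
  step <- max(1L, floor(4e6 / n))
  for (s in seq(1, nrow(tc), by = step)) {
    e <- min(nrow(tc), s + step - 1)
    dx <- outer(ctr$x, tc$x[s:e], "-")
    dy <- outer(ctr$y, tc$y[s:e], "-")
    dd <- dx * dx + dy * dy
    j <- max.col(-dd, ties.method = "first")     # fast row-wise minimum
    d2 <- pmin(d2, dd[cbind(seq_len(n), j)])
  }
  m <- matrix(sqrt(d2), nrow = spec$n_rows, ncol = spec$n_cols)
  layer(name, m, spec, kind = "continuous")
}

## ---- ESRI ASCII grid I/O ---------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' @param path file path (`.asc`).
#' @param name layer name; defaults to the file stem.
#' @param kind `"continuous"` or `"categorical"`.
#' @return a [layer()].
#' @export
read_ascii_grid <- function(path, name = NULL,
                            kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("cannot read raster file '%s'", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                    "yllcenter", "cellsize", "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stopf("'%s' is not an ESRI ASCII grid (missing %s)", path,
          paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- hdr[["nodata_value"]] %||% -9999
  xll <- if (!is.null(hdr[["xllcorner"]])) hdr[["xllcorner"]]
         else if (!is.null(hdr[["xllcenter"]])) hdr[["xllcenter"]] - hdr$cellsize / 2
         else 0
  yll <- if (!is.null(hdr[["yllcorner"]])) hdr[["yllcorner"]]
         else if (!is.null(hdr[["yllcenter"]])) hdr[["yllcenter"]] - hdr$cellsize / 2
         else 0
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stopf("'%s': expected %d values, found %d", path,
          hdr$ncols * hdr$nrows, length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  spec <- grid_spec(hdr$ncols, hdr$nrows, hdr$cellsize,
                    origin_x = xll, origin_y = yll + hdr$nrows * hdr$cellsize,
                    nodata_flag = nodata)
  layer(name %||% sub("\\.[^.]*$", "", basename(path)), m, spec, kind)
}

#' Write a layer as an ESRI ASCII grid
#'
#' @param lyr a [layer()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(lyr, path) {
  spec <- lyr$spec
  m <- lyr$values
  m[is.na(m)] <- spec$nodata_flag
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x),
    sprintf("yllcorner %.10g", spec$origin_y - spec$n_rows * spec$cell_size),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %g", spec$nodata_flag)), con)
  utils::write.table(format(m, trim = TRUE, digits = 15, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load aligned raster files into a stack
#'
#' Grids whose header differs from the first file's by more than a relative
#' 1e-6 are rejected, naming the offending layer.
#'
#' @param paths character vector of ESRI ASCII grid files.
#' @param names layer names; default file stems.
#' @param kinds per-layer `"continuous"`/`"categorical"` (recycled).
#' @return a [raster_stack()].
#' @export
load_stack <- function(paths, names = NULL, kinds = "continuous") {
  stopifnot(length(paths) >= 1)
  kinds <- rep_len(kinds, length(paths))
  layers <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    layers[[i]] <- read_ascii_grid(paths[i], name = names[i], kind = kinds[i])
    if (i > 1 && !spec_equal(layers[[1]]$spec, layers[[i]]$spec))
      stopf("layer '%s' (%s) is not aligned with '%s'",
            layers[[i]]$name, paths[i], layers[[1]]$name)
  }
  raster_stack(layers)
}

#' Write every layer of a stack as ASCII grids
#'
#' @param stack a [raster_stack()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    write_ascii_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  }, "")
  invisible(paths)
}
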