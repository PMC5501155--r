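## Habitat mapping and accounting: replicate-averaged suitability, max-TSS
## binarization, suitable-area estimates, zonal (county / nature-reserve)
## summaries with a cell-center rule, protected-area gap fractions, and
## patch fragmentation statistics.

#' Average replicate suitability grids
#'
#' Cell-wise arithmetic mean; a cell masked in any input grid is masked in
#' the mean.
#'
#' @param grids list of suitability [layer()]s (or matrices plus `spec`).
#' @param spec required when `grids` are bare matrices.
#' @return a [layer()] named `"suitability"`.
#' @export
average_replicates <- function(grids, spec = NULL) {
  if (length(grids) == 0) stopf("average_replicates: no grids")
  mats <- lapply(grids, function(g) {
    if (inherits(g, "hab_layer")) {
      if (is.null(spec)) spec <<- g$spec
      if (!spec_equal(spec, g$spec)) stopf("replicate grids have mismatched specs")
      g$values
    } else as.matrix(g)
  })
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1) stopf("replicate grids have mismatched shapes")
  acc <- Reduce(`+`, mats)
  layer("suitability", acc / length(mats), spec %||% grid_spec(ncol(mats[[1]]),
        nrow(mats[[1]]), 1))
}

#' Threshold a suitability map into binary habitat
#'
#' A cell is suitable when its suitability is at or above the threshold.
#'
#' @param map a suitability [layer()].
#' @param threshold value in `[0, 1]`.
#' @return a `binary_habitat_map`: `spec`, logical `suitable` matrix (`NA`
#'   where masked), `threshold`.
#' @export
apply_threshold <- function(map, threshold) {
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  structure(list(spec = map$spec, suitable = map$values >= threshold,
                 threshold = threshold),
            class = "binary_habitat_map")
}

#' Total suitable habitat area
#' @param map a [apply_threshold()] result.
#' @return area in km^2.
#' @export
habitat_area <- function(map) {
  sum(map$suitable, na.rm = TRUE) * cell_area_km2(map$spec)
}

#' Percentage of a zone that is suitable
#'
#' The worked-example arithmetic behind zonal gap tables: `100 *
#' suitable_km2 / zone_km2`, reported at two decimals, half up.
#'
#' @param suitable_km2 suitable area within the zone.
#' @param zone_km2 total zone area.
#' @return percentage, 2 decimal places.
#' @export
zone_proportion <- function(suitable_km2, zone_km2) {
  round_half_up(100 * suitable_km2 / zone_km2, 2)
}

#' Per-zone suitable-habitat accounting
#'
#' Cells are assigned to a zone when their center falls inside it;
#' overlapping zones each count the shared cells. Zone area counts all cells
#' (masked or not) whose center is inside, so it measures the zone's
#' geographic footprint on the grid.
#'
#' @param map a [apply_threshold()] result.
#' @param zones a [zone_set()].
#' @param roles optional filter of zone roles (e.g. `"reserve"`).
#' @return data frame `zone, role, zone_area_km2, suitable_km2,
#'   proportion_pct`.
#' @export
zonal_summary <- function(map, zones, roles = NULL) {
  area <- cell_area_km2(map$spec)
  zl <- zones$zones
  if (!is.null(roles)) zl <- Filter(function(z) z$role %in% roles, zl)
  rows <- lapply(zl, function(z) {
    zm <- zone_mask(z, map$spec)
    if (!any(zm)) warnf("zone '%s' lies outside the grid extent", z$name)
    suit <- sum(map$suitable & zm, na.rm = TRUE) * area
    zarea <- sum(zm) * area
    data.frame(zone = z$name, role = z$role, zone_area_km2 = zarea,
               suitable_km2 = suit,
               proportion_pct = if (zarea > 0) zone_proportion(suit, zarea) else 0)
  })
  do.call(rbind, rows)
}

#' Fraction of suitable habitat inside protected areas
#'
#' Computes the cell-wise union of all zones with the given role (so
#' overlapping reserves are not double-counted) and reports the percentage
#' of total suitable area falling inside the union, at two decimals.
#'
#' @param map a [apply_threshold()] result.
#' @param zones a [zone_set()].
#' @param role zone role defining the protected network.
#' @return percentage of suitable habitat under protection.
#' @export
protected_fraction <- function(map, zones, role = "reserve") {
  total <- habitat_area(map)
  if (total <= 0) stopf("protected_fraction: no suitable habitat")
  zl <- Filter(function(z) z$role == role, zones$zones)
  if (length(zl) == 0) stopf("no zones with role '%s'", role)
  um <- matrix(FALSE, map$spec$n_rows, map$spec$n_cols)
  for (z in zl) um <- um | zone_mask(z, map$spec)
  inside <- sum(map$suitable & um, na.rm = TRUE) * cell_area_km2(map$spec)
  round_half_up(100 * inside / total, 2)
}

#' Patch fragmentation statistics
#'
#' Connected components of suitable cells under 4- or 8-connectivity
#' (default 8: diagonally touching ridgeline cells connect).
#'
#' @param map a [apply_threshold()] result.
#' @param connectivity 4 or 8.
#' @return a `patch_stats` list: `n_patches`, `cell_counts`, `areas_km2`,
#'   `largest_fraction`, and the label matrix `labels`.
#' @export
patch_stats <- function(map, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  suit <- map$suitable
  suit[is.na(suit)] <- FALSE
  nr <- nrow(suit); nc <- ncol(suit)
  labels <- matrix(0L, nr, nc)
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  n_patch <- 0L
  counts <- integer(0)
  todo <- integer(nr * nc)                      # reusable DFS stack
  for (start in which(suit & labels == 0L)) {
    if (labels[start] != 0L) next
    n_patch <- n_patch + 1L
    top <- 1L; todo[1L] <- start; labels[start] <- n_patch
    size <- 0L
    while (top > 0L) {
      cur <- todo[top]; top <- top - 1L
      size <- size + 1L
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- cc + dc[k]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          nb <- (c2 - 1L) * nr + r2
          if (suit[nb] && labels[nb] == 0L) {
            labels[nb] <- n_patch
            top <- top + 1L; todo[top] <- nb
          }
        }
      }
    }
    counts[n_patch] <- size
  }
  areas <- counts * cell_area_km2(map$spec)
  structure(list(n_patches = n_patch, cell_counts = counts,
                 areas_km2 = areas,
                 largest_fraction = if (n_patch > 0) max(areas) / sum(areas) else NA_real_,
                 labels = labels),
            class = "patch_stats")
}

#' Write a binary habitat map as an ASCII grid (0/1, nodata preserved)
#' @param map a [apply_threshold()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_habitat_map <- function(map, path) {
  write_ascii_grid(layer("habitat", map$suitable + 0, map$spec), path)
}
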