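## Zone polygons (counties, nature reserves, study region) read from GeoJSON,
## rasterized onto the model grid by the cell-center rule.

#' Construct a zone set
#'
#' @param zones list of zones; each zone is a list with `name`, `role`
#'   (`"county"`, `"reserve"` or `"region"`) and `rings`, a list of closed
#'   rings, each a two-column matrix of x,y vertices. Interior rings (holes)
#'   are handled by even-odd parity.
#' @return a `zone_set`.
#' @export
zone_set <- function(zones) {
  for (z in zones) {
    stopifnot(!is.null(z$name), !is.null(z$role), length(z$rings) >= 1)
    for (r in z$rings) {
      r <- as.matrix(r)
      if (nrow(r) < 4 || any(r[1, ] != r[nrow(r), ]))
        stopf("zone '%s': polygon rings must be closed", z$name)
    }
  }
  key <- paste(vapply(zones, `[[`, "", "role"), vapply(zones, `[[`, "", "name"))
  if (anyDuplicated(key)) stopf("zone names must be unique within a role")
  structure(list(zones = zones), class = "zone_set")
}

#' Read zones from a GeoJSON FeatureCollection
#'
#' Features must be Polygon or MultiPolygon with properties `name` and
#' `role`. Coordinates are taken as projected meters on the model grid's
#' CRS; no reprojection is performed.
#'
#' @param path GeoJSON file.
#' @return a [zone_set()].
#' @export
read_zones <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stopf("'%s' is not a GeoJSON FeatureCollection", path)
  zones <- lapply(gj$features, function(f) {
    geom <- f$geometry
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      stopf("unsupported geometry type '%s'", geom$type))
    list(name = f$properties$name, role = f$properties$role %||% "region",
         rings = rings)
  })
  zone_set(zones)
}

## even-odd point-in-polygon over all rings of one zone, via mgcv::in.out
## (loops separated by NA rows)
points_in_zone <- function(zone, x, y) {
  bnd <- do.call(rbind, lapply(zone$rings, function(r) rbind(as.matrix(r), c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, cbind(x, y))
}

#' Rasterize a zone to a cell mask
#'
#' A cell belongs to the zone when its center falls inside the polygon
#' (even-odd rule); a deterministic, resolution-limited convention.
#'
#' @param zone one element of a [zone_set()]'s `zones`.
#' @param spec the [grid_spec()].
#' @return logical `n_rows x n_cols` matrix.
#' @export
zone_mask <- function(zone, spec) {
  ctr <- all_cell_centers(spec)
  matrix(points_in_zone(zone, ctr$x, ctr$y),
         nrow = spec$n_rows, ncol = spec$n_cols)
}
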