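## Occurrence records: georeferenced presence points in projected meters,
## with spatial thinning by overlapping home-range buffers.

#' Construct an occurrence set
#'
#' @param records data frame with columns `id`, `x`, `y` and optionally
#'   `source`, `year`. Coordinates are projected meters.
#' @param thinned has the set been spatially thinned?
#' @param thin_radius buffer radius (m) used for thinning, if any.
#' @return an `occurrence_set`.
#' @export
occurrence_set <- function(records, thinned = FALSE, thin_radius = NULL) {
  records <- as.data.frame(records)
  if (nrow(records) > 0) {
    stopifnot(all(c("x", "y") %in% names(records)))
    if (any(!is.finite(records$x)) || any(!is.finite(records$y)))
      stopf("occurrence coordinates must be finite")
  }
  if (is.null(records$id)) records$id <- seq_len(nrow(records))
  if (is.null(records$source)) records$source <- rep(NA_character_, nrow(records))
  if (is.null(records$year)) records$year <- rep(NA_integer_, nrow(records))
  structure(list(records = records, thinned = isTRUE(thinned),
                 thin_radius = thin_radius),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records%s\n", nrow(x$records),
              if (x$thinned) sprintf(" (thinned, radius %g m)", x$thin_radius) else ""))
  invisible(x)
}

#' Read occurrences from CSV
#'
#' Expects a header `id,x,y,source,year` with coordinates in projected
#' meters.
#'
#' @param path CSV file.
#' @return an [occurrence_set()].
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(df)))
    stopf("occurrence CSV must have columns id,x,y (got: %s)",
          paste(names(df), collapse = ","))
  occurrence_set(df)
}

#' Write occurrences to CSV
#' @param occ an [occurrence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ$records[, c("id", "x", "y", "source", "year")],
                   path, row.names = FALSE)
  invisible(path)
}

## connected components of the graph "center distance < threshold";
## single-linkage, so chains collapse into one component
distance_components <- function(x, y, threshold) {
  n <- length(x)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (i in seq_len(max(0, n - 1))) {
    d2 <- (x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2
    for (j in which(d2 < threshold^2)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) comp[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Spatially thin occurrences by overlapping buffers
#'
#' Records whose circular buffers of `buffer_radius` overlap (center distance
#' below twice the radius) are grouped into connected components
#' (single-linkage, so chains collapse), and exactly one record per component
#' is kept, chosen uniformly at random under `seed`. The retained count is
#' therefore independent of the seed; only which representative survives
#' varies.
#'
#' @param occ an [occurrence_set()].
#' @param buffer_radius buffer radius in meters. The default 564.19 m is the
#'   radius of a circle of area 1 km^2, the approximate minimum home-range
#'   size motivating the thinning.
#' @param seed integer seed for the random representative choice.
#' @return a thinned [occurrence_set()].
#' @export
thin_occurrences <- function(occ, buffer_radius = 564.19, seed = 1) {
  if (buffer_radius <= 0) stopf("buffer_radius must be positive")
  rec <- occ$records
  if (nrow(rec) == 0)
    return(occurrence_set(rec, thinned = TRUE, thin_radius = buffer_radius))
  comp <- distance_components(rec$x, rec$y, 2 * buffer_radius)
  keep <- with_seed(seed, {
    vapply(split(seq_len(nrow(rec)), comp), function(ix) {
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
    }, 1L)
  })
  keep <- sort(unname(keep))
  occurrence_set(rec[keep, , drop = FALSE], thinned = TRUE,
                 thin_radius = buffer_radius)
}
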