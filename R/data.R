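#' County and nature-reserve habitat areas for the Chinese monal
#'
#' Reported zone areas and suitable-habitat areas (km^2) for the Chinese
#' monal (*Lophophorus lhuysii*) across the twelve counties and ten nature
#' reserves of the Qionglai Mountains, plus the reserve-network and
#' whole-region totals. Shipped as a worked example for the zonal
#' accounting arithmetic ([zone_proportion()], protected fractions): the
#' proportion columns of such gap tables are recomputable from these areas.
#'
#' @return data frame with columns `zone`, `role` (`county`, `reserve`,
#'   `reserve_total`, `region`), `zone_area_km2`, `suitable_km2`.
#' @export
monal_zone_areas <- function() {
  utils::read.csv(system.file("extdata", "monal_zone_areas.csv",
                              package = "maxhab"),
                  stringsAsFactors = FALSE)
}
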