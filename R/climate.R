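#' Saturated water vapour pressure (Tetens relation)
#'
#' Saturated vapour pressure of water over a liquid surface at air
#' temperature `temp`, by the Tetens relation
#' \deqn{SVP = a \exp\left(\frac{b\,T}{T + c}\right)}
#' with the meteorological constants \eqn{a = 0.61078} kPa, \eqn{b = 17.27},
#' \eqn{c = 237.3} degC. The constants are exposed so a Magnus-family
#' variant can be substituted.
#'
#' @param temp Air temperature, degC. Must exceed absolute zero.
#' @param a,b,c Tetens constants (kPa, unitless, degC).
#' @return Saturated vapour pressure, kPa. Strictly increasing in `temp`.
#' @examples
#' svp(0)    # 0.61078 exactly
#' svp(25)   # ~3.17 kPa
#' @seealso [vpd()]
#' @export
svp <- function(temp, a = 0.61078, b = 17.27, c = 237.3) {
  if (any(!is.finite(temp))) stop_field("temp", "must be finite")
  if (any(temp <= -273.15)) stop_field("temp", "must exceed -273.15 degC")
  a * exp(b * temp / (temp + c))
}

#' Vapour pressure deficit
#'
#' The drying power of the air: `svp(temp) - vp`, assuming the evaporating
#' surface (here, an insect's respiratory surfaces) is saturated with water
#' vapour at body temperature equal to air temperature. Monthly-mean inputs
#' can occasionally give `vp > svp(temp)`; such non-physical negative
#' deficits are floored at zero with a warning.
#'
#' @param temp Air temperature, degC.
#' @param vp Ambient (actual) vapour pressure, kPa; non-negative.
#' @param ... Passed on to [svp()] (alternative constants).
#' @return Vapour pressure deficit, kPa (>= 0).
#' @examples
#' vpd(25, 1.5)
#' vpd(20, svp(20))  # saturation: exactly 0
#' @export
vpd <- function(temp, vp, ...) {
  if (any(!is.finite(vp)) || any(vp < 0)) {
    stop_field("vp", "must be finite and >= 0")
  }
  d <- svp(temp, ...) - vp
  neg <- d < 0
  if (any(neg)) {
    warning(sprintf(
      "vp exceeds svp(temp) for %d input(s); VPD floored at 0", sum(neg)))
    d[neg] <- 0
  }
  d
}

.site_required_cols <- c("site_id", "altitude_m", "tmin_c", "pdry_mm",
                         "vp_kpa", "side")

#' Add saturated vapour pressure and VPD columns to a site-climate table
#'
#' Computes `svp_kpa = svp(tmin_c)` and `vpd_kpa = vpd(tmin_c, vp_kpa)` for
#' each site. Existing `svp_kpa`/`vpd_kpa` columns are recomputed, so the
#' operation is idempotent. All other columns pass through untouched.
#'
#' @param sites Data frame with columns `site_id`, `altitude_m`, `tmin_c`
#'   (mean temperature of the coldest month, degC), `pdry_mm` (precipitation
#'   of the driest month, mm), `vp_kpa` (vapour pressure of the driest
#'   month, kPa) and `side` (`"wet"` or `"dry"`).
#' @return The input data frame with `svp_kpa` and `vpd_kpa` appended.
#' @examples
#' sites <- simulate_climate_gradient(trait_sim_params(n_sites = 4))
#' annotate_sites(sites)
#' @export
annotate_sites <- function(sites) {
  if (!is.data.frame(sites)) stop_field("sites", "must be a data frame")
  missing_cols <- setdiff(.site_required_cols, names(sites))
  if (length(missing_cols)) {
    stop(sprintf("site table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  sites$svp_kpa <- svp(sites$tmin_c)
  sites$vpd_kpa <- vpd(sites$tmin_c, sites$vp_kpa)
  sites
}
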