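# Solar declination / hour-angle day-length model. Used both for the
# photoperiod term of the DM-family senescence models and for the
# night-length weights that disaggregate annual ALAN to months.

#' Astronomical day length
#'
#' Hours of daylight from the standard solar declination / hour-angle
#' formula, with the declination approximated as
#' \eqn{\delta = 23.44 \sin(2\pi (284 + doy) / 365)} degrees. The cosine of
#' the sunset hour angle is clamped to \[-1, 1\] so polar day and polar night
#' return 24 and 0 hours rather than NaN.
#'
#' @param latitude Latitude in degrees, in \[-90, 90\].
#' @param doy Day of year (vector allowed), 1..365 on the 365-day calendar.
#' @return Day length in hours, same length as `doy`.
#' @export
day_length <- function(latitude, doy) {
  if (length(latitude) != 1L || is.na(latitude) || latitude < -90 || latitude > 90)
    stop("`latitude` must be a single value in [-90, 90]")
  stopifnot(all(doy >= 1), all(doy <= 365))
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  lat <- latitude * pi / 180
  cos_h <- -tan(lat) * tan(decl)
  cos_h <- pmin(1, pmax(-1, cos_h))
  2 * acos(cos_h) * 180 / pi / 15
}

#' Astronomical night length
#'
#' `24 - day_length(latitude, doy)`; the nightly hours a pixel is exposed to
#' artificial light under cloud-free conditions.
#'
#' @inheritParams day_length
#' @return Night length in hours in \[0, 24\].
#' @examples
#' night_length(0, 100)    # ~12 h at the equator
#' night_length(70, 172)   # 0 h: polar day
#' @export
night_length <- function(latitude, doy) {
  24 - day_length(latitude, doy)
}

#' Mean nightly hours per calendar month
#'
#' Averages [night_length()] over the days of each month, giving the 12
#' night-length weights NH_month used to disaggregate annual ALAN.
#'
#' @inheritParams day_length
#' @return Numeric vector of 12 monthly mean night lengths (hours).
#' @export
night_length_monthly <- function(latitude) {
  vapply(1:12, function(m) mean(night_length(latitude, month_doys(m))),
         numeric(1))
}
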