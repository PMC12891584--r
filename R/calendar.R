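# 365-day calendar (Feb 29 dropped) used throughout the package.
# DOY is 1-based: Jan 1 = 1, Dec 31 = 365.

.MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_END <- cumsum(.MONTH_DAYS)
.MONTH_START <- c(1L, head(.MONTH_END, -1L) + 1L)

#' Calendar month of a day of year
#'
#' Maps a day-of-year on the package's fixed 365-day calendar (leap day
#' dropped) to its calendar month.
#'
#' @param doy Integer day of year in 1..365.
#' @return Integer month in 1..12.
#' @examples
#' doy_to_month(1)    # 1  (January)
#' doy_to_month(172)  # 6  (June, the boreal summer solstice)
#' @export
doy_to_month <- function(doy) {
  stopifnot(all(doy >= 1L), all(doy <= 365L))
  findInterval(doy, .MONTH_START)
}

#' Days of year belonging to a calendar month
#'
#' @param month Integer month in 1..12.
#' @return Integer vector of days of year.
#' @export
month_doys <- function(month) {
  stopifnot(length(month) == 1L, month >= 1L, month <= 12L)
  seq.int(.MONTH_START[month], .MONTH_END[month])
}

# Day of the boreal summer solstice on the 365-day calendar; onset search
# for senescence forcing starts here.
SOLSTICE_DOY <- 172L
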