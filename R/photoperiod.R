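#' Photoperiod from latitude and day of year
#'
#' Standard solar-declination day-length computation with a -0.833 deg
#' horizon (refraction plus solar radius). Declination uses the cosine
#' approximation \eqn{\delta = -23.44 \cos(2\pi (N + 10)/365)} degrees.
#' Above the polar circles the sunrise equation degenerates: the function
#' returns explicit polar-day / polar-night sentinels instead of clock hours.
#'
#' @param latitude Degrees north, in `[-90, 90]`.
#' @param day_of_year Integer day of year (1--366).
#' @return List with `sunrise`, `sunset` (local solar clock hours, `NA` under
#'   polar conditions), `day_length` (hours: 24 for polar day, 0 for polar
#'   night) and `polar` (`"none"`, `"day"`, `"night"`).
#' @export
photoperiod <- function(latitude, day_of_year) {
  alx_check(is.numeric(latitude) && abs(latitude) <= 90,
            "latitude must be in [-90, 90]")
  alx_check(is.numeric(day_of_year) && day_of_year >= 1 && day_of_year <= 366,
            "day_of_year must be in 1..366")
  deg2rad <- pi / 180
  decl <- -23.44 * cos(2 * pi * (day_of_year + 10) / 365)
  cos_h <- (sin(-0.833 * deg2rad) -
              sin(latitude * deg2rad) * sin(decl * deg2rad)) /
    (cos(latitude * deg2rad) * cos(decl * deg2rad))
  if (cos_h < -1) {
    return(list(sunrise = NA_real_, sunset = NA_real_,
                day_length = 24, polar = "day"))
  }
  if (cos_h > 1) {
    return(list(sunrise = NA_real_, sunset = NA_real_,
                day_length = 0, polar = "night"))
  }
  h <- acos(cos_h) / deg2rad / 15  # half day length in hours
  list(sunrise = 12 - h, sunset = 12 + h, day_length = 2 * h, polar = "none")
}
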