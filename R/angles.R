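#' Angle utilities
#'
#' All headings and bearings in this package are expressed in degrees,
#' measured *clockwise* from the arena reference direction (+y, "up the
#' page"), so that a heading of 0 means facing up-page and 90 means facing
#' right. This matches the EWMN horizontal ring in which the right side of
#' the body carries code 2.
#'
#' @name angles
#' @keywords internal
NULL

# wrap to [0, 360)
wrap360 <- function(a) a %% 360

# wrap to (-180, 180]
wrap180 <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

# clockwise-from-+y bearing of a vector (dx, dy), degrees in [0, 360)
bearing_cw <- function(dx, dy) wrap360(atan2(dx, dy) * 180 / pi)

# unit vector pointing along a clockwise-from-+y bearing
unit_cw <- function(angle) {
  r <- angle * pi / 180
  cbind(sin(r), cos(r))
}

#' Discretize an angle into EWMN sectors
#'
#' Maps an angle (degrees, clockwise from the 0 direction) onto the EWMN
#' ring of `n_sectors` equal sectors, numbered clockwise starting at 0.
#' Sector bins are half-open and centred on the sector directions: with 8
#' sectors of 45 degrees, sector `k` covers `[45k - 22.5, 45k + 22.5)`, so
#' 0 maps to sector 0, 90 to sector 2 (the right side), 180 to sector 4,
#' and the lower bin edge is inclusive (337.5 maps to 0).
#'
#' @param angle numeric vector of angles in degrees (any range; wrapped).
#' @param n_sectors number of sectors, 8 (45-degree units) or 16
#'   (22.5-degree units).
#' @return integer vector of sector codes in `0:(n_sectors - 1)`; `NA`
#'   where `angle` is `NA`.
#' @examples
#' sectorize(180)      # 4: anti-parallel
#' sectorize(90)       # 2: the right side
#' sectorize(337.5)    # 0: lower bin edge is inclusive
#' @export
sectorize <- function(angle, n_sectors = 8) {
  stopifnot(n_sectors %in% c(8L, 16L))
  w <- 360 / n_sectors
  as.integer(floor(wrap360(angle) / w + 0.5) %% n_sectors)
}
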