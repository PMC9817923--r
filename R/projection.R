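# Ellipsoidal transverse-Mercator projection (WGS84), after the
# Karney/Krueger series formulation: accurate to well below a millimetre
# within a UTM zone, and exactly invertible to numerical precision. All
# pipeline distances and areas are Euclidean in this projected CRS.

.WGS84 <- list(a = 6378137.0, f = 1 / 298.257223563)

# Series coefficients for the given third flattening n (order n^4 is ample).
.tm_consts <- function() {
  f <- .WGS84$f
  n <- f / (2 - f)
  A <- .WGS84$a / (1 + n) * (1 + n^2 / 4 + n^4 / 64)
  alpha <- c(
    n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180,
    13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440,
    61 * n^3 / 240 - 103 * n^4 / 140,
    49561 * n^4 / 161280
  )
  beta <- c(
    n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360,
    n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440,
    17 * n^3 / 480 - 37 * n^4 / 840,
    4397 * n^4 / 161280
  )
  e <- sqrt(f * (2 - f))
  list(A = A, alpha = alpha, beta = beta, e = e)
}

#' Parse a projected CRS identifier
#'
#' Supported identifiers: UTM EPSG codes (`"EPSG:32601"`–`"EPSG:32660"` north,
#' `"EPSG:32701"`–`"EPSG:32760"` south) and the shorthand `"utm:32N"` /
#' `"utm:32S"`. Geographic CRS identifiers (e.g. `"EPSG:4326"`) are rejected:
#' all distance and area computations require metre units.
#'
#' @param crs CRS identifier string.
#' @return A list with fields `id`, `lon0` (central meridian, degrees), `k0`,
#'   `fe` (false easting, m), `fn` (false northing, m).
#' @export
parse_crs <- function(crs) {
  if (is.list(crs) && !is.null(crs$lon0)) return(crs)
  if (!is.character(crs) || length(crs) != 1) {
    stop("crs must be a single identifier string", call. = FALSE)
  }
  id <- toupper(gsub("\\s", "", crs))
  if (id %in% c("EPSG:4326", "EPSG:4258", "WGS84")) {
    stop("geographic (degree-unit) CRS '", crs,
         "' cannot be used; supply a projected metric CRS (e.g. a UTM zone)",
         call. = FALSE)
  }
  zone <- NA_integer_
  south <- FALSE
  if (grepl("^EPSG:32[67][0-9]{2}$", id)) {
    code <- as.integer(sub("EPSG:", "", id))
    if (code >= 32601 && code <= 32660) {
      zone <- code - 32600
    } else if (code >= 32701 && code <= 32760) {
      zone <- code - 32700
      south <- TRUE
    }
  } else if (grepl("^UTM:[0-9]{1,2}[NS]$", id)) {
    zone <- as.integer(sub("^UTM:([0-9]+)[NS]$", "\\1", id))
    south <- grepl("S$", id)
  }
  if (is.na(zone) || zone < 1 || zone > 60) {
    stop("unrecognised or unsupported CRS identifier: ", crs, call. = FALSE)
  }
  list(id = id, lon0 = -183 + 6 * zone, k0 = 0.9996,
       fe = 5e5, fn = if (south) 1e7 else 0)
}

#' UTM CRS identifier covering a longitude/latitude
#'
#' @param lon,lat Coordinates in degrees.
#' @return An `"EPSG:326xx"` / `"EPSG:327xx"` identifier string.
#' @export
utm_crs_for <- function(lon, lat) {
  zone <- pmin(60, pmax(1, floor((lon + 180) / 6) + 1))
  sprintf("EPSG:%d", ifelse(lat >= 0, 32600, 32700) + zone)
}

#' Project geographic to planar coordinates
#'
#' Forward transverse-Mercator projection on the WGS84 ellipsoid.
#'
#' @param lon,lat Numeric vectors, degrees.
#' @param crs Projected CRS identifier (see [parse_crs()]).
#' @return A two-column matrix of easting/northing in metres.
#' @export
lonlat_to_xy <- function(lon, lat, crs) {
  p <- parse_crs(crs)
  k <- .tm_consts()
  phi <- lat * pi / 180
  lam <- (lon - p$lon0) * pi / 180
  s <- sin(phi)
  t <- sinh(atanh(s) - k$e * atanh(k$e * s))
  xip <- atan2(t, cos(lam))
  etap <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))
  xi <- xip
  eta <- etap
  for (j in 1:4) {
    xi <- xi + k$alpha[j] * sin(2 * j * xip) * cosh(2 * j * etap)
    eta <- eta + k$alpha[j] * cos(2 * j * xip) * sinh(2 * j * etap)
  }
  cbind(x = p$fe + p$k0 * k$A * eta, y = p$fn + p$k0 * k$A * xi)
}

#' Inverse projection: planar to geographic coordinates
#'
#' @param x,y Numeric vectors, metres in `crs`.
#' @param crs Projected CRS identifier.
#' @return A two-column matrix of longitude/latitude in degrees.
#' @export
xy_to_lonlat <- function(x, y, crs) {
  p <- parse_crs(crs)
  k <- .tm_consts()
  xi <- (y - p$fn) / (p$k0 * k$A)
  eta <- (x - p$fe) / (p$k0 * k$A)
  xip <- xi
  etap <- eta
  for (j in 1:4) {
    xip <- xip - k$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    etap <- etap - k$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  taup <- sin(xip) / sqrt(sinh(etap)^2 + cos(xip)^2)
  # Newton inversion of the conformal-latitude relation tau' = tau(phi).
  e <- k$e
  tau <- taup
  for (it in 1:5) {
    sig <- sinh(e * atanh(e * tau / sqrt(1 + tau^2)))
    f <- tau * sqrt(1 + sig^2) - sig * sqrt(1 + tau^2) - taup
    df <- (sqrt(1 + sig^2) * sqrt(1 + tau^2) - sig * tau) * (1 - e^2) *
      sqrt(1 + tau^2) / (1 + (1 - e^2) * tau^2)
    tau <- tau - f / df
  }
  phi <- atan(tau)
  lam <- atan2(sinh(etap), cos(xip))
  cbind(lon = p$lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}
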