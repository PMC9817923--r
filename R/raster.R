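# Lightweight single-band raster grid. Values are stored as a matrix whose
# row 1 is the NORTHERN row (row-major from the north-west corner);
# coordinates are cell-centre registered. I/O uses the ESRI ASCII grid
# format, a plain-text raster interchange format readable by any GIS.

#' Construct a raster grid
#'
#' @param values Numeric matrix; row 1 is the northern row.
#' @param xmin,ymin Coordinates (m) of the outer corner of the south-west cell.
#' @param res Cell size in metres (square cells).
#' @param crs Projected CRS identifier.
#' @return An object of class `wm_raster`.
#' @export
wm_raster <- function(values, xmin, ymin, res, crs) {
  stopifnot(is.matrix(values), res > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 res = res, crs = crs),
            class = "wm_raster")
}

#' @export
print.wm_raster <- function(x, ...) {
  cat(sprintf("<wm_raster> %d x %d cells @ %g m, origin (%g, %g), crs %s\n",
              nrow(x$values), ncol(x$values), x$res, x$xmin, x$ymin,
              if (is.character(x$crs)) x$crs else x$crs$id))
  invisible(x)
}

#' @export
dim.wm_raster <- function(x) dim(x$values)

raster_extent <- function(r) {
  c(xmin = r$xmin, xmax = r$xmin + ncol(r$values) * r$res,
    ymin = r$ymin, ymax = r$ymin + nrow(r$values) * r$res)
}

# x/y coordinates of all cell centres (vectors over cols / rows).
raster_xcoords <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$res
raster_ycoords <- function(r) {
  ymax <- r$ymin + nrow(r$values) * r$res
  ymax - (seq_len(nrow(r$values)) - 0.5) * r$res
}

# Row/col indices of point(s); NA outside the grid.
raster_rowcol <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$res) + 1
  nr <- nrow(r$values)
  row <- nr - floor((y - r$ymin) / r$res)
  bad <- col < 1 | col > ncol(r$values) | row < 1 | row > nr
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @param r A [wm_raster()].
#' @param x,y Coordinates in the raster CRS (m).
#' @return Numeric vector; `NA` for points outside the grid.
#' @export
raster_extract <- function(r, x, y) {
  rc <- raster_rowcol(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- r$values[rc[ok, , drop = FALSE]]
  out
}

#' Mean raster value in a circular buffer
#'
#' Cells whose centre lies within `radius` of the point are averaged. Buffers
#' extending beyond the raster use the available cells only.
#'
#' @param r A [wm_raster()].
#' @param x,y Buffer centre (single point, m).
#' @param radius Buffer radius (m).
#' @return Mean value, or `NA` if no cell centre falls inside the buffer.
#' @export
raster_buffer_mean <- function(r, x, y, radius) {
  w <- .buffer_window(r, x, y, radius)
  if (is.null(w)) return(NA_real_)
  mean(r$values[w$rows, w$cols, drop = FALSE][w$inside], na.rm = TRUE)
}

# Rows/cols of the bounding window of a circular buffer plus the logical mask
# of in-circle cells within that window. NULL when fully off-grid.
.buffer_window <- function(r, x, y, radius) {
  xs <- raster_xcoords(r)
  ys <- raster_ycoords(r)
  cols <- which(abs(xs - x) <= radius)
  rows <- which(abs(ys - y) <= radius)
  if (!length(cols) || !length(rows)) return(NULL)
  dx <- xs[cols] - x
  dy <- ys[rows] - y
  inside <- outer(dy^2, dx^2, `+`) <= radius^2
  if (!any(inside)) return(NULL)
  list(rows = rows, cols = cols, inside = inside)
}

# 8-connected component labelling of a logical matrix; iterative flood
# fill, no recursion. Returns an integer label matrix (0 = background).
label_components_8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(lab)
  nextlab <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    lab[start] <- nextlab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      rr <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- rr + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        j <- (c2 - 1L) * nr + r2
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nextlab
          stack <- c(stack, j)
        }
      }
    }
  }
  lab
}

count_patches_8 <- function(mask) max(label_components_8(mask))

#' Patch density inside a circular buffer
#'
#' Counts 8-connected patches of land-cover classes whose cell centres fall
#' inside the buffer and divides by the buffer area, giving patches per km2
#' (the patch-density landscape metric computed on the full class mosaic).
#'
#' @param r Categorical [wm_raster()] of integer class codes.
#' @param x,y Buffer centre (m).
#' @param radius Buffer radius (m).
#' @param classes Class codes to count patches of; default all codes present.
#' @return Patches per km2 (0 when the buffer contains no counted class).
#' @export
raster_patch_density <- function(r, x, y, radius, classes = NULL) {
  w <- .buffer_window(r, x, y, radius)
  if (is.null(w)) return(NA_real_)
  sub <- r$values[w$rows, w$cols, drop = FALSE]
  sub[!w$inside] <- NA
  if (is.null(classes)) classes <- sort(unique(sub[!is.na(sub)]))
  npatch <- 0L
  for (cl in classes) {
    npatch <- npatch + count_patches_8(!is.na(sub) & sub == cl)
  }
  area_km2 <- pi * radius^2 / 1e6
  npatch / area_km2
}

# Coordinates (x, y) of centres of all cells equal to a class code.
class_cell_coords <- function(r, class) {
  idx <- which(r$values == class)
  if (!length(idx)) return(cbind(x = numeric(0), y = numeric(0)))
  nr <- nrow(r$values)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  cbind(x = raster_xcoords(r)[cols], y = raster_ycoords(r)[rows])
}

#' Distance from points to the nearest cell of a raster class
#'
#' Euclidean distance (m) from each query point to the nearest cell centre of
#' the given land-cover class; 0 when the point lies in such a cell.
#'
#' @param r Categorical [wm_raster()].
#' @param x,y Query coordinates (vectors, m).
#' @param class Class code.
#' @return Numeric vector of distances; `Inf` when the class is absent.
#' @export
raster_class_distance <- function(r, x, y, class) {
  cc <- class_cell_coords(r, class)
  if (!nrow(cc)) return(rep(Inf, length(x)))
  at <- raster_extract(r, x, y)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (!is.na(at[i]) && at[i] == class) {
      out[i] <- 0
    } else {
      out[i] <- sqrt(min((cc[, 1] - x[i])^2 + (cc[, 2] - y[i])^2))
    }
  }
  out
}

#' Distance from points to polylines
#'
#' @param x,y Query coordinates (vectors, m).
#' @param lines List of polylines, each a 2-column coordinate matrix (m).
#' @return Vector of minimum point-to-segment distances (m); `Inf` for an
#'   empty line set.
#' @export
dist_to_lines <- function(x, y, lines) {
  if (!length(lines)) return(rep(Inf, length(x)))
  segs <- do.call(rbind, lapply(lines, function(m) {
    if (nrow(m) < 2) return(NULL)
    cbind(m[-nrow(m), 1], m[-nrow(m), 2], m[-1, 1], m[-1, 2])
  }))
  if (is.null(segs) || !nrow(segs)) return(rep(Inf, length(x)))
  vx <- segs[, 3] - segs[, 1]
  vy <- segs[, 4] - segs[, 2]
  len2 <- pmax(vx^2 + vy^2, .Machine$double.eps)
  vapply(seq_along(x), function(i) {
    t <- pmin(1, pmax(0, ((x[i] - segs[, 1]) * vx + (y[i] - segs[, 2]) * vy) / len2))
    sqrt(min((segs[, 1] + t * vx - x[i])^2 + (segs[, 2] + t * vy - y[i])^2))
  }, numeric(1))
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster format (`.asc`): a 6-line header followed by rows of cell
#' values from the northern row down. A sidecar `<path>.crs` file records the
#' CRS identifier.
#'
#' @param r A [wm_raster()].
#' @param path Output file path.
#' @param digits Significant digits written (default 15: round-trips doubles).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, digits = 15) {
  con <- file(path, "w")
  on.exit(close(con))
  nr <- nrow(r$values); nc <- ncol(r$values)
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10f", r$xmin),
    sprintf("yllcorner %.10f", r$ymin),
    sprintf("cellsize %.10f", r$res),
    "NODATA_value -9999"
  ), con)
  v <- r$values
  v[is.na(v)] <- -9999
  for (i in seq_len(nr)) {
    writeLines(paste(formatC(v[i, ], digits = digits, format = "g"),
                     collapse = " "), con)
  }
  crsid <- if (is.character(r$crs)) r$crs else r$crs$id
  writeLines(crsid, paste0(path, ".crs"))
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path `.asc` file written by [write_ascii_grid()] or any GIS.
#' @param crs CRS identifier; defaults to the sidecar `<path>.crs` if present.
#' @return A [wm_raster()].
#' @export
read_ascii_grid <- function(path, crs = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  nc <- as.integer(vals["ncols"]); nr <- as.integer(vals["nrows"])
  v <- scan(path, skip = 6, quiet = TRUE)
  stopifnot(length(v) == nr * nc)
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA
  if (is.null(crs)) {
    sidecar <- paste0(path, ".crs")
    crs <- if (file.exists(sidecar)) readLines(sidecar, n = 1) else "unknown"
  }
  wm_raster(m, unname(vals["xllcorner"]), unname(vals["yllcorner"]),
            unname(vals["cellsize"]), crs)
}

# Resample raster `r` onto the grid of `template`: method "near" (categorical)
# or "bilinear" (continuous).
raster_resample <- function(r, template, method = c("near", "bilinear")) {
  method <- match.arg(method)
  xs <- raster_xcoords(template)
  ys <- raster_ycoords(template)
  out <- matrix(NA_real_, length(ys), length(xs))
  if (method == "near") {
    for (i in seq_along(ys)) {
      out[i, ] <- raster_extract(r, xs, rep(ys[i], length(xs)))
    }
  } else {
    rx <- raster_xcoords(r)
    ry <- raster_ycoords(r)  # decreasing
    for (i in seq_along(ys)) {
      out[i, ] <- .bilinear(r$values, rx, ry, xs, ys[i])
    }
  }
  wm_raster(out, template$xmin, template$ymin, template$res, template$crs)
}

.bilinear <- function(v, rx, ry, qx, qy) {
  # ry is decreasing (north first); interpolate with clamping at edges.
  cx <- findInterval(qx, rx, all.inside = TRUE)
  iy <- findInterval(-qy, -ry, all.inside = TRUE)
  x1 <- rx[cx]; x2 <- rx[cx + 1]
  y1 <- ry[iy]; y2 <- ry[iy + 1]
  tx <- pmin(1, pmax(0, (qx - x1) / (x2 - x1)))
  ty <- pmin(1, pmax(0, (qy - y1) / (y2 - y1)))
  v11 <- v[cbind(iy, cx)];     v12 <- v[cbind(iy, cx + 1)]
  v21 <- v[cbind(iy + 1, cx)]; v22 <- v[cbind(iy + 1, cx + 1)]
  (1 - ty) * ((1 - tx) * v11 + tx * v12) + ty * ((1 - tx) * v21 + tx * v22)
}
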