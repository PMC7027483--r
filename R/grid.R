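# grid_layer: a minimal georeferenced raster container.
#
# Convention: pixel-is-area, origin top-left, row-major storage. Row 1 is the
# northernmost row. All layers in one analysis must share the grid exactly;
# there is no resampling here (inputs are assumed already co-registered at
# 1 km^2).

#' Create a georeferenced grid layer
#'
#' A `grid_layer` couples a matrix of per-pixel values with an optional
#' matrix of per-pixel relative standard deviations and a simple
#' georeference (lower-left corner, square cell size, CRS label). Missing
#' pixels are `NA` internally and serialised as the nodata value.
#'
#' @param values numeric matrix, row 1 = top (north).
#' @param rel_sd optional matrix of relative standard deviations
#'   (unitless, `>= 0` wherever `values` is valid), same shape as `values`.
#' @param units character units label carried as metadata.
#' @param xll,yll coordinates of the lower-left grid corner (metres).
#' @param cellsize square pixel edge length in metres (default 1000 m,
#'   i.e. 1 km² = 100 ha pixels).
#' @param crs free-text label of the projected CRS. Geometric operations
#'   (buffers, distances) require projected coordinates in metres.
#' @param nodata value used for missing pixels on serialisation.
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(values, rel_sd = NULL, units = "", xll = 0, yll = 0,
                       cellsize = 1000, crs = "local-projected-m",
                       nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.null(rel_sd)) {
    if (!is.matrix(rel_sd) || !all(dim(rel_sd) == dim(values)))
      stop("`rel_sd` must be a matrix with the same shape as `values`")
    if (any(rel_sd < 0 & !is.na(values) & !is.na(rel_sd)))
      stop("`rel_sd` must be >= 0 wherever values are valid")
  }
  if (cellsize <= 0) stop("`cellsize` must be positive")
  structure(
    list(values = values, rel_sd = rel_sd, units = units,
         xll = xll, yll = yll, cellsize = cellsize, crs = crs,
         nodata = nodata),
    class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_layer> %d x %d pixels, cellsize %g m%s\n",
              nrow(v), ncol(v), x$cellsize,
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  valid: %d/%d  range: [%.4g, %.4g]  mean: %.4g\n",
                sum(ok), length(v), min(v[ok]), max(v[ok]), mean(v[ok])))
  else cat("  all nodata\n")
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

#' Pixel area in hectares
#' @param x a `grid_layer`.
#' @return scalar area of one pixel in ha.
#' @export
pixel_area_ha <- function(x) (x$cellsize / 100)^2

#' Pixel centre coordinates
#'
#' @param x a `grid_layer` (or any object with xll/yll/cellsize and a
#'   values matrix).
#' @return list with matrices `x` and `y` of centre coordinates (metres),
#'   same shape as the grid. Row 1 is the northernmost row.
#' @export
pixel_centers <- function(x) {
  nr <- nrow(x$values); nc <- ncol(x$values); cs <- x$cellsize
  cx <- matrix(rep(x$xll + (seq_len(nc) - 0.5) * cs, each = nr), nr, nc)
  cy <- matrix(rep(x$yll + (nr - seq_len(nr) + 0.5) * cs, times = nc), nr, nc)
  list(x = cx, y = cy)
}

#' @keywords internal
check_same_grid <- function(a, b) {
  if (!all(dim(a$values) == dim(b$values)))
    stop("grids are not co-registered: shape mismatch (",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"), ")")
  if (a$cellsize != b$cellsize || a$xll != b$xll || a$yll != b$yll)
    stop("grids are not co-registered: georeference mismatch")
  invisible(TRUE)
}

#' Replace the values (and optionally rel_sd) of a layer, keeping georeference
#' @keywords internal
with_values <- function(x, values, rel_sd = x$rel_sd, units = x$units) {
  grid_layer(values, rel_sd = rel_sd, units = units, xll = x$xll,
             yll = x$yll, cellsize = x$cellsize, crs = x$crs,
             nodata = x$nodata)
}

#' Area-weighted study total of a layer
#'
#' Sums `value x pixel area` over valid pixels. For carbon-rate layers in
#' kg C ha^-1 yr^-1 the optional CO2 conversion multiplies by 44/12 and
#' rescales kg to Mg, yielding Mg CO2eq yr^-1 (conversion applied only at
#' reporting time; layers themselves stay in carbon units).
#'
#' @param x a `grid_layer` in per-ha units.
#' @param as_co2eq if `TRUE`, convert kg C to Mg CO2-equivalent.
#' @return scalar total.
#' @export
study_total <- function(x, as_co2eq = FALSE) {
  v <- x$values
  tot <- sum(v[!is.na(v)] * pixel_area_ha(x))
  if (as_co2eq) c_to_co2eq_mg(tot) else tot
}

# ---- plain-text serialisation (ESRI ASCII grid) ----------------------------

#' Write a grid layer as an ESRI ASCII grid
#'
#' One file per band. `rel_sd`, when present, is written alongside with a
#' `_relsd` suffix. The ASCII-grid format is plain text and readable by any
#' GIS toolchain.
#'
#' @param x a `grid_layer`.
#' @param path output file path (`.asc`).
#' @return invisibly, the path(s) written.
#' @export
write_ascii_grid <- function(x, path) {
  write_one <- function(m, p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("ncols %d", ncol(m)),
      sprintf("nrows %d", nrow(m)),
      sprintf("xllcorner %.6f", x$xll),
      sprintf("yllcorner %.6f", x$yll),
      sprintf("cellsize %.6f", x$cellsize),
      sprintf("NODATA_value %g", x$nodata)), con)
    m[is.na(m)] <- x$nodata
    utils::write.table(format(m, trim = TRUE, digits = 10), con,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    p
  }
  out <- write_one(x$values, path)
  if (!is.null(x$rel_sd))
    out <- c(out, write_one(x$rel_sd, sub("(\\.[^.]+)?$", "_relsd\\1", path)))
  invisible(out)
}

#' Read an ESRI ASCII grid into a grid layer
#'
#' @param path path to an `.asc` file written by [write_ascii_grid()] or any
#'   conforming tool.
#' @param units units label to attach.
#' @return a `grid_layer` (without `rel_sd`; read that band separately).
#' @export
read_ascii_grid <- function(path, units = "") {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == val[["nrows"]], ncol(m) == val[["ncols"]])
  m[m == val[["nodata_value"]]] <- NA_real_
  grid_layer(m, units = units, xll = val[["xllcorner"]],
             yll = val[["yllcorner"]], cellsize = val[["cellsize"]],
             nodata = val[["nodata_value"]])
}
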