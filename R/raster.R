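#' Georeferenced single-band grid
#'
#' Light-weight container for a single-band raster on a regular metric grid:
#' an integer or numeric matrix plus an affine transform (lower-left corner,
#' square cell size) and a CRS tag. Row 1 of the matrix is the top
#' (northernmost) row, matching on-disk raster order.
#'
#' @param values numeric or integer matrix, row 1 = top row.
#' @param cell_size cell edge length in metres (> 0).
#' @param xll,yll coordinates of the lower-left corner of the grid (metres).
#' @param crs free-text CRS tag; the package works in local metric
#'   coordinates and only checks that tags agree across layers.
#' @param nodata value marking missing cells (default `NA`-free: -9999).
#'
#' @return An object of class `eha_raster`.
#' @export
eha_raster <- function(values, cell_size, xll = 0, yll = 0,
                       crs = "LOCAL_METRIC", nodata = -9999L) {
  stopifnot(is.matrix(values), is.numeric(cell_size), cell_size > 0)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll),
         crs = as.character(crs), nodata = nodata),
    class = "eha_raster"
  )
}

#' @export
print.eha_raster <- function(x, ...) {
  cat(sprintf("<eha_raster> %d x %d cells, %.0f m cell, origin (%.0f, %.0f), crs '%s'\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll, x$crs))
  invisible(x)
}

#' @export
dim.eha_raster <- function(x) dim(x$values)

# x/y coordinates of cell centroids; row 1 is the top row.
raster_centroids <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cell_size,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cell_size)
}

#' Tidy a raster into a long tibble
#'
#' @param x an [eha_raster()].
#' @param ... unused.
#' @return A tibble with `row`, `col`, centroid `x`, `y` and `value`;
#'   nodata cells are returned as `NA`.
#' @export
tidy.eha_raster <- function(x, ...) {
  cc <- raster_centroids(x)
  v <- x$values
  v[v == x$nodata] <- NA
  tibble::tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    x = rep(cc$x, each = nrow(v)),
    y = rep(cc$y, times = ncol(v)),
    value = as.vector(v)
  )
}

#' Write a raster as an ESRI ASCII grid
#'
#' Writes the plain-text `.asc` interchange format (header of six lines, then
#' rows top to bottom). The CRS tag is stored in a small JSON sidecar
#' `<path>.json` because the ASCII grid format itself carries none.
#'
#' @param r an [eha_raster()].
#' @param path output file path (conventionally ending in `.asc`).
#' @param digits significant digits for numeric grids.
#' @return `path`, invisibly.
#' @export
write_raster_asc <- function(r, path, digits = 10) {
  stopifnot(inherits(r, "eha_raster"))
  v <- r$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %s", format(r$nodata, scientific = FALSE))
  )
  body <- apply(v, 1, function(row) {
    paste(format(row, trim = TRUE, digits = digits, scientific = FALSE),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  jsonlite::write_json(list(crs = r$crs), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file written by [write_raster_asc()] or any
#'   conforming tool. A `<path>.json` sidecar, if present, supplies the CRS
#'   tag.
#' @return An [eha_raster()].
#' @export
read_raster_asc <- function(path) {
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- vapply(kv, `[`, "", 2)
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) {
    stop("missing georeferencing header in ", path, "; expected keys: ",
         paste(setdiff(need, keys), collapse = ", "))
  }
  g <- as.numeric(vals[match(need, keys)])
  body <- lines[-(1:6)]
  if (length(body) != g[2]) stop("expected ", g[2], " data rows, got ", length(body))
  v <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = g[2], ncol = g[1], byrow = TRUE)
  crs <- "LOCAL_METRIC"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    crs <- jsonlite::read_json(sidecar)$crs %||% crs
  }
  eha_raster(v, cell_size = g[5], xll = g[3], yll = g[4], crs = crs,
             nodata = g[6])
}

#' Read and validate a loss-year raster
#'
#' Reads a single-band integer grid coding, per pixel, the first year of
#' detected forest loss: 0 = never lost, v in 1..`n_years` = first loss in
#' year `year_base + v` (Global Forest Change convention, year_base 2000).
#'
#' @param path `.asc` file path.
#' @param n_years number of annual time steps (default 18, codes 0-18).
#' @return An `eha_raster` of class `c("loss_raster", "eha_raster")` with a
#'   `n_years` field.
#' @export
read_loss_raster <- function(path, n_years = 18) {
  r <- read_raster_asc(path)
  as_loss_raster(r, n_years = n_years)
}

#' Validate a raster as a loss-year raster
#'
#' @param r an [eha_raster()].
#' @param n_years number of annual steps; valid codes are 0..`n_years`.
#' @return `r` with class `loss_raster` prepended and integer values.
#' @export
as_loss_raster <- function(r, n_years = 18) {
  stopifnot(inherits(r, "eha_raster"), n_years >= 2)
  v <- r$values
  ok <- v == r$nodata | (v >= 0 & v <= n_years & v == round(v))
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf(
      "invalid loss-year code %s at pixel (row %d, col %d); valid codes are 0..%d or nodata %s",
      format(v[bad]), (bad - 1) %% nrow(v) + 1, (bad - 1) %/% nrow(v) + 1,
      n_years, format(r$nodata)))
  }
  r$values <- matrix(as.integer(v), nrow(v), ncol(v))
  r$n_years <- as.integer(n_years)
  class(r) <- unique(c("loss_raster", class(r)))
  r
}
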