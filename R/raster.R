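#' Georeferenced raster layer
#'
#' A minimal planar raster: a numeric matrix whose first row is the
#' northernmost row (top-left origin, as in ESRI ASCII grids), a lower-left
#' corner, a square pixel size, and a nodata sentinel. Continuous layers hold
#' arbitrary numeric values; categorical layers hold integer class codes with
#' an optional code-to-label table.
#'
#' @param values numeric matrix (rows x cols), row 1 = top (north).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize pixel edge length in map units (> 0).
#' @param nodata nodata sentinel value (default -9999).
#' @param kind "continuous" or "categorical".
#' @param class_table named character vector mapping class codes to labels
#'   (categorical only), e.g. `c("1" = "fynbos", "2" = "cultivation")`.
#' @return object of class `raster_layer`.
#' @export
raster_layer <- function(values, xll = 0, yll = 0, cellsize = 1,
                         nodata = -9999, kind = c("continuous", "categorical"),
                         class_table = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop_popland("raster values must be a numeric matrix")
  if (nrow(values) < 1 || ncol(values) < 1)
    stop_popland("raster extent must be positive (got %d x %d)", nrow(values), ncol(values))
  if (!is.finite(cellsize) || cellsize <= 0)
    stop_popland("cellsize must be a positive number")
  if (kind == "categorical") {
    v <- values[values != nodata & !is.na(values)]
    if (length(v) && any(v != round(v)))
      stop_popland("categorical raster values must be integer class codes")
  }
  bad <- !is.finite(values) & !is.na(values)
  if (any(bad)) stop_popland("raster contains non-finite values that are not nodata")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         nodata = nodata, kind = kind, class_table = class_table),
    class = "raster_layer"
  )
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf("raster_layer: %d x %d %s, cellsize %g, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$kind, x$cellsize, x$xll, x$yll))
  invisible(x)
}

raster_extent <- function(r) {
  c(xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cellsize,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cellsize)
}

point_in_raster <- function(r, x, y) {
  e <- raster_extent(r)
  x >= e["xmin"] & x <= e["xmax"] & y >= e["ymin"] & y <= e["ymax"]
}

#' Generate a synthetic landscape raster
#'
#' Produces the landscape layers used by the synthetic study design:
#' smooth continuous gradients (elevation / precipitation analogues), a
#' ridge (a high-valued band acting as a putative barrier), a constant
#' field, or a patchy categorical mosaic (vegetation / land-use analogue)
#' built from a seeded Voronoi tessellation of random sites.
#'
#' @param extent integer `c(rows, cols)`.
#' @param kind one of "gradient", "ridge", "constant", "categorical_patches".
#' @param params list of kind-specific parameters:
#'   * gradient: `direction` ("east" or "north"), `range = c(lo, hi)`.
#'   * ridge: `axis` ("vertical" horizontal band position on x), `center`
#'     (map units), `width` (Gaussian sd, map units), `base`, `height`.
#'   * constant: `value`.
#'   * categorical_patches: `n_classes`, `n_patches`, `seed`.
#' @param xll,yll,cellsize georeferencing, as [raster_layer()].
#' @return a `raster_layer`.
#' @export
make_landscape <- function(extent, kind = c("gradient", "ridge", "constant",
                                            "categorical_patches"),
                           params = list(), xll = 0, yll = 0, cellsize = 1) {
  kind <- match.arg(kind)
  extent <- as.integer(extent)
  if (length(extent) != 2L || any(extent <= 0))
    stop_popland("extent must be positive c(rows, cols)")
  nr <- extent[1]; nc <- extent[2]
  # cell-center coordinates
  cx <- xll + (seq_len(nc) - 0.5) * cellsize
  cy <- yll + (nr - seq_len(nr) + 0.5) * cellsize  # row 1 = top
  vals <- switch(kind,
    constant = {
      v <- params$value %||% 0
      matrix(v, nr, nc)
    },
    gradient = {
      rg <- params$range %||% c(0, 100)
      dir <- params$direction %||% "east"
      if (dir == "east") {
        if (nc == 1) row_vals <- rep(mean(rg), 1)
        else row_vals <- rg[1] + (rg[2] - rg[1]) * (seq_len(nc) - 1) / (nc - 1)
        matrix(row_vals, nr, nc, byrow = TRUE)
      } else if (dir == "north") {
        if (nr == 1) col_vals <- rep(mean(rg), 1)
        else col_vals <- rg[2] - (rg[2] - rg[1]) * (seq_len(nr) - 1) / (nr - 1)
        matrix(col_vals, nr, nc)
      } else stop_popland("unknown gradient direction '%s'", dir)
    },
    ridge = {
      center <- params$center %||% (xll + nc * cellsize / 2)
      width <- params$width %||% (nc * cellsize / 10)
      base <- params$base %||% 0
      height <- params$height %||% 100
      row_vals <- base + height * exp(-((cx - center) / width)^2)
      matrix(row_vals, nr, nc, byrow = TRUE)
    },
    categorical_patches = {
      k <- params$n_classes %||% 3L
      np <- params$n_patches %||% (4L * k)
      sd <- params$seed %||% 1L
      set.seed(derive_seed(sd, 11L))
      px <- stats::runif(np, min(cx), max(cx))
      py <- stats::runif(np, min(cy), max(cy))
      pclass <- sample(rep_len(seq_len(k), np))
      g <- expand.grid(y = cy, x = cx)  # column-major over rows
      # nearest Voronoi site per cell
      d2 <- outer(g$x, px, `-`)^2 + outer(g$y, py, `-`)^2
      cls <- pclass[max.col(-d2, ties.method = "first")]
      matrix(cls, nr, nc)
    }
  )
  ct <- NULL
  knd <- "continuous"
  if (kind == "categorical_patches") {
    knd <- "categorical"
    k <- params$n_classes %||% 3L
    ct <- params$class_table %||% stats::setNames(paste0("class", seq_len(k)), seq_len(k))
  }
  raster_layer(vals, xll = xll, yll = yll, cellsize = cellsize,
               kind = knd, class_table = ct)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path (.asc). Supports `xllcorner/yllcorner` headers.
#' @param kind "continuous" or "categorical".
#' @param class_table optional class table for categorical layers.
#' @return a `raster_layer`.
#' @export
read_ascii_grid <- function(path, kind = "continuous", class_table = NULL) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (is.null(nc) || is.null(nr)) stop_popland("not an ESRI ASCII grid: %s", path)
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) stop_popland("grid body length mismatch in %s", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  raster_layer(m, xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0,
               cellsize = hdr$cellsize %||% 1,
               nodata = hdr$nodata_value %||% -9999,
               kind = kind, class_table = class_table)
}

#' Write an ESRI ASCII grid
#'
#' @param r a `raster_layer`.
#' @param path output path.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "raster_layer"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", r$nodata)
  ), con)
  m <- r$values
  m[is.na(m)] <- r$nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract a supercover raster transect
#'
#' Returns the values of every pixel that the straight segment between two
#' points crosses with positive length (a "supercover" traversal), endpoints
#' included. The traversal is computed from the full ordered set of grid-line
#' crossings, so it is symmetric: the transect from b to a visits the same
#' pixel set in reverse. Nodata pixels are dropped from the value sequence
#' but counted separately.
#'
#' @param raster a `raster_layer`.
#' @param a,b numeric `c(x, y)` endpoints in map units, inside the raster
#'   extent (no reprojection is performed; coordinates must share the raster
#'   CRS).
#' @return list with `values` (nodata removed), `cells` (matrix of row, col),
#'   `n_nodata` (count of traversed nodata pixels).
#' @export
extract_transect <- function(raster, a, b) {
  stopifnot(inherits(raster, "raster_layer"))
  a <- as.numeric(a); b <- as.numeric(b)
  if (!point_in_raster(raster, a[1], a[2]) || !point_in_raster(raster, b[1], b[2]))
    stop_popland("transect endpoints must lie inside the raster extent")
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cs <- raster$cellsize
  ytop <- raster$yll + nr * cs
  # continuous grid coordinates: gx in [0, nc], gy (from top) in [0, nr]
  gx <- c((a[1] - raster$xll) / cs, (b[1] - raster$xll) / cs)
  gy <- c((ytop - a[2]) / cs, (ytop - b[2]) / cs)
  cell_of <- function(x, y) {
    col <- min(max(floor(x) + 1L, 1L), nc)
    row <- min(max(floor(y) + 1L, 1L), nr)
    c(row, col)
  }
  if (gx[1] == gx[2] && gy[1] == gy[2]) {
    rc <- cell_of(gx[1], gy[1])
    v <- raster$values[rc[1], rc[2]]
    nodata <- is.na(v) || v == raster$nodata
    return(list(values = if (nodata) numeric(0) else v,
                cells = matrix(rc, ncol = 2, dimnames = list(NULL, c("row", "col"))),
                n_nodata = as.integer(nodata)))
  }
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  ts <- c(0, 1)
  if (dx != 0) {
    ks <- seq(ceiling(min(gx)), floor(max(gx)))
    ts <- c(ts, (ks - gx[1]) / dx)
  }
  if (dy != 0) {
    ks <- seq(ceiling(min(gy)), floor(max(gy)))
    ts <- c(ts, (ks - gy[1]) / dy)
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  keep <- (ts[-1] - ts[-length(ts)]) > 1e-12   # positive-length intersections only
  mid <- mid[keep]
  rows <- pmin(pmax(floor(gy[1] + mid * dy) + 1L, 1L), nr)
  cols <- pmin(pmax(floor(gx[1] + mid * dx) + 1L, 1L), nc)
  key <- rows + nr * (cols - 1L)
  dup <- duplicated(key)
  rows <- rows[!dup]; cols <- cols[!dup]
  vals <- raster$values[cbind(rows, cols)]
  nodata <- is.na(vals) | vals == raster$nodata
  if (all(nodata))
    warning("transect traverses only nodata pixels")
  list(values = vals[!nodata],
       cells = cbind(row = rows, col = cols),
       n_nodata = sum(nodata))
}
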