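#' Create a raster grid
#'
#' The basic spatial carrier of the package: a rectangular raster with a
#' square cell size, an origin, and an implicit nodata mask (`NA` cells).
#' Rows run north to south (row 1 is the northern edge), columns west to
#' east. Cell `(1, 1)` is the upper-left cell; a cell covers the half-open
#' box `[x, x + cell_size) x (y - cell_size, y]` so every point belongs to
#' exactly one cell.
#'
#' @param values numeric matrix of cell values; `NA` marks nodata.
#' @param x_origin x coordinate (map units) of the western (left) edge.
#' @param y_origin y coordinate of the northern (top) edge.
#' @param cell_size square cell edge length in map units, `> 0`.
#' @param kind `"quantitative"` or `"categorical"`.
#' @param levels for categorical grids, an optional named level table
#'   (integer codes to labels). At most 26 levels are allowed.
#' @return an object of class `sdm_grid`.
#' @export
new_grid <- function(values, x_origin = 0, y_origin = nrow(values),
                     cell_size = 1,
                     kind = c("quantitative", "categorical"),
                     levels = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (kind == "categorical") {
    codes <- unique(values[!is.na(values)])
    if (length(codes) > 26)
      stop("categorical grids support at most 26 levels")
    if (any(codes != round(codes)))
      stop("categorical grid values must be integer codes")
    if (is.null(levels)) levels <- sort(codes)
  }
  structure(
    list(values = values, x_origin = as.numeric(x_origin),
         y_origin = as.numeric(y_origin), cell_size = as.numeric(cell_size),
         kind = kind, levels = levels),
    class = "sdm_grid")
}

#' @export
print.sdm_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<sdm_grid> %d x %d cells (%s), cell size %g\n",
              nrow(v), ncol(v), x$kind, x$cell_size))
  cat(sprintf("  origin (W, N): (%g, %g); %d nodata cells\n",
              x$x_origin, x$y_origin, sum(is.na(v))))
  ok <- v[!is.na(v)]
  if (length(ok))
    cat(sprintf("  values: [%g, %g]\n", min(ok), max(ok)))
  invisible(x)
}

is_grid <- function(x) inherits(x, "sdm_grid")

#' Grid dimensions as (nrow, ncol)
#' @param g an `sdm_grid`.
#' @return integer vector `c(nrow, ncol)`.
#' @export
grid_dim <- function(g) dim(g$values)

grid_check <- function(g, arg = "grid") {
  if (!is_grid(g)) stop(sprintf("`%s` must be an sdm_grid", arg))
  invisible(g)
}

#' Do two grids share the same geometry?
#' @param a,b `sdm_grid` objects.
#' @return logical.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$x_origin, a$y_origin, a$cell_size),
                     c(b$x_origin, b$y_origin, b$cell_size)))
}

#' Cell-centre coordinates of every cell
#' @param g an `sdm_grid`.
#' @return matrix with columns `x`, `y`, one row per cell in column-major
#'   (R matrix) order.
#' @export
cell_centers <- function(g) {
  d <- dim(g$values)
  cs <- g$cell_size
  rows <- seq_len(d[1]); cols <- seq_len(d[2])
  x <- g$x_origin + (cols - 0.5) * cs
  y <- g$y_origin - (rows - 0.5) * cs
  cbind(x = rep(x, each = d[1]), y = rep(y, times = d[2]))
}

#' Locate the cells containing points
#'
#' Applies the half-open containment convention: x in
#' `[x0 + (c-1)*cs, x0 + c*cs)` and y in `(y0 - r*cs, y0 - (r-1)*cs]`.
#'
#' @param g an `sdm_grid`.
#' @param x,y point coordinates (map units).
#' @return data.frame with columns `row`, `col`, `inside` (logical).
#' @export
locate_cells <- function(g, x, y) {
  cs <- g$cell_size
  d <- dim(g$values)
  col <- floor((x - g$x_origin) / cs) + 1
  # row r covers (y0 - r*cs, y0 - (r-1)*cs]: floor() + 1 sends a shared
  # edge y = y0 - k*cs to row k + 1, whose closed top edge it is
  row <- floor((g$y_origin - y) / cs) + 1
  inside <- row >= 1 & row <= d[1] & col >= 1 & col <= d[2] &
    is.finite(x) & is.finite(y)
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Values of a grid at point locations
#' @param g an `sdm_grid`.
#' @param x,y coordinates.
#' @return numeric vector; `NA` outside the grid or on nodata.
#' @export
grid_value_at <- function(g, x, y) {
  loc <- locate_cells(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- loc$inside
  out[ok] <- g$values[cbind(loc$row[ok], loc$col[ok])]
  out
}

## ---- terrain derivatives -------------------------------------------------

# Shift a matrix by (dr, dc), padding with NA.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

horn_gradients <- function(dem) {
  grid_check(dem, "dem")
  if (dem$kind != "quantitative") stop("DEM must be quantitative")
  m <- dem$values
  if (nrow(m) < 3 || ncol(m) < 3)
    stop("DEM must be at least 3 x 3 cells")
  cs <- dem$cell_size
  # neighbours: a b c / d e f / g h i, row 1 = north
  a <- shift_mat(m,  1,  1); b <- shift_mat(m,  1, 0); cc <- shift_mat(m,  1, -1)
  d <- shift_mat(m,  0,  1);                            f <- shift_mat(m,  0, -1)
  g <- shift_mat(m, -1,  1); h <- shift_mat(m, -1, 0); i <- shift_mat(m, -1, -1)
  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)  # eastward dz/dx
  gy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)  # northward dz/dy
  bad <- is.na(a) | is.na(b) | is.na(cc) | is.na(d) | is.na(f) |
    is.na(g) | is.na(h) | is.na(i) | is.na(m)
  gx[bad] <- NA; gy[bad] <- NA
  list(gx = gx, gy = gy)
}

#' Slope from a DEM (Horn 3x3 stencil)
#'
#' Rate of change of the surface computed with Horn's weighted finite
#' differences on the 3x3 neighbourhood; returned in degrees. Edge cells and
#' cells adjacent to nodata become nodata.
#'
#' @param dem quantitative `sdm_grid` of elevations/depths, at least 3x3.
#' @return an `sdm_grid` of slopes in degrees.
#' @export
derive_slope <- function(dem) {
  gr <- horn_gradients(dem)
  slope <- atan(sqrt(gr$gx^2 + gr$gy^2)) * 180 / pi
  new_grid(slope, dem$x_origin, dem$y_origin, dem$cell_size)
}

#' Eastness and northness from a DEM
#'
#' Aspect is the azimuth of steepest descent, measured clockwise from north;
#' it is decomposed into its sine (eastness) and cosine (northness) to avoid
#' the circular discontinuity at north. Flat cells get eastness = northness
#' = 0, a deliberately neutral value so flat seabeds remain modellable.
#'
#' @param dem quantitative `sdm_grid`, at least 3x3.
#' @return list with `eastness` and `northness` grids.
#' @export
derive_aspect_components <- function(dem) {
  gr <- horn_gradients(dem)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  east <- -gr$gx / mag
  north <- -gr$gy / mag
  flat <- !is.na(mag) & mag == 0
  east[flat] <- 0; north[flat] <- 0
  list(
    eastness = new_grid(east, dem$x_origin, dem$y_origin, dem$cell_size),
    northness = new_grid(north, dem$x_origin, dem$y_origin, dem$cell_size))
}

## ---- distances -----------------------------------------------------------

# Minimum Euclidean distance from each row of `from` (x, y) to the nearest
# row of `to` (x, y). Chunked to bound memory.
min_dist_to_points <- function(from, to, chunk = 2048L) {
  n <- nrow(from)
  out <- numeric(n)
  tx <- to[, 1]; ty <- to[, 2]
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(from[s:e, 1], tx, "-")
    dy <- outer(from[s:e, 2], ty, "-")
    out[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  out
}

#' Euclidean distance to the nearest shore cell
#'
#' Distance (map units) from every cell centre to the nearest centre of a
#' cell flagged as shore. Shore cells get 0.
#'
#' @param shore_mask `sdm_grid` whose nonzero, non-`NA` cells are shoreline.
#' @return quantitative `sdm_grid` of distances.
#' @export
distance_to_shore <- function(shore_mask) {
  grid_check(shore_mask, "shore_mask")
  m <- shore_mask$values
  shore <- which(!is.na(m) & m != 0)
  if (!length(shore)) stop("shore mask contains no shore cells")
  ctr <- cell_centers(shore_mask)
  d <- min_dist_to_points(ctr, ctr[shore, , drop = FALSE])
  new_grid(matrix(d, nrow(m), ncol(m)),
           shore_mask$x_origin, shore_mask$y_origin, shore_mask$cell_size)
}

## ---- environment stacks --------------------------------------------------

#' Bundle co-registered grids into a predictor stack
#'
#' @param layers named list of `sdm_grid` objects sharing origin, cell size
#'   and dimensions.
#' @return an object of class `sdm_stack`.
#' @export
new_stack <- function(layers) {
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("`layers` must be a non-empty named list")
  lapply(layers, grid_check)
  ref <- layers[[1]]
  for (nm in names(layers)[-1])
    if (!same_geometry(ref, layers[[nm]]))
      stop(sprintf("layer '%s' is not co-registered with '%s'",
                   nm, names(layers)[1]))
  structure(list(layers = layers), class = "sdm_stack")
}

#' @export
print.sdm_stack <- function(x, ...) {
  d <- grid_dim(x$layers[[1]])
  cat(sprintf("<sdm_stack> %d layers, %d x %d cells: %s\n",
              length(x$layers), d[1], d[2],
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Joint validity mask of a stack
#'
#' A cell is valid only when it is valid (non-nodata) in every layer.
#'
#' @param stack an `sdm_stack`.
#' @return logical matrix.
#' @export
stack_valid_mask <- function(stack) {
  Reduce(`&`, lapply(stack$layers, function(g) !is.na(g$values)))
}

#' Predictor table of all valid cells
#'
#' One row per jointly valid cell, one column per layer; categorical layers
#' become factors. Cell indices and centre coordinates are included so rows
#' can be mapped back onto the grid.
#'
#' @param stack an `sdm_stack`.
#' @return data.frame with columns `cell`, `x`, `y` and one per layer.
#' @export
stack_table <- function(stack) {
  ok <- which(stack_valid_mask(stack))
  ctr <- cell_centers(stack$layers[[1]])
  cols <- lapply(stack$layers, function(g) {
    v <- g$values[ok]
    if (g$kind == "categorical") factor(v, levels = g$levels) else v
  })
  cbind(data.frame(cell = ok, x = ctr[ok, 1], y = ctr[ok, 2]),
        as.data.frame(cols))
}

#' Extract predictor values at point locations
#'
#' Assigns each point to its containing cell (no interpolation) and returns
#' the stacked layer values there. Points outside the grid or on a nodata
#' cell are excluded from the returned table and reported.
#'
#' @param stack an `sdm_stack`.
#' @param pts data.frame with columns `x`, `y` (extra columns carried over).
#' @param quiet suppress the exclusion message.
#' @return data.frame of the valid rows, with an attribute `excluded`
#'   holding the indices of dropped points.
#' @export
extract_at_points <- function(stack, pts, quiet = FALSE) {
  if (!all(c("x", "y") %in% names(pts)))
    stop("`pts` must have columns x and y")
  ref <- stack$layers[[1]]
  loc <- locate_cells(ref, pts$x, pts$y)
  valid <- stack_valid_mask(stack)
  ok <- loc$inside
  ok[ok] <- valid[cbind(loc$row[ok], loc$col[ok])]
  if (!any(ok)) stop("no point falls on a valid cell")
  idx <- cbind(loc$row[ok], loc$col[ok])
  cols <- lapply(stack$layers, function(g) {
    v <- g$values[idx]
    if (g$kind == "categorical") factor(v, levels = g$levels) else v
  })
  out <- cbind(pts[ok, , drop = FALSE],
               cell = (idx[, 2] - 1L) * nrow(valid) + idx[, 1L],
               as.data.frame(cols, row.names = NULL))
  rownames(out) <- NULL
  excl <- which(!ok)
  if (length(excl) && !quiet)
    message(sprintf("extract_at_points: %d point(s) outside grid or on nodata, excluded",
                    length(excl)))
  attr(out, "excluded") <- excl
  out
}

## ---- ESRI ASCII grid I/O -------------------------------------------------

#' Write a grid as an ESRI ASCII raster
#'
#' Values are written with 17 significant digits so a write/read round trip
#' is bit-exact for doubles.
#'
#' @param g an `sdm_grid`.
#' @param path output file.
#' @param nodata nodata sentinel written to the header.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  grid_check(g)
  m <- g$values
  yll <- g$y_origin - nrow(m) * g$cell_size
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.17g", g$x_origin),
    sprintf("yllcorner %.17g", yll),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", nodata))
  m[is.na(m)] <- nodata
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file path.
#' @param kind `"quantitative"` or `"categorical"`.
#' @return an `sdm_grid`.
#' @export
read_ascii_grid <- function(path, kind = "quantitative") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("value count does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  new_grid(m, x_origin = xll, y_origin = yll + nr * hdr$cellsize,
           cell_size = hdr$cellsize, kind = kind)
}
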