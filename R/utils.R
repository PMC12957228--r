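#' @keywords internal
"_PACKAGE"

BAND_NAMES <- c("blue", "green", "red", "red_edge", "nir")
CLASS_NAMES <- c("soil", "stems_leaves", "lint")
# raster codes: 0 = unclassified, 1 = soil, 2 = stems_leaves, 3 = lint
CLASS_CODES <- c(soil = 1L, stems_leaves = 2L, lint = 3L)
UNCLASSIFIED_CODE <- 0L

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)

#' Flatten a height x width x band reflectance array to a pixel matrix
#'
#' Pixels are in column-major raster order; columns are the five bands.
#' @keywords internal
#' @noRd
pixel_matrix <- function(reflectance) {
  d <- dim(reflectance)
  m <- matrix(reflectance, nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- BAND_NAMES
  m
}

#' Test which pixel centers fall inside a polygon (even-odd ray casting)
#'
#' Pixel (i, j) (row, col) has center (x, y) = (j - 0.5, i - 0.5) with the
#' origin at the raster's top-left corner and y increasing downwards.
#'
#' @param coords two-column matrix of polygon vertices (x, y), open or closed.
#' @param dim raster dimensions c(height, width).
#' @return integer vector of linear (column-major) pixel indices inside.
#' @keywords internal
polygon_pixel_index <- function(coords, dim) {
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  if (nrow(coords) > 1 && all(coords[1, ] == coords[nrow(coords), ])) {
    coords <- coords[-nrow(coords), , drop = FALSE]
  }
  h <- dim[1]; w <- dim[2]
  jr <- range(coords[, 1]); ir <- range(coords[, 2])
  cols <- max(1L, ceiling(jr[1] + 0.5)):min(w, floor(jr[2] + 0.5))
  rows <- max(1L, ceiling(ir[1] + 0.5)):min(h, floor(ir[2] + 0.5))
  if (!length(cols) || !length(rows)) return(integer(0))
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  inside <- rep(FALSE, length(px))
  n <- nrow(coords)
  xj <- coords[c(2:n, 1), 1]; yj <- coords[c(2:n, 1), 2]
  xi <- coords[, 1]; yi <- coords[, 2]
  for (k in seq_len(n)) {
    crosses <- ((yi[k] > py) != (yj[k] > py))
    if (any(crosses)) {
      xint <- xi[k] + (py[crosses] - yi[k]) / (yj[k] - yi[k]) * (xj[k] - xi[k])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  ii <- rep(rows, times = length(cols))[inside]
  jj <- rep(cols, each = length(rows))[inside]
  as.integer((jj - 1L) * h + ii)
}

#' Axis-aligned rectangle as a closed polygon coordinate matrix
#' @keywords internal
#' @noRd
rect_coords <- function(row0, row1, col0, col1) {
  # pixel rows row0..row1, cols col0..col1 (inclusive) -> boundary on pixel edges
  x0 <- col0 - 1; x1 <- col1; y0 <- row0 - 1; y1 <- row1
  cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
}

#' Summed-area table of a logical matrix
#' @keywords internal
#' @noRd
integral_image <- function(m) {
  apply(apply(m, 2, cumsum), 1, cumsum) |> t()
}

#' Top-left positions of size x size all-TRUE windows
#' @keywords internal
#' @noRd
pure_window_positions <- function(ind, size) {
  h <- nrow(ind); w <- ncol(ind)
  if (h < size || w < size) return(cbind(row = integer(0), col = integer(0)))
  S <- integral_image(ind)
  Sp <- rbind(0, cbind(0, S))
  r <- 1:(h - size + 1); c <- 1:(w - size + 1)
  win <- Sp[r + size, c + size, drop = FALSE] - Sp[r, c + size, drop = FALSE] -
    Sp[r + size, c, drop = FALSE] + Sp[r, c, drop = FALSE]
  hit <- which(win == size * size, arr.ind = TRUE)
  cbind(row = hit[, 1], col = hit[, 2])
}
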