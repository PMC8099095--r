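#' Cell containment and cell centers
#'
#' `cellFromXY` maps projected coordinates to (row, col) indices under the
#' half-open cell convention: a cell owns `[x, x + cellSize)` horizontally and
#' `(y - cellSize, y]` vertically, so a point on a shared edge belongs to the
#' cell to its right/below. Points outside the extent map to `NA`.
#' `xyFromCell` returns cell-center coordinates.
#'
#' @param spec a [GridSpec-class].
#' @param x,y projected coordinates (metres).
#' @param row,col cell indices (1-based, row 1 at the top).
#' @return `cellFromXY`: a two-column integer matrix `(row, col)`;
#'   `xyFromCell`: a two-column numeric matrix `(x, y)` of cell centers.
#' @export
cellFromXY <- function(spec, x, y) {
  col <- floor((x - spec@xmin) / spec@cellSize) + 1
  row <- floor((spec@ymax - y) / spec@cellSize) + 1
  # top edge (y == ymax) belongs to row 1; right/bottom edges are outside
  row[y == spec@ymax] <- 1
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1 | col > spec@ncols | row < 1 | row > spec@nrows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname cellFromXY
#' @export
xyFromCell <- function(spec, row, col) {
  cbind(x = spec@xmin + (col - 0.5) * spec@cellSize,
        y = spec@ymax - (row - 0.5) * spec@cellSize)
}

# Derive a child seed from a base seed and a small offset, kept within the
# 32-bit integer range expected by set.seed().
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 97L * as.numeric(offset)) %% 2147483647)
}

# Mode of a vector (first-encountered value on ties), ignoring NA.
statMode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}
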