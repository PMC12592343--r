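#' Grid specification for a discretised store floor
#'
#' Defines the square grid a store floor is discretised into. The grid is
#' always square with side `2^depth` cells, so that every cell can be named by
#' a fixed-length hierarchical quadrant code (see [encode_cell()]). The
#' full-store configuration uses `depth = 6` (a 64 x 64 grid, 4096 cells); the
#' small "desk" world used for CPU-scale experiments uses `depth = 4`
#' (16 x 16).
#'
#' @param depth Recursion depth of the quadrant subdivision; the grid has
#'   `2^depth` cells per side and codes have `depth` characters.
#' @param cell_size_m Physical edge length of one cell in meters.
#' @param origin Corner convention; only `"lower-left"` is supported: x grows
#'   with columns, y grows with rows.
#' @return An object of class `grid_spec` with fields `n_cols`, `n_rows`,
#'   `depth`, `cell_size_m`, `origin`.
#' @examples
#' g <- grid_spec(depth = 6, cell_size_m = 0.25)
#' g$n_cols # 64
#' @export
grid_spec <- function(depth = 6L, cell_size_m = 0.25, origin = "lower-left") {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L)
    stop("`depth` must be an integer >= 1", call. = FALSE)
  if (depth > 6L)
    stop("`depth` > 6 would exhaust the a-z quadrant alphabet", call. = FALSE)
  if (!is.numeric(cell_size_m) || cell_size_m <= 0)
    stop("`cell_size_m` must be > 0", call. = FALSE)
  origin <- match.arg(origin, "lower-left")
  n <- as.integer(2^depth)
  structure(
    list(n_cols = n, n_rows = n, depth = depth,
         cell_size_m = cell_size_m, origin = origin),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells (depth %d), cell %.3g m, origin %s\n",
              x$n_cols, x$n_rows, x$depth, x$cell_size_m, x$origin))
  invisible(x)
}

#' Rebuild a grid_spec from a config list
#'
#' Validates the square power-of-two constraint that [grid_spec()] guarantees
#' by construction; used when reading YAML run configs.
#'
#' @param cfg A list with fields `n_cols`, `n_rows`, `depth`, `cell_size_m`.
#' @return A `grid_spec`.
#' @export
grid_from_config <- function(cfg) {
  g <- grid_spec(depth = cfg$depth, cell_size_m = cfg$cell_size_m)
  if (!is.null(cfg$n_cols) && (cfg$n_cols != g$n_cols ||
                               (!is.null(cfg$n_rows) && cfg$n_rows != g$n_rows)))
    stop("grid config is not square 2^depth: n_cols/n_rows must equal ",
         g$n_cols, call. = FALSE)
  g
}

# 4-letter alphabet block for subdivision level d (1-based): a-d, e-h, i-l, ...
level_block <- function(d) letters[(4L * (d - 1L) + 1L):(4L * (d - 1L) + 4L)]

#' Encode grid cells as hierarchical quadrant codes
#'
#' Each cell is named by a `depth`-character string; character `d` records
#' which quadrant the cell falls into at subdivision level `d`, drawn from
#' that level's private 4-letter block of the alphabet (level 1: a-d, level 2:
#' e-h, ...). The quadrant index is `2*row_bit + col_bit` with bits taken
#' most-significant first (Z-order), so codes sharing a prefix share a square
#' neighbourhood: the longer the common prefix, the closer the cells.
#'
#' @param col,row Integer cell indices, 0-based, vectorised.
#' @param grid A [grid_spec()].
#' @return Character vector of codes, one per input cell.
#' @examples
#' g <- grid_spec(6)
#' encode_cell(0, 0, g)    # "aeimqu"
#' encode_cell(63, 63, g)  # "dhlptx"
#' @seealso [decode_code()], [validate_code()], [prefix_region()]
#' @export
encode_cell <- function(col, row, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  col <- as.integer(col); row <- as.integer(row)
  if (length(col) != length(row))
    stop("`col` and `row` must have equal length", call. = FALSE)
  if (any(is.na(col) | is.na(row)) ||
      any(col < 0L | col >= grid$n_cols | row < 0L | row >= grid$n_rows))
    stop(sprintf("cell index out of range for %d x %d grid",
                 grid$n_cols, grid$n_rows), call. = FALSE)
  parts <- vector("list", grid$depth)
  for (l in seq_len(grid$depth)) {
    shift <- grid$depth - l
    cb <- bitwAnd(bitwShiftR(col, shift), 1L)
    rb <- bitwAnd(bitwShiftR(row, shift), 1L)
    parts[[l]] <- letters[4L * (l - 1L) + 2L * rb + cb + 1L]
  }
  do.call(paste0, parts)
}

#' Decode quadrant codes back to cell indices
#'
#' Inverse of [encode_cell()]; `decode_code(encode_cell(c, r, g), g)` returns
#' `(c, r)` for every cell.
#'
#' @param code Character vector of full-length codes.
#' @param grid A [grid_spec()].
#' @return A data.frame with integer columns `col`, `row`.
#' @export
decode_code <- function(code, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ok <- validate_code(code, grid)
  if (any(!ok)) {
    bad <- code[!ok][1L]
    # name the first offending character position for the error
    pos <- bad_char_position(bad, grid)
    stop(sprintf("malformed code '%s': character %s is not in its level's block",
                 bad, pos), call. = FALSE)
  }
  n <- length(code)
  col <- integer(n); row <- integer(n)
  mat <- matrix(unlist(strsplit(code, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  for (l in seq_len(grid$depth)) {
    q <- match(mat[, l], level_block(l)) - 1L
    col <- col * 2L + q %% 2L
    row <- row * 2L + q %/% 2L
  }
  data.frame(col = col, row = row)
}

bad_char_position <- function(s, grid) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (length(ch) != grid$depth) return(sprintf("(length %d != depth %d)",
                                               length(ch), grid$depth))
  for (l in seq_along(ch)) if (!(ch[l] %in% level_block(l))) return(l)
  "?"
}

#' Validate quadrant codes
#'
#' Total function: returns `TRUE` iff the string has exactly `depth`
#' characters and each character lies in its level's 4-letter block.
#'
#' @param s Character vector of candidate codes.
#' @param grid A [grid_spec()].
#' @return Logical vector.
#' @export
validate_code <- function(s, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  pat <- paste0("^", paste(vapply(seq_len(grid$depth), function(l) {
    b <- level_block(l)
    sprintf("[%s-%s]", b[1L], b[4L])
  }, character(1L)), collapse = ""), "$")
  !is.na(s) & grepl(pat, s)
}

#' Map physical coordinates to grid cells
#'
#' Cells are half-open intervals `[k*s, (k+1)*s)` in both axes, so a point on
#' a cell boundary belongs to the higher-index cell.
#'
#' @param x_m,y_m Coordinates in meters from the lower-left corner, vectorised.
#' @param grid A [grid_spec()].
#' @return A data.frame with integer columns `col`, `row`.
#' @export
point_to_cell <- function(x_m, y_m, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(x_m < 0 | y_m < 0 |
          x_m >= grid$n_cols * grid$cell_size_m |
          y_m >= grid$n_rows * grid$cell_size_m))
    stop("point outside store bounds", call. = FALSE)
  data.frame(col = as.integer(floor(x_m / grid$cell_size_m)),
             row = as.integer(floor(y_m / grid$cell_size_m)))
}

#' Physical center of grid cells
#'
#' @param col,row Integer cell indices (0-based), vectorised.
#' @param grid A [grid_spec()].
#' @return A data.frame with columns `x_m`, `y_m`.
#' @export
cell_center <- function(col, row, grid) {
  data.frame(x_m = (col + 0.5) * grid$cell_size_m,
             y_m = (row + 0.5) * grid$cell_size_m)
}

#' Bounding box of the cells sharing a code prefix
#'
#' Codes sharing a length-`p` prefix fill an axis-aligned square of side
#' `2^(depth - p)` cells; this is the locality property of the hierarchical
#' encoding.
#'
#' @param prefix A code prefix of length 0..depth (valid for its length).
#' @param grid A [grid_spec()].
#' @return A list with `col_min`, `col_max`, `row_min`, `row_max` (0-based,
#'   inclusive) and `side` (cells per side).
#' @export
prefix_region <- function(prefix, grid) {
  stopifnot(inherits(grid, "grid_spec"), length(prefix) == 1L)
  ch <- if (nzchar(prefix)) strsplit(prefix, "", fixed = TRUE)[[1L]] else character(0)
  p <- length(ch)
  if (p > grid$depth)
    stop("prefix longer than code depth", call. = FALSE)
  col <- 0L; row <- 0L
  for (l in seq_len(p)) {
    q <- match(ch[l], level_block(l))
    if (is.na(q))
      stop(sprintf("invalid prefix '%s': character %d not in level block",
                   prefix, l), call. = FALSE)
    q <- q - 1L
    col <- col * 2L + q %% 2L
    row <- row * 2L + q %/% 2L
  }
  side <- as.integer(2^(grid$depth - p))
  list(col_min = col * side, col_max = (col + 1L) * side - 1L,
       row_min = row * side, row_max = (row + 1L) * side - 1L,
       side = side)
}
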