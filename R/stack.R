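# Raster container: a covariate stack is a set of named real-valued layers on
# a shared regular grid (projected metres, default 120 m cells), plus a boolean
# availability mask and a flag set of anthropogenic layer names. Matrices are
# indexed [row, col] with row 1 at the *bottom* edge (y increases with row).

#' Create a covariate stack
#'
#' @param origin numeric length 2, (xmin, ymin) of the grid in metres.
#' @param cell_size cell edge length in metres (default 120).
#' @param n_rows,n_cols grid dimensions.
#' @param layers named list of `n_rows x n_cols` numeric matrices.
#' @param anthropogenic character vector, subset of `names(layers)` flagged as
#'   development covariates (zeroed under the reference scenario).
#' @param mask logical `n_rows x n_cols` matrix, `TRUE` = available habitat.
#'   Defaults to all available.
#' @param crs free-text CRS tag (metadata only; all computation is planar).
#' @return object of class `covariate_stack`.
#' @export
covariate_stack <- function(origin, cell_size = 120, n_rows, n_cols,
                            layers = list(), anthropogenic = character(),
                            mask = NULL, crs = "local-metric") {
  stopifnot(length(origin) == 2, cell_size > 0, n_rows >= 1, n_cols >= 1)
  if (is.null(mask)) mask <- matrix(TRUE, n_rows, n_cols)
  x <- structure(
    list(origin = as.numeric(origin), cell_size = as.numeric(cell_size),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs = crs, layers = layers,
         anthropogenic = anthropogenic, mask = mask),
    class = "covariate_stack")
  validate_stack(x)
}

validate_stack <- function(x) {
  for (nm in names(x$layers)) {
    m <- x$layers[[nm]]
    if (!is.matrix(m) || nrow(m) != x$n_rows || ncol(m) != x$n_cols)
      stop("layer '", nm, "' does not match grid geometry", call. = FALSE)
    if (any(!is.finite(m[x$mask])))
      stop("layer '", nm, "' has non-finite values inside the mask", call. = FALSE)
  }
  if (!any(x$mask)) stop("availability mask has no available cells", call. = FALSE)
  if (!all(x$anthropogenic %in% names(x$layers)))
    stop("anthropogenic names not all present among layers", call. = FALSE)
  x
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat("<covariate_stack> ", x$n_rows, "x", x$n_cols, " cells of ",
      x$cell_size, " m (", x$crs, ")\n", sep = "")
  cat("  layers: ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  cat("  anthropogenic: ", paste(x$anthropogenic, collapse = ", "), "\n", sep = "")
  cat("  available: ", sum(x$mask), "/", length(x$mask), " cells\n", sep = "")
  invisible(x)
}

# Grid arithmetic ------------------------------------------------------------

#' Cell row/col of point coordinates
#'
#' @return integer matrix with columns `row`, `col`; `NA` outside the grid.
#' @keywords internal
cell_of <- function(stack, x, y) {
  col <- floor((x - stack$origin[1]) / stack$cell_size) + 1L
  row <- floor((y - stack$origin[2]) / stack$cell_size) + 1L
  bad <- col < 1L | col > stack$n_cols | row < 1L | row > stack$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates
#'
#' @return tibble with `row`, `col`, `x`, `y` for every cell (row-major over
#'   rows from the bottom).
#' @export
cell_centers <- function(stack) {
  g <- expand.grid(col = seq_len(stack$n_cols), row = seq_len(stack$n_rows))
  tibble::tibble(
    row = g$row, col = g$col,
    x = stack$origin[1] + (g$col - 0.5) * stack$cell_size,
    y = stack$origin[2] + (g$row - 0.5) * stack$cell_size)
}

#' Extract layer values at point locations
#'
#' @param stack a [covariate_stack()].
#' @param layer layer name.
#' @param x,y point coordinates in metres.
#' @return numeric vector, `NA` outside the grid.
#' @export
extract_layer <- function(stack, layer, x, y) {
  if (!layer %in% names(stack$layers))
    stop("no layer named '", layer, "'", call. = FALSE)
  rc <- cell_of(stack, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- stack$layers[[layer]][cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Is a point in available habitat?
#' @return logical vector; `FALSE` outside the grid.
#' @export
is_available <- function(stack, x, y) {
  rc <- cell_of(stack, x, y)
  out <- rep(FALSE, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- stack$mask[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Long-format view of a covariate stack
#'
#' One row per cell per layer, ready for ggplot2.
#'
#' @param x a `covariate_stack`.
#' @param ... unused.
#' @return tibble with `x`, `y`, `row`, `col`, `layer`, `value`, `available`.
#' @export
as_tibble.covariate_stack <- function(x, ...) {
  cc <- cell_centers(x)
  avail <- x$mask[cbind(cc$row, cc$col)]
  purrr::map_dfr(names(x$layers), function(nm) {
    dplyr::mutate(cc, layer = nm,
                  value = x$layers[[nm]][cbind(cc$row, cc$col)],
                  available = avail)
  })
}

# Plain-text raster I/O -------------------------------------------------------

#' Write a grid layer as an ESRI ASCII grid (.asc)
#'
#' Plain-text raster interchange: 6 header lines then rows from the top of the
#' grid. `NA` is written as -9999.
#'
#' @param stack a [covariate_stack()].
#' @param layer layer name, or `"mask"` for the availability mask (0/1).
#' @param path output file path.
#' @export
write_ascii_grid <- function(stack, layer, path) {
  m <- if (identical(layer, "mask")) stack$mask * 1 else stack$layers[[layer]]
  if (is.null(m)) stop("no layer named '", layer, "'", call. = FALSE)
  hdr <- c(
    paste("ncols", stack$n_cols), paste("nrows", stack$n_rows),
    paste("xllcorner", stack$origin[1]), paste("yllcorner", stack$origin[2]),
    paste("cellsize", stack$cell_size), "NODATA_value -9999")
  m[is.na(m)] <- -9999
  body <- apply(m[stack$n_rows:1, , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path file path.
#' @return list with `origin`, `cell_size`, and the value `matrix` (row 1 at
#'   the bottom edge, -9999 mapped back to `NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  vals <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                          vapply(hdr, function(h) tolower(h[1]), ""))
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  m[m == vals[["nodata_value"]]] <- NA
  list(origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
       cell_size = vals[["cellsize"]], matrix = m)
}
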