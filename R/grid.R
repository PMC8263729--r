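#' Categorical land-use grid
#'
#' A minimal raster container: an integer matrix of land-use codes plus the
#' cell size in metres and the class dictionary. Row 1 is the northern edge;
#' cell centres are at ((col - 0.5) * cell_size, (nrow - row + 0.5) *
#' cell_size) in projected metres.
#'
#' @param values integer matrix of class codes (NA = nodata).
#' @param cell_size cell edge length in metres.
#' @param classes class dictionary; codes in `values` must appear in it.
#' @return An object of class `land_grid`.
#' @export
land_grid <- function(values, cell_size = 30, classes = habitat_classes()) {
  stopifnot(is.matrix(values), is.numeric(cell_size), cell_size > 0)
  storage.mode(values) <- "integer"
  bad <- setdiff(unique(values[!is.na(values)]), classes$code)
  if (length(bad) > 0)
    stop("unknown land-use codes in grid: ", paste(sort(bad), collapse = ", "))
  structure(list(values = values, cell_size = cell_size, classes = classes),
            class = "land_grid")
}

#' @export
as.matrix.land_grid <- function(x, ...) x$values

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("land_grid: %d x %d cells at %g m (%.2f km^2)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              sum(!is.na(x$values)) * cell_area_km2(x$cell_size)))
  tab <- table(factor(x$values, levels = x$classes$code,
                      labels = x$classes$name))
  tab <- tab[tab > 0]
  print(round(100 * tab / sum(tab), 2))
  invisible(x)
}

#' @export
plot.land_grid <- function(x, ...) {
  graphics::image(t(x$values[nrow(x$values):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(14, "Spectral"),
                  axes = FALSE, ...)
  invisible(x)
}

#' @export
dim.land_grid <- function(x) dim(x$values)

cell_area_km2 <- function(cell_size) (cell_size / 1000)^2

#' Total valid area of a grid in km^2
#' @param grid a `land_grid` or plain matrix.
#' @param cell_size cell size in metres (taken from the grid if a `land_grid`).
#' @export
grid_area_km2 <- function(grid, cell_size = NULL) {
  m <- grid_values(grid)
  cs <- if (inherits(grid, "land_grid")) grid$cell_size else cell_size
  stopifnot(!is.null(cs))
  sum(!is.na(m)) * cell_area_km2(cs)
}

# accept either a land_grid-like object or a bare matrix
grid_values <- function(x) {
  if (is.matrix(x)) x
  else if (is.list(x) && is.matrix(x$values)) x$values
  else stop("expected a matrix or a grid object with a $values matrix")
}

# Zero-padded linear convolution of matrix x with a centred odd-sized kernel,
# via FFT. Exact up to floating-point roundoff (~1e-13 for O(1) values).
conv2d <- function(x, kernel) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- stats::nextn(nr + kr - 1L, 2L)
  pc <- stats::nextn(nc + kc - 1L, 2L)
  X <- matrix(0, pr, pc); X[seq_len(nr), seq_len(nc)] <- x
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- kernel
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  r0 <- (kr + 1L) %/% 2L
  c0 <- (kc + 1L) %/% 2L
  full[r0:(r0 + nr - 1L), c0:(c0 + nc - 1L)]
}

# Gaussian smoothing of a matrix, kernel-normalized over in-bounds cells so a
# constant input stays constant (used by the synthetic generators).
smooth_field <- function(x, sigma_cells) {
  if (sigma_cells <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma_cells))
  off <- (-r):r
  k <- exp(-outer(off^2, off^2, "+") / (2 * sigma_cells^2))
  num <- conv2d(x, k)
  den <- conv2d(matrix(1, nrow(x), ncol(x)), k)
  num / den
}

#' Block-resample a grid between resolutions
#'
#' Aggregates (or replicates) a matrix by an integer factor: `"mean"` block
#' averaging for continuous surfaces when coarsening, `"nearest"` for
#' categorical surfaces, and nearest/replication when refining. Emulates
#' harmonizing mixed-resolution inputs onto a common analysis grid.
#'
#' @param x numeric matrix.
#' @param factor integer > 0; `coarsen = TRUE` aggregates factor x factor
#'   blocks, otherwise each cell is replicated factor times.
#' @param method "mean" or "nearest" (block centre) when coarsening.
#' @param coarsen logical.
#' @return resampled matrix.
#' @export
resample_grid <- function(x, factor, method = c("mean", "nearest"),
                          coarsen = TRUE) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), factor >= 1, factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  if (!coarsen) {
    return(x[rep(seq_len(nrow(x)), each = factor),
             rep(seq_len(ncol(x)), each = factor), drop = FALSE])
  }
  nr <- (nrow(x) %/% factor) * factor
  nc <- (ncol(x) %/% factor) * factor
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  if (method == "nearest") {
    mid <- (factor + 1L) %/% 2L
    return(x[seq(mid, nr, by = factor), seq(mid, nc, by = factor),
             drop = FALSE])
  }
  ri <- (seq_len(nr) - 1L) %/% factor
  ci <- (seq_len(nc) - 1L) %/% factor
  acc <- rowsum(t(rowsum(x, ri)), ci)
  out <- t(acc) / factor^2
  dimnames(out) <- NULL
  out
}

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster export (`.asc`): portable, diffable, and readable by all
#' standard GIS stacks.
#'
#' @param x numeric/integer matrix (row 1 = north) or a `land_grid`.
#' @param path output file path.
#' @param cell_size cell size in metres (from the grid if a `land_grid`).
#' @param xllcorner,yllcorner lower-left corner coordinates, metres.
#' @param nodata nodata sentinel written for NA cells.
#' @export
write_asc <- function(x, path, cell_size = NULL, xllcorner = 0, yllcorner = 0,
                      nodata = -9999) {
  m <- grid_values(x)
  if (inherits(x, "land_grid")) cell_size <- x$cell_size
  stopifnot(!is.null(cell_size))
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.6f", xllcorner),
           sprintf("yllcorner %.6f", yllcorner),
           sprintf("cellsize %.6f", cell_size),
           sprintf("NODATA_value %g", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @return list with `values` (matrix, NA for nodata), `cell_size`,
#'   `xllcorner`, `yllcorner`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  nodata <- val("NODATA_value")
  body <- strsplit(trimws(lines[-(1:6)]), "[[:space:]]+")
  m <- matrix(as.numeric(unlist(body)), nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  list(values = m, cell_size = val("cellsize"),
       xllcorner = val("xllcorner"), yllcorner = val("yllcorner"))
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}
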