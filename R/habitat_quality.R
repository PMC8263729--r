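#' Distance-decay factor of a threat
#'
#' Interference intensity of a threat source at straight-line distance `d`:
#' linear attenuation `1 - d / d_rmax` or exponential decay
#' `exp(-2.99 d / d_rmax)`, truncated to exactly 0 beyond the maximum threat
#' distance.
#'
#' @param d distance(s) in km, >= 0.
#' @param d_rmax maximum threat distance in km, > 0.
#' @param decay `"linear"` or `"exponential"`.
#' @return numeric in [0, 1], vectorized over `d`.
#' @export
decay_factor <- function(d, d_rmax, decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  stopifnot(length(d_rmax) == 1, d_rmax > 0)
  if (any(d < 0)) stop("negative distance")
  out <- if (decay == "linear") 1 - d / d_rmax else exp(-2.99 * d / d_rmax)
  out[d > d_rmax] <- 0
  pmax(out, 0)
}

#' Binary threat-source presence grid
#'
#' Cells whose land-use code belongs to the threat's source set are 1, all
#' others 0 (the standard raster coding of threat-source maps).
#'
#' @param lulc a [land_grid()].
#' @param source_codes integer codes emitting the threat.
#' @return numeric 0/1 matrix (NA where the land grid is nodata).
#' @export
threat_presence <- function(lulc, source_codes) {
  v <- grid_values(lulc)
  known <- if (inherits(lulc, "land_grid")) lulc$classes$code else unique(v)
  unknown <- setdiff(source_codes, known)
  if (length(unknown) > 0)
    warning("source codes not in class dictionary treated as absent: ",
            paste(unknown, collapse = ", "))
  out <- matrix(as.numeric(v %in% source_codes), nrow(v), ncol(v))
  out[is.na(v)] <- NA_real_
  out
}

# Decay kernel over integer cell offsets within d_rmax (km); the kernel is
# clipped to the grid extent since farther offsets can never contribute.
threat_kernel <- function(d_rmax_km, decay, cell_size, nr, nc) {
  r <- floor(d_rmax_km * 1000 / cell_size)
  r <- min(r, max(nr, nc) - 1L)
  r <- max(r, 0L)
  off <- (-r):r
  dk <- sqrt(outer(off^2, off^2, "+")) * cell_size / 1000
  k <- decay_factor(as.vector(dk), d_rmax_km, decay)
  matrix(k, length(off), length(off))
}

#' Kernel density of one threat around every cell
#'
#' Distance-decayed, kernel-normalized exposure to a threat: at each cell the
#' decayed sum of presence over all in-range cells, divided by the decayed sum
#' over all in-bounds cells of the kernel. Equals 1 where everything within
#' `d_rmax` is a source and 0 where nothing is. Set `normalize = FALSE` for
#' the raw decayed sum.
#'
#' @param presence 0/1 matrix from [threat_presence()] (NA allowed).
#' @param d_rmax_km maximum threat distance, km.
#' @param decay decay law, see [decay_factor()].
#' @param cell_size cell size in metres.
#' @param normalize divide by the in-bounds kernel mass (default TRUE).
#' @return numeric matrix in [0, 1] (unbounded if `normalize = FALSE`).
#' @export
threat_density <- function(presence, d_rmax_km, decay, cell_size,
                           normalize = TRUE) {
  stopifnot(is.matrix(presence))
  nr <- nrow(presence); nc <- ncol(presence)
  na_mask <- is.na(presence)
  p <- presence
  p[na_mask] <- 0
  k <- threat_kernel(d_rmax_km, decay, cell_size, nr, nc)
  num <- conv2d(p, k)
  if (!normalize) {
    num[num < 0] <- 0
    num[na_mask] <- NA_real_
    return(num)
  }
  valid <- matrix(1, nr, nc)
  valid[na_mask] <- 0
  den <- conv2d(valid, k)
  out <- ifelse(den > 0, num / den, 0)
  out <- pmin(pmax(out, 0), 1)
  out[na_mask] <- NA_real_
  out
}

#' Habitat degradation surface
#'
#' Weighted, distance-decayed aggregate threat exposure per cell:
#' `D(x) = sum_r (w_r / sum w_r) * density_r(x) * beta(x) * S[j(x), r]`
#' where `j(x)` is the habitat class at `x`. With kernel-normalized densities,
#' sensitivities and accessibility in [0, 1] and normalized weights, D is
#' guaranteed to lie in [0, 1].
#'
#' @param lulc a [land_grid()].
#' @param threats threat parameter table, default [threat_table()].
#' @param sens sensitivity table, default [sensitivity_table()].
#' @param accessibility optional matrix of accessibility multipliers in
#'   [0, 1]; default 1 everywhere.
#' @param normalize kernel-normalize threat densities (default TRUE).
#' @return An object of class `degradation_surface`: list with `values`
#'   (matrix D), `cell_size`, `threats`, `normalized`.
#' @export
compute_degradation <- function(lulc, threats = threat_table(),
                                sens = sensitivity_table(),
                                accessibility = NULL, normalize = TRUE) {
  stopifnot(inherits(lulc, "land_grid"))
  if (all(threats$weight == 0)) stop("threat weights must not all be zero")
  v <- lulc$values
  nr <- nrow(v); nc <- ncol(v)
  if (is.null(accessibility)) accessibility <- matrix(1, nr, nc)
  stopifnot(identical(dim(accessibility), dim(v)))

  codes_seen <- unique(v[!is.na(v)])
  silent <- lulc$classes$code[!lulc$classes$habitat]
  missing <- setdiff(codes_seen, c(sens$code, silent))
  if (length(missing) > 0)
    warning("habitat classes missing from sensitivity table get S = 0: ",
            paste(sort(missing), collapse = ", "))

  w <- threats$weight / sum(threats$weight)
  D <- matrix(0, nr, nc)
  max_code <- max(c(v, sens$code, silent), na.rm = TRUE)
  for (r in seq_len(nrow(threats))) {
    pres <- threat_presence(lulc, threats$source_codes[[r]])
    dens <- threat_density(pres, threats$d_rmax_km[r], threats$decay[r],
                           lulc$cell_size, normalize = normalize)
    s_lookup <- numeric(max_code)
    s_lookup[sens$code] <- sens[[threats$threat[r]]]
    S <- matrix(0, nr, nc)
    ok <- !is.na(v)
    S[ok] <- s_lookup[v[ok]]
    D <- D + w[r] * dens * S
  }
  D <- D * accessibility
  D[is.na(v)] <- NA_real_
  structure(list(values = D, cell_size = lulc$cell_size, threats = threats,
                 normalized = normalize),
            class = "degradation_surface")
}

#' @export
print.degradation_surface <- function(x, ...) {
  cat(sprintf("degradation_surface: %d x %d, mean D = %.4f (range %.4f-%.4f)\n",
              nrow(x$values), ncol(x$values),
              mean(x$values, na.rm = TRUE), min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Habitat quality surface
#'
#' Half-saturation quality model: `Q(x) = H_j * (1 - D^2 / (D^2 + k^2))` with
#' `j` the habitat class at `x`. Quality equals the class suitability where
#' degradation is zero and half of it where `D = k`.
#'
#' @param degradation a `degradation_surface` from [compute_degradation()].
#' @param lulc the [land_grid()] the degradation was computed on.
#' @param sens sensitivity table supplying per-class suitability `H`.
#' @param k half-saturation constant, > 0 (default 0.5).
#' @return An object of class `quality_surface`: list with `values` (matrix
#'   Q), `cell_size`, `k`.
#' @export
compute_quality <- function(degradation, lulc, sens = sensitivity_table(),
                            k = 0.5) {
  stopifnot(inherits(degradation, "degradation_surface"),
            inherits(lulc, "land_grid"), k > 0)
  v <- lulc$values
  D <- degradation$values
  stopifnot(identical(dim(D), dim(v)))
  max_code <- max(c(v, sens$code), na.rm = TRUE)
  h_lookup <- numeric(max_code)
  h_lookup[sens$code] <- sens$H
  H <- matrix(0, nrow(v), ncol(v))
  ok <- !is.na(v)
  H[ok] <- h_lookup[v[ok]]
  Q <- H * (1 - D^2 / (D^2 + k^2))
  Q[is.na(v)] <- NA_real_
  structure(list(values = Q, cell_size = lulc$cell_size, k = k),
            class = "quality_surface")
}

#' @export
print.quality_surface <- function(x, ...) {
  cat(sprintf("quality_surface: %d x %d, mean Q = %.4f (k = %g)\n",
              nrow(x$values), ncol(x$values),
              mean(x$values, na.rm = TRUE), x$k))
  invisible(x)
}

#' @export
plot.quality_surface <- function(x, ...) {
  graphics::image(t(x$values[nrow(x$values):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "Greens", rev = TRUE),
                  zlim = c(0, 1), axes = FALSE, ...)
  invisible(x)
}

#' Five-level habitat quality grading
#'
#' Grades quality into I [0, 0.2), II [0.2, 0.4), III [0.4, 0.6),
#' IV [0.6, 0.8), V [0.8, 1].
#'
#' @param quality a `quality_surface` or a numeric matrix/vector in [0, 1].
#' @return integer grades 1..5 (same shape as input), NA propagated.
#' @export
grade_quality <- function(quality) {
  q <- if (inherits(quality, "quality_surface")) quality$values
       else quality
  rng <- range(q, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("quality values outside [0, 1]")
  q <- pmin(pmax(q, 0), 1)
  g <- findInterval(q, c(0.2, 0.4, 0.6, 0.8)) + 1L
  if (is.matrix(q)) g <- matrix(g, nrow(q), ncol(q))
  g
}
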