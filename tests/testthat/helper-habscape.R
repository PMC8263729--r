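# Independent brute-force oracle for the degradation model: enumerates every
# (cell, source-cell) pair through an explicit pairwise distance matrix --
# no convolution, no kernels over offsets. Only feasible on small grids.
oracle_decay <- function(d, d_rmax, decay) {
  out <- if (decay == "linear") 1 - d / d_rmax else exp(-2.99 * d / d_rmax)
  out[d > d_rmax] <- 0
  pmax(out, 0)
}

oracle_pairwise_km <- function(nr, nc, cell_size) {
  rows <- as.vector(row(matrix(0, nr, nc)))
  cols <- as.vector(col(matrix(0, nr, nc)))
  sqrt(outer(rows, rows, "-")^2 + outer(cols, cols, "-")^2) * cell_size / 1000
}

oracle_density <- function(presence, d_rmax_km, decay, cell_size,
                           pair_km = NULL) {
  nr <- nrow(presence); nc <- ncol(presence)
  if (is.null(pair_km)) pair_km <- oracle_pairwise_km(nr, nc, cell_size)
  K <- oracle_decay(pair_km, d_rmax_km, decay)
  num <- K %*% as.vector(presence)
  den <- K %*% rep(1, nr * nc)
  matrix(as.vector(num / den), nr, nc)
}

oracle_degradation <- function(lulc, threats = threat_table(),
                               sens = sensitivity_table(), pair_km = NULL,
                               kernels = NULL) {
  v <- lulc$values
  nr <- nrow(v); nc <- ncol(v)
  if (is.null(pair_km)) pair_km <- oracle_pairwise_km(nr, nc, lulc$cell_size)
  w <- threats$weight / sum(threats$weight)
  D <- numeric(nr * nc)
  ones <- rep(1, nr * nc)
  for (r in seq_len(nrow(threats))) {
    K <- if (is.null(kernels)) {
      oracle_decay(pair_km, threats$d_rmax_km[r], threats$decay[r])
    } else kernels[[r]]
    pres <- as.numeric(as.vector(v) %in% threats$source_codes[[r]])
    dens <- as.vector((K %*% pres) / (K %*% ones))
    s_lookup <- numeric(max(c(v, sens$code), na.rm = TRUE))
    s_lookup[sens$code] <- sens[[threats$threat[r]]]
    S <- numeric(nr * nc)
    ok <- !is.na(as.vector(v))
    S[ok] <- s_lookup[as.vector(v)[ok]]
    D <- D + w[r] * dens * S
  }
  matrix(D, nr, nc)
}

# quality surface wrapper for hand-built degradation grids
make_degradation <- function(values, cell_size = 30) {
  structure(list(values = values, cell_size = cell_size,
                 threats = NULL, normalized = TRUE),
            class = "degradation_surface")
}

make_quality <- function(values, cell_size = 30, k = 0.5) {
  structure(list(values = values, cell_size = cell_size, k = k),
            class = "quality_surface")
}

# uniform single-class grid
uniform_grid <- function(code, nr = 8, nc = 8, cell_size = 30) {
  land_grid(matrix(as.integer(code), nr, nc), cell_size = cell_size)
}

# four well-separated Gaussian clusters in 4-d standardized indicator space,
# with strictly ordered per-cluster SUM levels
planted_clusters <- function(n = 400, seed = 1, sd = 0.05) {
  centers <- matrix(c(0.90, 0.90, 0.90, 0.90,
                      0.65, 0.65, 0.65, 0.65,
                      0.35, 0.35, 0.35, 0.35,
                      0.10, 0.10, 0.10, 0.10), 4, 4, byrow = TRUE)
  set.seed(seed)
  cl <- rep(1:4, length.out = n)
  X <- centers[cl, ] + matrix(rnorm(4 * n, 0, sd), n, 4)
  colnames(X) <- c("q_std", "ntl_std", "pop_std", "lur_std")
  list(X = X, cluster = cl,
       table = data.frame(X, sum_std = rowSums(X)))
}

# connected-component count of a logical mask under 4-connectivity
n_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      cell <- queue[[1]]; queue <- queue[-1]
      r <- (cell - 1L) %% nr + 1L; c <- (cell - 1L) %/% nr + 1L
      for (d in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
        if (d[1] >= 1 && d[1] <= nr && d[2] >= 1 && d[2] <= nc) {
          j <- (d[2] - 1L) * nr + d[1]
          if (mask[j] && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
        }
      }
    }
  }
  cur
}
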