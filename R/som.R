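#' Train a Kohonen self-organizing feature map
#'
#' Classic online SOM: per sample, the best-matching unit (BMU, Euclidean
#' distance) and its Gaussian grid neighbourhood move toward the sample; the
#' learning rate and neighbourhood radius decay exponentially between their
#' initial and final values over the epochs. Weights are initialized from
#' seeded random data rows, so training is a pure function of the seed.
#'
#' @param data numeric matrix, one row per sample (standardized indicators).
#' @param grid_shape c(rows, cols) of the neuron grid; default 2 x 2 so the
#'   four neurons are the four zones directly.
#' @param epochs training epochs (full passes over the data).
#' @param lr c(initial, final) learning rate.
#' @param radius c(initial, final) neighbourhood radius in grid units.
#' @param seed integer RNG seed.
#' @return object of class `som_model`: `weights` (neurons x dims),
#'   `grid_coords`, `grid_shape`, `qe` (per-epoch mean quantization error),
#'   schedule and seed.
#' @export
train_som <- function(data, grid_shape = c(2, 2), epochs = 500,
                      lr = c(0.5, 0.01), radius = c(1, 0.1), seed = 1) {
  data <- as.matrix(data)
  if (nrow(data) == 0) stop("empty data")
  if (any(!is.finite(data))) stop("non-finite values in data")
  m <- prod(grid_shape)
  if (nrow(data) < m) stop("need at least as many samples as neurons")
  stopifnot(epochs >= 1, all(lr > 0), lr[1] >= lr[2],
            all(radius > 0), radius[1] >= radius[2])
  n <- nrow(data); d <- ncol(data)
  gc_ <- as.matrix(expand.grid(row = seq_len(grid_shape[1]),
                               col = seq_len(grid_shape[2])))
  # squared grid distances between neurons
  gd2 <- as.matrix(stats::dist(gc_))^2
  with_seed(seed, {
    tW <- t(data[sample.int(n, m), , drop = FALSE])  # d x m, column = neuron
    tdata <- t(data)
    qe <- numeric(epochs)
    denom <- max(epochs - 1, 1)
    for (e in seq_len(epochs)) {
      alpha <- lr[1] * (lr[2] / lr[1])^((e - 1) / denom)
      sigma <- radius[1] * (radius[2] / radius[1])^((e - 1) / denom)
      h_all <- alpha * exp(-gd2 / (2 * sigma^2))  # m x m: row = BMU
      ord <- sample.int(n)
      qsum <- 0
      for (s in ord) {
        dt <- tW - tdata[, s]           # column-wise recycling over neurons
        d2 <- .colSums(dt * dt, d, m)
        bmu <- which.min(d2)
        qsum <- qsum + sqrt(d2[bmu])
        tW <- tW - dt * rep(h_all[bmu, ], each = d)
      }
      qe[e] <- qsum / n
    }
    W <- t(tW)
    structure(list(weights = W, grid_coords = gc_, grid_shape = grid_shape,
                   qe = qe, epochs = epochs, lr = lr, radius = radius,
                   seed = seed, dim = d),
              class = "som_model")
  })
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf(
    "som_model: %d x %d map, %d-d inputs, %d epochs, final QE = %.4f\n",
    x$grid_shape[1], x$grid_shape[2], x$dim, x$epochs,
    x$qe[length(x$qe)]))
  invisible(x)
}

#' Best-matching unit for new samples
#'
#' @param object a `som_model`.
#' @param newdata matrix with the model's input dimension.
#' @param ... unused.
#' @return integer vector of neuron indices.
#' @export
predict.som_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$dim)
  W <- object$weights
  d2 <- outer(rowSums(newdata^2), rep(1, nrow(W))) -
    2 * newdata %*% t(W) +
    outer(rep(1, nrow(newdata)), rowSums(W^2))
  apply(d2, 1, which.min)
}

#' Assign basins to green-development zones
#'
#' Maps each basin to its BMU on the trained map and relabels the non-empty
#' neurons A, B, C, ... by descending mean member `sum_std` (joint
#' standardized development level), so zone A is always the
#' highest-development group regardless of neuron indexing.
#'
#' @param som a trained `som_model`.
#' @param table a standardized basin table (see [standardize_indicators()])
#'   containing `cols` and `sum_std`.
#' @param cols indicator columns the map was trained on.
#' @return list with `zone` (factor per basin), `neuron` (BMU index),
#'   `summary` (per-zone mean indicators, SUM and size) and `empty_neurons`.
#'   Fewer non-empty neurons than map cells is flagged with a warning.
#' @export
assign_zones <- function(som, table,
                         cols = c("q_std", "ntl_std", "pop_std", "lur_std")) {
  stopifnot(inherits(som, "som_model"), all(cols %in% names(table)),
            "sum_std" %in% names(table))
  X <- as.matrix(table[, cols])
  bmu <- predict(som, X)
  m <- nrow(som$weights)
  occupied <- sort(unique(bmu))
  empty <- setdiff(seq_len(m), occupied)
  if (length(occupied) < m)
    warning("degenerate zoning: ", length(empty), " empty neuron(s)")
  mean_sum <- vapply(occupied, function(j) mean(table$sum_std[bmu == j]),
                     numeric(1))
  ord <- occupied[order(-mean_sum)]
  zone_of_neuron <- stats::setNames(LETTERS[seq_along(ord)], ord)
  zone <- factor(zone_of_neuron[as.character(bmu)],
                 levels = LETTERS[seq_along(ord)])
  summ <- do.call(rbind, lapply(seq_along(ord), function(k) {
    sel <- bmu == ord[k]
    data.frame(zone = LETTERS[k], neuron = ord[k], n = sum(sel),
               t(colMeans(table[sel, c(cols, "sum_std"), drop = FALSE])),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(zone = zone, neuron = bmu, summary = summ, empty_neurons = empty)
}
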