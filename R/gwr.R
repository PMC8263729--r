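# Small-sample corrected AIC used for both global and local models, based on
# the effective number of parameters (hat-matrix trace), so OLS and GWR fits
# are compared on the same criterion.
aicc_from_hat <- function(n, rss, tr_s) {
  if (n - 2 - tr_s <= 0) return(Inf)
  2 * n * log(sqrt(rss / n)) + n * log(2 * pi) +
    n * (n + tr_s) / (n - 2 - tr_s)
}

# Validate and assemble a regression design: response, predictor matrix with
# intercept column, coordinates in metres.
build_design <- function(y, x, coords) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  coords <- as.matrix(coords)
  stopifnot(length(y) == nrow(x), nrow(coords) == length(y),
            ncol(coords) == 2)
  if (any(!is.finite(y)) || any(!is.finite(x)) || any(!is.finite(coords)))
    stop("design contains missing or non-finite values")
  if (length(y) < ncol(x) + 2)
    stop("need at least k + 2 observations")
  list(y = as.numeric(y), X = cbind(`(Intercept)` = 1, x), coords = coords)
}

#' Ordinary least squares fit
#'
#' QR-based least squares with residual standard error
#' `sigma = sqrt(RSS / (n - p))`, R-squared, and the small-sample corrected
#' AICc on the hat-trace form (trace = p for OLS) so it is directly
#' comparable with [gwr_fit()].
#'
#' @param y numeric response.
#' @param x predictor matrix (no intercept column; one is added).
#' @param coords optional n x 2 coordinates, kept for later GWR comparison.
#' @return object of class `hq_ols` with coefficients, fitted values,
#'   residuals, `sigma`, `r_squared`, `aicc`.
#' @export
ols_fit <- function(y, x, coords = NULL) {
  if (is.null(coords)) coords <- matrix(0, length(y), 2)
  d <- build_design(y, x, coords)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) stop("rank-deficient design")
  beta <- qr.coef(qrX, d$y)
  fitted <- drop(d$X %*% beta)
  res <- d$y - fitted
  n <- length(d$y); p <- ncol(d$X)
  rss <- sum(res^2)
  tss <- sum((d$y - mean(d$y))^2)
  structure(list(coefficients = beta, fitted = fitted, residuals = res,
                 sigma = sqrt(rss / (n - p)),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 aicc = aicc_from_hat(n, rss, p),
                 n = n, p = p, design = d),
            class = "hq_ols")
}

#' @export
print.hq_ols <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R^2 = %.4f, sigma = %.4f, AICc = %.2f\n",
              x$n, x$r_squared, x$sigma, x$aicc))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.hq_ols <- function(object, ...) object$coefficients

#' @export
residuals.hq_ols <- function(object, ...) object$residuals

#' @export
predict.hq_ols <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  drop(cbind(1, as.matrix(newdata)) %*% object$coefficients)
}

gwr_weights <- function(dists, bandwidth, kernel, adaptive) {
  if (kernel == "uniform") return(rep(1, length(dists)))
  if (adaptive) {
    k <- max(2L, round(bandwidth))
    bw <- sort(dists)[min(k, length(dists))]
  } else bw <- bandwidth
  if (kernel == "gaussian") {
    exp(-0.5 * (dists / bw)^2)
  } else {  # bisquare
    w <- (1 - (dists / bw)^2)^2
    w[dists >= bw] <- 0
    w
  }
}

#' Geographically weighted regression
#'
#' At every location i, a weighted least-squares regression with kernel
#' weights on the distances from i yields local coefficients; the hat-matrix
#' trace gives the effective number of parameters for the AICc. With the
#' `"uniform"` kernel every local fit reproduces OLS exactly.
#'
#' @param y numeric response (e.g. basin mean habitat quality).
#' @param x predictor matrix (no intercept column).
#' @param coords n x 2 matrix of projected coordinates, metres.
#' @param bandwidth kernel bandwidth in metres (or neighbour count when
#'   `adaptive = TRUE`).
#' @param kernel "gaussian" (default), "bisquare" or "uniform".
#' @param adaptive use a k-nearest-neighbour adaptive bandwidth (bisquare).
#' @return object of class `hq_gwr`: matrix of local `coefficients` (one row
#'   per location), `local_r2`, `fitted`, `residuals`, `sigma`, `aicc`,
#'   `tr_s` (hat trace), `bandwidth`, `kernel`.
#' @export
gwr_fit <- function(y, x, coords, bandwidth,
                    kernel = c("gaussian", "bisquare", "uniform"),
                    adaptive = FALSE) {
  kernel <- match.arg(kernel)
  if (kernel != "uniform" && bandwidth <= 0) stop("bandwidth must be > 0")
  d <- build_design(y, x, coords)
  n <- length(d$y); p <- ncol(d$X)
  dx <- outer(d$coords[, 1], d$coords[, 1], "-")
  dy <- outer(d$coords[, 2], d$coords[, 2], "-")
  dists <- sqrt(dx^2 + dy^2)
  beta <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(d$X)))
  fitted <- numeric(n); hat_ii <- numeric(n); local_r2 <- numeric(n)
  for (i in seq_len(n)) {
    w <- gwr_weights(dists[i, ], bandwidth, kernel, adaptive)
    Xw <- d$X * w
    XtWX <- crossprod(d$X, Xw)
    XtWy <- crossprod(Xw, d$y)
    A <- tryCatch(solve(XtWX, cbind(XtWy, t(Xw))),
                  error = function(e)
                    stop("local fit rank-deficient at unit ", i,
                         " (bandwidth too small)", call. = FALSE))
    beta[i, ] <- A[, 1]
    fitted[i] <- sum(d$X[i, ] * beta[i, ])
    hat_ii[i] <- sum(d$X[i, ] * A[, i + 1])
    yw_bar <- sum(w * d$y) / sum(w)
    pred_all <- drop(d$X %*% beta[i, ])
    wrss <- sum(w * (d$y - pred_all)^2)
    wtss <- sum(w * (d$y - yw_bar)^2)
    local_r2[i] <- if (wtss > 0) 1 - wrss / wtss else NA_real_
  }
  res <- d$y - fitted
  rss <- sum(res^2)
  tr_s <- sum(hat_ii)
  structure(list(coefficients = beta, local_r2 = local_r2, fitted = fitted,
                 residuals = res,
                 sigma = sqrt(rss / max(n - tr_s, .Machine$double.eps)),
                 aicc = aicc_from_hat(n, rss, tr_s), tr_s = tr_s,
                 bandwidth = bandwidth, kernel = kernel,
                 adaptive = adaptive, n = n, p = p, design = d),
            class = "hq_gwr")
}

#' @export
print.hq_gwr <- function(x, ...) {
  cat(sprintf(
    "GWR fit: n = %d, %s kernel, bandwidth = %g, eff. params = %.2f\n",
    x$n, x$kernel, x$bandwidth, x$tr_s))
  cat(sprintf("  sigma = %.4f, AICc = %.2f, median local R^2 = %.4f\n",
              x$sigma, x$aicc, stats::median(x$local_r2, na.rm = TRUE)))
  cat("local coefficient quartiles:\n")
  print(apply(x$coefficients, 2, stats::quantile,
              probs = c(0.25, 0.5, 0.75)))
  invisible(x)
}

#' @export
coef.hq_gwr <- function(object, ...) object$coefficients

#' @export
residuals.hq_gwr <- function(object, ...) object$residuals

#' @export
summary.hq_gwr <- function(object, ...) {
  out <- list(n = object$n, kernel = object$kernel,
              bandwidth = object$bandwidth, tr_s = object$tr_s,
              sigma = object$sigma, aicc = object$aicc,
              coef_summary = apply(object$coefficients, 2, summary),
              local_r2_summary = summary(object$local_r2))
  class(out) <- "summary.hq_gwr"
  out
}

#' @export
print.summary.hq_gwr <- function(x, ...) {
  cat(sprintf("GWR summary (n = %d, %s kernel, bw = %g)\n",
              x$n, x$kernel, x$bandwidth))
  print(x$coef_summary)
  invisible(x)
}

#' AICc-minimizing bandwidth by golden-section search
#'
#' Deterministic golden-section search for the fixed bandwidth minimizing the
#' GWR AICc over `[lower, upper]` (defaults: 1% to 2x the coordinate extent).
#' A monotone criterion returns the corresponding boundary.
#'
#' @param y,x,coords as in [gwr_fit()].
#' @param kernel kernel name.
#' @param lower,upper search interval in metres.
#' @param tol relative convergence tolerance.
#' @return list with `bandwidth` and `aicc`.
#' @export
select_bandwidth <- function(y, x, coords, kernel = "gaussian",
                             lower = NULL, upper = NULL, tol = 1e-3) {
  coords <- as.matrix(coords)
  if (length(y) < 10) stop("bandwidth selection needs >= 10 units")
  extent <- sqrt(diff(range(coords[, 1]))^2 + diff(range(coords[, 2]))^2)
  if (is.null(lower)) lower <- 0.01 * extent
  if (is.null(upper)) upper <- 2 * extent
  crit <- function(bw) {
    fit <- tryCatch(gwr_fit(y, x, coords, bw, kernel = kernel),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$aicc)) Inf else fit$aicc
  }
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- crit(c1); f2 <- crit(c2)
  while ((b - a) > tol * upper) {
    if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- crit(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- crit(c2)
    }
  }
  bw <- (a + b) / 2
  fa <- crit(bw)
  if (!is.finite(fa) && !is.finite(f1) && !is.finite(f2))
    stop("AICc non-finite over the whole bandwidth range")
  list(bandwidth = bw, aicc = fa)
}

#' Compare an OLS and a GWR fit
#'
#' Reports AICc and sigma differences (GWR minus OLS); GWR is preferred only
#' when both are lower, OLS when both are higher, otherwise the comparison is
#' flagged ambiguous.
#'
#' @param ols an `hq_ols` fit.
#' @param gwr an `hq_gwr` fit on the same design.
#' @return list with `delta_aicc`, `delta_sigma`, `preferred`
#'   ("GWR"/"OLS"/"ambiguous").
#' @export
compare_models <- function(ols, gwr) {
  stopifnot(inherits(ols, "hq_ols"), inherits(gwr, "hq_gwr"),
            ols$n == gwr$n)
  da <- gwr$aicc - ols$aicc
  ds <- gwr$sigma - ols$sigma
  # numerically indistinguishable fits are a tie, not a preference
  ea <- 1e-8 * max(1, abs(ols$aicc))
  es <- 1e-8 * max(1, abs(ols$sigma))
  preferred <- if (da < -ea && ds < -es) "GWR"
    else if (da > ea && ds > es) "OLS"
    else "ambiguous"
  list(delta_aicc = da, delta_sigma = ds, preferred = preferred)
}

#' Sign classes of local GWR coefficients
#'
#' @param gwr an `hq_gwr` fit.
#' @param predictor predictor column name (default: first non-intercept).
#' @return list with per-unit `sign` (+1/-1/0) and `shares` (percent of units
#'   per sign; sums to 100).
#' @export
coefficient_sign_map <- function(gwr, predictor = NULL) {
  stopifnot(inherits(gwr, "hq_gwr"))
  nm <- setdiff(colnames(gwr$coefficients), "(Intercept)")
  if (is.null(predictor)) predictor <- nm[1]
  stopifnot(predictor %in% colnames(gwr$coefficients))
  s <- sign(gwr$coefficients[, predictor])
  shares <- 100 * c(negative = mean(s < 0), zero = mean(s == 0),
                    positive = mean(s > 0))
  list(sign = s, shares = shares)
}
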