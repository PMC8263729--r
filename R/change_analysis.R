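#' Land-use transition matrix between two epochs
#'
#' Cross-tabulates co-registered cells by (from-class, to-class); cells that
#' are nodata at either epoch are excluded. Areas are counts times the cell
#' area in km^2, so row sums of areas equal the class areas at the first
#' epoch and the matrix total equals the common valid area.
#'
#' @param lulc_t1,lulc_t2 co-registered [land_grid()]s.
#' @return object of class `transition_matrix`: list with `counts` and
#'   `areas` (from x to matrices), `cell_size`, `area_km2` (total).
#' @export
transition_matrix <- function(lulc_t1, lulc_t2) {
  stopifnot(inherits(lulc_t1, "land_grid"), inherits(lulc_t2, "land_grid"))
  if (!identical(dim(lulc_t1$values), dim(lulc_t2$values)) ||
      lulc_t1$cell_size != lulc_t2$cell_size)
    stop("epoch grids are not co-registered")
  v1 <- lulc_t1$values; v2 <- lulc_t2$values
  ok <- !is.na(v1) & !is.na(v2)
  lev <- lulc_t1$classes$code
  counts <- table(factor(v1[ok], levels = lev),
                  factor(v2[ok], levels = lev))
  counts <- unclass(counts)
  areas <- counts * cell_area_km2(lulc_t1$cell_size)
  structure(list(counts = counts, areas = areas,
                 cell_size = lulc_t1$cell_size,
                 area_km2 = sum(areas)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %.2f km^2 total, %.2f km^2 changed\n",
              x$area_km2, x$area_km2 - sum(diag(x$areas))))
  invisible(x)
}

#' Sources of new construction land
#'
#' Labels every cell that became construction between the epochs by its
#' donor class at the first epoch (expansion-source map); all other cells are
#' NA.
#'
#' @param lulc_t1,lulc_t2 co-registered [land_grid()]s.
#' @param codes construction codes, default [construction_codes()].
#' @return integer matrix of donor class codes (NA elsewhere).
#' @export
expansion_sources <- function(lulc_t1, lulc_t2,
                              codes = construction_codes()) {
  stopifnot(identical(dim(lulc_t1$values), dim(lulc_t2$values)))
  v1 <- lulc_t1$values; v2 <- lulc_t2$values
  new_constr <- !is.na(v1) & !is.na(v2) &
    !(v1 %in% codes) & (v2 %in% codes)
  out <- matrix(NA_integer_, nrow(v1), ncol(v1))
  out[new_constr] <- v1[new_constr]
  out
}

#' HQCI and CI of one land-use transition
#'
#' Over the n cells converting from `from_codes` to `to_codes` between the
#' epochs: HQCI is the mean per-cell quality change (t2 - t1; negative =
#' loss), S the converted area in km^2, and CI = HQCI * S the total
#' contribution, identically equal to the summed per-cell quality change
#' times the cell area.
#'
#' @param q_t1,q_t2 `quality_surface`s at the two epochs.
#' @param lulc_t1,lulc_t2 co-registered [land_grid()]s.
#' @param from_codes,to_codes integer code sets defining the transition.
#' @return list with `hqci`, `ci`, `area_km2`, `n`. If no cell undergoes the
#'   transition, `n = 0`, `area_km2 = 0` and `hqci`/`ci` are NA (undefined,
#'   not zero).
#' @export
hqci_ci <- function(q_t1, q_t2, lulc_t1, lulc_t2, from_codes, to_codes) {
  stopifnot(inherits(q_t1, "quality_surface"),
            inherits(q_t2, "quality_surface"))
  v1 <- lulc_t1$values; v2 <- lulc_t2$values
  stopifnot(identical(dim(v1), dim(v2)),
            identical(dim(q_t1$values), dim(v1)),
            identical(dim(q_t2$values), dim(v1)))
  sel <- !is.na(v1) & !is.na(v2) &
    (v1 %in% from_codes) & (v2 %in% to_codes)
  n <- sum(sel)
  if (n == 0)
    return(list(hqci = NA_real_, ci = NA_real_, area_km2 = 0, n = 0L))
  dq <- q_t2$values[sel] - q_t1$values[sel]
  hqci <- mean(dq)
  area <- n * cell_area_km2(lulc_t1$cell_size)
  list(hqci = hqci, ci = hqci * area, area_km2 = area, n = as.integer(n))
}

#' Transition report for conversions to construction land
#'
#' One row per aggregate donor group ([class_groups()]) that lost cells to
#' construction between the epochs, with HQCI, converted area and CI; the
#' reporting convention rounds HQCI, area and CI to 2 decimals.
#'
#' @param q_t1,q_t2 `quality_surface`s.
#' @param lulc_t1,lulc_t2 co-registered [land_grid()]s.
#' @param digits rounding for the report columns (NULL = no rounding).
#' @return data.frame with columns `source`, `hqci`, `area_km2`, `ci`, `n`.
#' @export
transition_report <- function(q_t1, q_t2, lulc_t1, lulc_t2, digits = 2) {
  grp <- class_groups()
  constr <- construction_codes(lulc_t1$classes)
  donors <- setdiff(unique(grp), "construction")
  rows <- lapply(donors, function(g) {
    from <- as.integer(names(grp)[grp == g])
    r <- hqci_ci(q_t1, q_t2, lulc_t1, lulc_t2, from, constr)
    data.frame(source = g, hqci = r$hqci, area_km2 = r$area_km2,
               ci = r$ci, n = r$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    out$hqci <- round(out$hqci, digits)
    out$area_km2 <- round(out$area_km2, digits)
    out$ci <- round(out$ci, digits)
  }
  out
}

#' Recompute HQCI from reported CI and area totals
#'
#' The reporting identity HQCI = CI / S, rounded to the report precision;
#' used to check printed transition tables for internal consistency.
#'
#' @param ci total contribution index (dimensionless x km^2).
#' @param area_km2 converted area, km^2.
#' @param digits rounding of the resulting HQCI (default 2, the report
#'   convention).
#' @return numeric HQCI values.
#' @export
hqci_from_totals <- function(ci, area_km2, digits = 2) {
  stopifnot(length(ci) == length(area_km2), all(area_km2 > 0))
  round(ci / area_km2, digits)
}

#' Grade share and grade change bookkeeping across epochs
#'
#' Per epoch, the percentage of valid area in each quality grade I..V; per
#' consecutive period (plus the full first-to-last period), the signed area
#' change per grade in km^2. Sub-period deltas telescope exactly to the
#' full-period delta before rounding.
#'
#' @param surfaces named list of `quality_surface`s (>= 2), in epoch order.
#' @return list with data.frames `shares` (epoch x grade, %) and `changes`
#'   (period x grade, km^2).
#' @export
grade_change_table <- function(surfaces) {
  stopifnot(is.list(surfaces), length(surfaces) >= 2)
  nm <- names(surfaces)
  if (is.null(nm)) nm <- paste0("epoch", seq_along(surfaces))
  glab <- c("I", "II", "III", "IV", "V")
  areas <- t(vapply(surfaces, function(qs) {
    g <- grade_quality(qs)
    as.numeric(table(factor(g, levels = 1:5))) *
      cell_area_km2(qs$cell_size)
  }, numeric(5)))
  colnames(areas) <- glab
  shares <- data.frame(epoch = nm,
                       100 * areas / rowSums(areas),
                       check.names = FALSE, stringsAsFactors = FALSE)
  periods <- c(paste(nm[-length(nm)], nm[-1], sep = "-"),
               paste(nm[1], nm[length(nm)], sep = "-"))
  deltas <- rbind(areas[-1, , drop = FALSE] -
                    areas[-nrow(areas), , drop = FALSE],
                  areas[nrow(areas), ] - areas[1, ])
  changes <- data.frame(period = periods, deltas,
                        check.names = FALSE, stringsAsFactors = FALSE)
  rownames(shares) <- rownames(changes) <- NULL
  list(shares = shares, changes = changes)
}

#' Mean habitat quality over valid cells
#'
#' @param quality a `quality_surface` or numeric matrix.
#' @return arithmetic mean over non-NA cells.
#' @export
mean_quality <- function(quality) {
  q <- if (inherits(quality, "quality_surface")) quality$values else quality
  if (all(is.na(q))) stop("no valid cells")
  mean(q, na.rm = TRUE)
}
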