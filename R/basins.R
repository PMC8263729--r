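#' Zonal mean of a raster over basin labels
#'
#' Arithmetic mean of the value grid over the valid (non-NA) cells of each
#' basin. Basins whose cells are all NA get an NA mean and are flagged.
#'
#' @param grid numeric matrix (or grid object with `$values`).
#' @param basin_labels integer label matrix, co-registered with `grid`.
#' @return named numeric vector of per-basin means, with attribute `empty`
#'   listing labels that had no valid cell.
#' @export
zonal_mean <- function(grid, basin_labels) {
  v <- grid_values(grid)
  stopifnot(identical(dim(v), dim(basin_labels)))
  labs <- sort(unique(as.vector(basin_labels[!is.na(basin_labels)])))
  ok <- !is.na(v) & !is.na(basin_labels)
  if (!any(ok)) stop("no overlap between basin labels and valid data")
  sums <- rowsum(v[ok], basin_labels[ok])
  cnts <- rowsum(rep(1, sum(ok)), basin_labels[ok])
  out <- rep(NA_real_, length(labs))
  names(out) <- labs
  out[rownames(sums)] <- sums / cnts
  attr(out, "empty") <- labs[!(labs %in% as.integer(rownames(sums)))]
  out
}

#' Land urbanization rate per basin
#'
#' Share of each basin's valid cells occupied by construction land.
#'
#' @param lulc a [land_grid()].
#' @param basin_labels integer label matrix.
#' @param codes construction codes, default from the grid's dictionary.
#' @return named numeric vector in [0, 1].
#' @export
land_urbanization_rate <- function(lulc, basin_labels,
                                   codes = construction_codes(lulc$classes)) {
  v <- lulc$values
  built <- matrix(as.numeric(v %in% codes), nrow(v), ncol(v))
  built[is.na(v)] <- NA_real_
  zonal_mean(built, basin_labels)
}

#' Assemble the per-basin indicator table
#'
#' Aggregates habitat quality, nighttime light, population and land
#' urbanization rate to basins, with basin area and centroid (mean of member
#' cell centres, projected metres; origin at the grid's south-west corner).
#'
#' @param basin_labels integer label matrix.
#' @param quality a `quality_surface`.
#' @param ntl,pop covariate matrices.
#' @param lulc a [land_grid()].
#' @return data.frame with columns `basin`, `area_km2`, `q_mean`, `ntl_mean`,
#'   `pop_mean`, `lur`, `x`, `y`.
#' @export
basin_table <- function(basin_labels, quality, ntl, pop, lulc) {
  cs <- lulc$cell_size
  nr <- nrow(basin_labels)
  xs <- (col(basin_labels) - 0.5) * cs
  ys <- (nr - row(basin_labels) + 0.5) * cs
  labs <- sort(unique(as.vector(basin_labels)))
  cnt <- as.numeric(table(factor(basin_labels, levels = labs)))
  out <- data.frame(
    basin = labs,
    area_km2 = cnt * cell_area_km2(cs),
    q_mean = as.numeric(zonal_mean(quality$values, basin_labels)[as.character(labs)]),
    ntl_mean = as.numeric(zonal_mean(ntl, basin_labels)[as.character(labs)]),
    pop_mean = as.numeric(zonal_mean(pop, basin_labels)[as.character(labs)]),
    lur = as.numeric(land_urbanization_rate(lulc, basin_labels)[as.character(labs)]),
    x = as.numeric(zonal_mean(xs, basin_labels)[as.character(labs)]),
    y = as.numeric(zonal_mean(ys, basin_labels)[as.character(labs)])
  )
  rownames(out) <- NULL
  out
}

#' Standardize basin indicators and form their SUM
#'
#' Adds standardized columns (`*_std`) for the four coupling indicators and
#' their per-basin sum `sum_std`. Min-max maps each column to [0, 1] (the
#' default, so the SUM lives on a common 0-4 scale); z-score centres to mean
#' 0, sd 1 and rejects constant columns.
#'
#' @param table a [basin_table()]-like data.frame.
#' @param method "minmax" or "zscore".
#' @param cols columns to standardize.
#' @return the table with added `<col>_std` columns and `sum_std`.
#' @export
standardize_indicators <- function(table,
                                   method = c("minmax", "zscore"),
                                   cols = c("q_mean", "ntl_mean",
                                            "pop_mean", "lur")) {
  method <- match.arg(method)
  stopifnot(nrow(table) >= 2, all(cols %in% names(table)))
  std <- lapply(cols, function(cn) {
    x <- table[[cn]]
    if (any(!is.finite(x))) stop("non-finite values in column ", cn)
    if (method == "minmax") {
      rng <- range(x)
      if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else rep(0, length(x))
    } else {
      s <- stats::sd(x)
      if (s == 0) stop("constant column under z-score: ", cn)
      (x - mean(x)) / s
    }
  })
  names(std) <- sub("_mean$", "", cols)
  for (nm in names(std)) table[[paste0(nm, "_std")]] <- std[[nm]]
  table$sum_std <- Reduce(`+`, std)
  table
}
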