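#' Configuration for synthetic land-use landscapes
#'
#' Describes the categorical landscape the generator emulates: a 30 m-style
#' land-use grid with clustered urban cores embedded in spatially banded
#' natural classes. Proportions are targets for the whole grid.
#'
#' @param grid_height,grid_width grid dimensions in cells.
#' @param cell_size cell size in metres.
#' @param class_mix named numeric vector of target proportions per class name
#'   or code (must sum to 1).
#' @param n_urban_seeds number of urban cluster seeds.
#' @param epochs number of land-use epochs to simulate.
#' @param growth_rate fraction of non-urban cells converted per epoch step.
#' @param compactness weight of 3x3 neighbourhood urban density in the
#'   conversion probability (0 = uniform infill, larger = more compact).
#' @param smoothness Gaussian smoothing sigma (cells) of the field that bands
#'   the natural classes; spatial autocorrelation knob, not inferred from any
#'   real product.
#' @param seed integer RNG seed.
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(grid_height = 256, grid_width = 256,
                             cell_size = 30,
                             class_mix = default_class_mix(),
                             n_urban_seeds = 5, epochs = 4,
                             growth_rate = 0.05, compactness = 3,
                             smoothness = 6, seed = 1) {
  cl <- habitat_classes()
  nm <- names(class_mix)
  if (is.null(nm)) stop("class_mix must be named by class name or code")
  codes <- ifelse(nm %in% cl$name, cl$code[match(nm, cl$name)],
                  suppressWarnings(as.integer(nm)))
  if (anyNA(codes) || !all(codes %in% cl$code))
    stop("class_mix references unknown land-use classes: ",
         paste(nm[is.na(codes) | !(codes %in% cl$code)], collapse = ", "))
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (any(class_mix < 0)) stop("class_mix proportions must be >= 0")
  stopifnot(grid_height >= 1, grid_width >= 1, cell_size > 0,
            n_urban_seeds >= 1, epochs >= 1,
            growth_rate >= 0, growth_rate <= 1, smoothness >= 0)
  mix <- as.numeric(class_mix)
  names(mix) <- as.character(codes)
  structure(list(grid_height = as.integer(grid_height),
                 grid_width = as.integer(grid_width),
                 cell_size = cell_size, class_mix = mix,
                 n_urban_seeds = as.integer(n_urban_seeds),
                 epochs = as.integer(epochs), growth_rate = growth_rate,
                 compactness = compactness, smoothness = smoothness,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Default class mix for synthetic landscapes
#'
#' A delta-plain style composition: cropland- and forest-dominated with a
#' water network, minor grassland/woodland classes and a c. 10% built-up core.
#'
#' @return named numeric vector summing to 1.
#' @export
default_class_mix <- function() {
  c(cropland = 0.30, forestland = 0.25, bush_forest = 0.05,
    sparse_woodland = 0.05, other_woodland = 0.02,
    high_grassland = 0.04, medium_grassland = 0.03, low_grassland = 0.03,
    water = 0.10, unused_land = 0.02, reclamation = 0.01,
    city_town = 0.06, rural_settlement = 0.03, other_construction = 0.01)
}

#' Configuration for synthetic covariate rasters
#'
#' Nighttime-light and population surfaces built from a smoothed built-up
#' density so that both correlate positively with urbanization.
#'
#' @param ntl_urban_mean,ntl_background_mean NTL intensity over fully urban /
#'   fully natural neighbourhoods (urban must exceed background).
#' @param pop_urban_mean,pop_background_mean persons per cell, same contrast
#'   requirement.
#' @param noise_sd additive Gaussian noise sd (NTL units; population noise is
#'   scaled by the pop/ntl contrast ratio).
#' @param smoothing_sigma Gaussian sigma (cells) of the built-up smoothing.
#' @param seed integer RNG seed.
#' @return list of class `covariate_config`.
#' @export
covariate_config <- function(ntl_urban_mean = 55, ntl_background_mean = 5,
                             pop_urban_mean = 250, pop_background_mean = 10,
                             noise_sd = 2, smoothing_sigma = 4, seed = 1) {
  if (ntl_urban_mean <= ntl_background_mean ||
      pop_urban_mean <= pop_background_mean)
    stop("urban means must exceed background means")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(ntl_urban_mean = ntl_urban_mean,
                 ntl_background_mean = ntl_background_mean,
                 pop_urban_mean = pop_urban_mean,
                 pop_background_mean = pop_background_mean,
                 noise_sd = noise_sd, smoothing_sigma = smoothing_sigma,
                 seed = as.integer(seed)),
            class = "covariate_config")
}

#' Generate a synthetic categorical landscape
#'
#' Urban (construction) cells are planted as `n_urban_seeds` compact connected
#' clusters; the remaining cells are banded into the natural classes along a
#' smoothed random field, so empirical proportions match `class_mix` up to
#' integer rounding while classes remain spatially clustered.
#'
#' @param config a [landscape_config()].
#' @return a [land_grid()].
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    nr <- config$grid_height; nc <- config$grid_width
    n <- nr * nc
    codes <- as.integer(names(config$class_mix))
    mix <- config$class_mix
    constr <- construction_codes()
    urb_codes <- codes[codes %in% constr]
    nat_codes <- codes[!(codes %in% constr)]

    out <- matrix(NA_integer_, nr, nc)

    # --- urban clusters -------------------------------------------------
    urb_total <- round(sum(mix[as.character(urb_codes)]) * n)
    if (urb_total > 0) {
      ns <- min(config$n_urban_seeds, urb_total)
      target_r <- sqrt(urb_total / (pi * ns))
      seeds <- NULL
      for (try in 1:200) {
        cand <- cbind(stats::runif(ns, 1, nr), stats::runif(ns, 1, nc))
        if (ns == 1 || min(stats::dist(cand)) > 2 * target_r + 2) {
          seeds <- cand; break
        }
      }
      if (is.null(seeds)) seeds <- cand  # dense grids: accept possible merges
      rows <- row(out); cols <- col(out)
      dmin <- matrix(Inf, nr, nc)
      for (s in seq_len(nrow(seeds)))
        dmin <- pmin(dmin, sqrt((rows - seeds[s, 1])^2 +
                                (cols - seeds[s, 2])^2))
      ord <- order(dmin, seq_len(n))  # ties broken by cell index
      urb_cells <- ord[seq_len(urb_total)]
      # subtype split: quotas per construction code, shuffled assignment
      quota <- round(mix[as.character(urb_codes)] /
                     sum(mix[as.character(urb_codes)]) * urb_total)
      quota[length(quota)] <- urb_total - sum(quota[-length(quota)])
      lab <- rep(urb_codes, times = pmax(quota, 0))
      lab <- c(lab, rep(urb_codes[1], urb_total - length(lab)))[1:urb_total]
      out[urb_cells] <- lab[sample.int(urb_total)]
    }

    # --- natural classes banded along a smoothed field ------------------
    rest <- which(is.na(out))
    if (length(rest) > 0) {
      if (length(nat_codes) == 0)
        stop("class_mix has no non-construction class but grid is not all urban")
      field <- smooth_field(matrix(stats::runif(n), nr, nc),
                            config$smoothness)
      o <- rest[order(field[rest], rest)]
      p <- mix[as.character(nat_codes)]
      p <- p / sum(p)
      cuts <- round(cumsum(p) * length(rest))
      cuts[length(cuts)] <- length(rest)
      start <- 1L
      for (i in seq_along(nat_codes)) {
        if (cuts[i] >= start) out[o[start:cuts[i]]] <- nat_codes[i]
        start <- cuts[i] + 1L
      }
    }
    land_grid(out, cell_size = config$cell_size)
  })
}

#' Grow urban land by one epoch step
#'
#' Converts `round(growth_rate * #non-construction cells)` cells to urban
#' land. Conversion weight is `exp(compactness * f)` with `f` the fraction of
#' construction cells in the 3x3 neighbourhood, so growth clings to existing
#' cores when `compactness > 0`; cells are drawn by exact weighted sampling
#' without replacement.
#'
#' @param lulc a [land_grid()] with at least one construction cell.
#' @param growth_rate fraction of current non-urban cells to convert, in
#'   [0, 1].
#' @param compactness neighbourhood-density weight, >= 0.
#' @param seed integer RNG seed.
#' @param to_code construction code assigned to converted cells.
#' @return a [land_grid()] with the same geometry.
#' @export
grow_urban <- function(lulc, growth_rate, compactness = 3, seed = 1,
                       to_code = 12L) {
  stopifnot(inherits(lulc, "land_grid"))
  if (growth_rate < 0 || growth_rate > 1)
    stop("growth_rate must be in [0, 1]")
  v <- lulc$values
  constr <- construction_codes(lulc$classes)
  is_urb <- matrix(v %in% constr, nrow(v), ncol(v))
  if (!any(is_urb, na.rm = TRUE)) stop("no construction cell to grow from")
  nonurb <- which(!is_urb & !is.na(v))
  n_conv <- round(growth_rate * length(nonurb))
  if (n_conv == 0) return(lulc)
  with_seed(seed, {
    ones3 <- matrix(1, 3, 3)
    f <- conv2d(is_urb * 1, ones3) /
      conv2d(matrix(1, nrow(v), ncol(v)), ones3)
    w <- exp(compactness * f[nonurb])
    # exponential race: exact weighted sampling without replacement
    keys <- stats::rexp(length(nonurb)) / w
    pick <- nonurb[order(keys)[seq_len(n_conv)]]
    v[pick] <- as.integer(to_code)
    land_grid(v, cell_size = lulc$cell_size, classes = lulc$classes)
  })
}

#' Simulate a multi-epoch land-use series
#'
#' Epoch 1 from [generate_landscape()], later epochs by repeated
#' [grow_urban()] steps with per-epoch derived seeds.
#'
#' @param config a [landscape_config()].
#' @return list of [land_grid()]s, length `config$epochs`.
#' @export
generate_epochs <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  out <- vector("list", config$epochs)
  out[[1]] <- generate_landscape(config)
  if (config$epochs > 1) {
    for (e in 2:config$epochs) {
      out[[e]] <- grow_urban(out[[e - 1]], config$growth_rate,
                             config$compactness,
                             seed = config$seed + 1000L * e)
    }
  }
  out
}

#' Generate NTL and population covariates from a land grid
#'
#' Both covariates are affine in the kernel-smoothed built-up density plus
#' seeded Gaussian noise, clamped non-negative, so they correlate positively
#' with urbanization by construction.
#'
#' @param lulc a [land_grid()].
#' @param config a [covariate_config()].
#' @return list with matrices `ntl`, `pop` and the smoothed built-up density
#'   `builtup`.
#' @export
generate_covariates <- function(lulc, config = covariate_config()) {
  stopifnot(inherits(lulc, "land_grid"), inherits(config, "covariate_config"))
  v <- lulc$values
  constr <- construction_codes(lulc$classes)
  built <- matrix(as.numeric(v %in% constr), nrow(v), ncol(v))
  s <- smooth_field(built, config$smoothing_sigma)
  with_seed(config$seed, {
    n <- length(v)
    ntl <- config$ntl_background_mean +
      (config$ntl_urban_mean - config$ntl_background_mean) * s +
      stats::rnorm(n, 0, config$noise_sd)
    pop_scale <- (config$pop_urban_mean - config$pop_background_mean) /
      (config$ntl_urban_mean - config$ntl_background_mean)
    pop <- config$pop_background_mean +
      (config$pop_urban_mean - config$pop_background_mean) * s +
      stats::rnorm(n, 0, config$noise_sd * pop_scale)
    ntl <- matrix(pmax(ntl, 0), nrow(v), ncol(v))
    pop <- matrix(pmax(pop, 0), nrow(v), ncol(v))
    ntl[is.na(v)] <- NA_real_
    pop[is.na(v)] <- NA_real_
    list(ntl = ntl, pop = pop, builtup = s)
  })
}

#' Generate a contiguous basin tessellation
#'
#' Multi-source breadth-first growth from `n_basins` seeded cells (a
#' grid-geodesic Voronoi partition, guaranteeing 4-connected basins), followed
#' by a smallest-first merge of basins below `min_area_km2` into the
#' neighbouring basin sharing the longest border. Labels are renumbered to
#' contiguous integers from 1.
#'
#' @param grid_shape c(nrow, ncol).
#' @param n_basins number of seeds, >= 1 and <= cell count.
#' @param min_area_km2 minimum basin area after merging.
#' @param cell_size cell size in metres.
#' @param seed integer RNG seed.
#' @return integer label matrix.
#' @export
generate_basins <- function(grid_shape, n_basins, min_area_km2 = 5,
                            cell_size = 30, seed = 1) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  n <- nr * nc
  if (n_basins < 1) stop("n_basins must be >= 1")
  if (n_basins > n) stop("n_basins exceeds cell count")
  lab <- with_seed(seed, {
    L <- matrix(NA_integer_, nr, nc)
    L[sample.int(n, n_basins)] <- seq_len(n_basins)
    # synchronous BFS fronts; ties resolved to the lowest label
    while (anyNA(L)) {
      cand <- matrix(Inf, nr, nc)
      shift_in <- function(M, dr, dc) {
        S <- matrix(Inf, nr, nc)
        rs <- max(1, 1 + dr):min(nr, nr + dr)
        cs <- max(1, 1 + dc):min(nc, nc + dc)
        S[rs, cs] <- M[rs - dr, cs - dc]
        S
      }
      Lnum <- matrix(as.numeric(L), nr, nc)
      Lnum[is.na(L)] <- Inf
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
        cand <- pmin(cand, shift_in(Lnum, d[1], d[2]))
      newly <- is.na(L) & is.finite(cand)
      if (!any(newly)) break
      L[newly] <- as.integer(cand[newly])
    }
    L
  })
  lab <- merge_small_basins(lab, min_area_km2, cell_size)
  # contiguous labels from 1, ordered by old label
  old <- sort(unique(as.vector(lab)))
  matrix(match(lab, old), nr, nc)
}

# Smallest-first merge of basins below the area threshold into the neighbour
# sharing the longest border (ties -> lowest neighbour label).
merge_small_basins <- function(lab, min_area_km2, cell_size) {
  area1 <- cell_area_km2(cell_size)
  repeat {
    areas <- table(lab) * area1
    if (length(areas) <= 1) break
    small <- names(areas)[areas < min_area_km2]
    if (length(small) == 0) break
    s <- as.integer(small[which.min(areas[small])])
    # border lengths with 4-neighbours
    h1 <- lab[-nrow(lab), , drop = FALSE]; h2 <- lab[-1, , drop = FALSE]
    v1 <- lab[, -ncol(lab), drop = FALSE]; v2 <- lab[, -1, drop = FALSE]
    pairs <- rbind(cbind(as.vector(h1), as.vector(h2)),
                   cbind(as.vector(v1), as.vector(v2)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    nb <- c(pairs[pairs[, 1] == s, 2], pairs[pairs[, 2] == s, 1])
    if (length(nb) == 0) break  # isolated component, nothing to merge into
    tb <- table(nb)
    best <- as.integer(names(tb)[order(-tb, as.integer(names(tb)))][1])
    lab[lab == s] <- best
  }
  lab
}
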