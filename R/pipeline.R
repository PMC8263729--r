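#' Run the full habitat-quality / urbanization coupling pipeline
#'
#' End-to-end synthetic analysis: simulate a multi-epoch land-use series,
#' compute degradation and quality surfaces per epoch, land-use transition and
#' HQCI/CI statistics, grade bookkeeping, basin tessellation and indicators,
#' univariate GWR against each urbanization indicator (with OLS comparison),
#' and SOFM zoning of basins into four green-development classes.
#'
#' Basin indicators follow the study design: covariates and quality are
#' averaged per basin per epoch, regressions use the final epoch, and the
#' zoning uses per-basin means across epochs.
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @param config landscape configuration; defaults to a 128 x 128 grid at
#'   30 m with the default class mix (kept modest so the whole pipeline runs
#'   in seconds).
#' @param n_basins basins requested before the minimum-area merge.
#' @param min_area_km2 basin merge threshold.
#' @param k half-saturation constant for the quality model.
#' @param som_epochs SOM training epochs.
#' @return list with `landscapes`, `quality`, `report` (transition report
#'   first vs last epoch), `grades` (shares/changes), `mean_q` per epoch,
#'   `basins`, `basin_tables` (per epoch), `table` (standardized, final
#'   epoch), `gwr` (per predictor: ols, gwr, bandwidth, comparison),
#'   `zones` (SOFM assignment on across-epoch means).
#' @export
run_pipeline <- function(seed = 1,
                         config = landscape_config(grid_height = 128,
                                                   grid_width = 128,
                                                   seed = seed),
                         n_basins = 60, min_area_km2 = 0.2, k = 0.5,
                         som_epochs = 200) {
  landscapes <- generate_epochs(config)
  threats <- threat_table()
  sens <- sensitivity_table()
  quality <- lapply(landscapes, function(g) {
    compute_quality(compute_degradation(g, threats, sens), g, sens, k = k)
  })
  names(quality) <- names(landscapes) <- paste0("t", seq_along(landscapes))

  nE <- length(landscapes)
  report <- transition_report(quality[[1]], quality[[nE]],
                              landscapes[[1]], landscapes[[nE]])
  grades <- grade_change_table(quality)
  mean_q <- vapply(quality, mean_quality, numeric(1))

  basins <- generate_basins(dim(landscapes[[1]]$values), n_basins,
                            min_area_km2 = min_area_km2,
                            cell_size = config$cell_size,
                            seed = seed + 7L)
  basin_tables <- lapply(seq_len(nE), function(e) {
    cov <- generate_covariates(landscapes[[e]],
                               covariate_config(seed = seed + 100L + e))
    basin_table(basins, quality[[e]], cov$ntl, cov$pop, landscapes[[e]])
  })

  tab <- standardize_indicators(basin_tables[[nE]])
  coords <- as.matrix(tab[, c("x", "y")])
  gwr_results <- lapply(c(ntl = "ntl_mean", pop = "pop_mean", lur = "lur"),
                        function(pred) {
    X <- as.matrix(tab[, pred, drop = FALSE])
    ols <- ols_fit(tab$q_mean, X, coords)
    bw <- select_bandwidth(tab$q_mean, X, coords)
    gwr <- gwr_fit(tab$q_mean, X, coords, bw$bandwidth)
    list(ols = ols, gwr = gwr, bandwidth = bw$bandwidth,
         comparison = compare_models(ols, gwr),
         signs = coefficient_sign_map(gwr))
  })

  # zoning input: per-basin means of the indicators across epochs
  mean_tab <- basin_tables[[1]]
  for (cn in c("q_mean", "ntl_mean", "pop_mean", "lur")) {
    mean_tab[[cn]] <- rowMeans(vapply(basin_tables, `[[`,
                                      numeric(nrow(mean_tab)), cn))
  }
  mean_tab <- standardize_indicators(mean_tab)
  som <- train_som(as.matrix(mean_tab[, c("q_std", "ntl_std", "pop_std",
                                          "lur_std")]),
                   epochs = som_epochs, seed = seed + 31L)
  zones <- assign_zones(som, mean_tab)

  list(landscapes = landscapes, quality = quality, report = report,
       grades = grades, mean_q = mean_q, basins = basins,
       basin_tables = basin_tables, table = tab, gwr = gwr_results,
       som = som, zones = zones, config = config)
}
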