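#' Simulate a complete synthetic study scene
#'
#' Generates everything the comparison pipeline consumes: a
#' fractional-Brownian habitat-suitability surface, a three-class
#' land-cover mosaic thresholded from a smoothed copy of the surface,
#' sampling sites with a minimum separation, and forward-simulated
#' microsatellite genotypes with migration decaying in distance.
#'
#' @param nrows,ncols surface dimensions.
#' @param hurst surface roughness exponent.
#' @param cell_size metres per cell.
#' @param n_sites number of sampling sites.
#' @param min_sep minimum site separation (metres).
#' @param n_ind_per_site,n_loci,migration_scale,mutation_rate,n_generations
#'   passed to [simulate_microsatellites()].
#' @param landcover_breaks thresholds for [classify_landcover()].
#' @param seed master seed; sub-seeds for each generator are derived from
#'   it deterministically.
#' @return list: `surface`, `landcover`, `sites`, `genotypes`, `seed`.
#' @export
simulate_scene <- function(nrows = 128, ncols = 128, hurst = 0.6,
                           cell_size = 30, n_sites = 17,
                           min_sep = 10 * cell_size,
                           n_ind_per_site = 25, n_loci = 10,
                           migration_scale = NULL, mutation_rate = 5e-4,
                           n_generations = 100,
                           landcover_breaks = c(1 / 3, 2 / 3), seed = 1L) {
  seed <- as.integer(seed)
  surface <- generate_surface(nrows, ncols, hurst = hurst,
                              cell_size = cell_size, seed = seed)
  landcover <- classify_landcover(surface, breaks = landcover_breaks)
  sites <- place_sites(surface, n = n_sites, min_sep = min_sep,
                       seed = seed + 1L)
  if (is.null(migration_scale)) {
    # a quarter of the raster diagonal: differentiation rises with distance
    migration_scale <- 0.25 * cell_size * sqrt(nrows^2 + ncols^2)
  }
  genotypes <- simulate_microsatellites(
    sites, n_ind_per_site = n_ind_per_site, n_loci = n_loci,
    migration_scale = migration_scale, mutation_rate = mutation_rate,
    n_generations = n_generations, seed = seed + 2L)
  list(surface = surface, landcover = landcover, sites = sites,
       genotypes = genotypes, seed = seed)
}

#' Assemble all predictor tables for a scene
#'
#' Clips the surface and land cover to every pairwise ellipse, computes
#' the gradient-surface-metric table, the PMM3 and PMM2 patch-metric
#' tables, and the resistance/distance table (LCP, commute distance,
#' Euclidean) on the full raster.
#'
#' @param scene a [simulate_scene()] result, or a list with `surface`,
#'   `landcover`, `sites`.
#' @param axis_ratio ellipse minor/major axis ratio.
#' @param connectivity raster-graph connectivity for the resistance
#'   models.
#' @return list of data frames: `gsm`, `pmm3`, `pmm2`, `rbm`.
#' @export
predictor_tables <- function(scene, axis_ratio = 0.5, connectivity = 8) {
  surf_clips <- pairwise_clips(scene$surface, scene$sites,
                               axis_ratio = axis_ratio)
  lc_clips <- pairwise_clips(scene$landcover, scene$sites,
                             axis_ratio = axis_ratio)
  list(gsm = gsm_table(surf_clips, scene$sites),
       pmm3 = pmm_table(lc_clips, scene$sites, scheme = "pmm3"),
       pmm2 = pmm_table(lc_clips, scene$sites, scheme = "pmm2"),
       rbm = resistance_table(scene$surface, scene$sites,
                              connectivity = connectivity))
}

# Fit one approach: Box-Cox'd response, VIF-pruned scaled predictors,
# dredge (multivariate) or direct fit (single predictor).
.fit_approach <- function(label, y_t, X, sites, r_max = 0.6,
                          vif_threshold = 10) {
  X <- as.matrix(X)
  keep <- colSums(!is.finite(X)) == 0
  if (!all(keep)) {
    warning(label, ": dropping predictors undefined on some pairs: ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  X <- scale_predictors(X)
  if (ncol(X) > 1L) {
    X <- vif_prune(X, threshold = vif_threshold)$X
  }
  tab <- dredge_mlpe(y_t, X, sites, r_max = r_max)
  best <- attr(tab, "fits")[[1]]
  r2 <- r2_nakagawa(best)
  list(label = label, table = tab, best = best,
       best_row = data.frame(
         approach = label, formula = tab$formula[1], aic = tab$aic[1],
         weight = tab$weight[1], r2m = unname(r2["marginal"]),
         r2c = unname(r2["conditional"]), rho = dependency_rho(best),
         stringsAsFactors = FALSE))
}

#' Run the six-approach connectivity comparison
#'
#' Fits MLPE models of the pairwise genetic distance against each
#' predictor family — GSM (gradient surface metrics), PMM3 and PMM2
#' (patch-mosaic metrics), LCP and CD (resistance models) and IBD
#' (Euclidean distance) — and ranks the best model of each approach by
#' AIC. The response is Box-Cox transformed once; predictors are
#' VIF-pruned (threshold 10) and standardised per approach; dredging
#' enumerates all submodels with pairwise predictor correlation capped
#' at `r_max` (single-predictor approaches are fitted directly).
#'
#' @param scene a [simulate_scene()]-style list (`surface`, `landcover`,
#'   `sites`, optionally `genotypes`).
#' @param response optional pairwise response vector (one value per
#'   [pair_index()] row); by default R_ST is computed from
#'   `scene$genotypes`.
#' @param tables optional precomputed [predictor_tables()] result.
#' @param r_max dredge collinearity cap.
#' @param top_n best rows per approach to keep in the report.
#' @return list of class `pairscape_report`: `report` (one row per
#'   approach with cross-approach `delta_aic` and `weight`), `top`
#'   (top-`top_n` rows per approach), `approaches` (full per-approach
#'   model tables), `boxcox`, `response`.
#' @export
run_comparison <- function(scene, response = NULL, tables = NULL,
                           r_max = 0.6, top_n = 3) {
  sites <- scene$sites
  if (is.null(response)) {
    if (is.null(scene$genotypes)) {
      stop("provide a response vector or genotypes in the scene", call. = FALSE)
    }
    response <- pairwise_column(rst_matrix(scene$genotypes)[sites$site_id,
                                                            sites$site_id],
                                sites)
  }
  bc <- boxcox_transform(response)
  y_t <- bc$transformed
  if (is.null(tables)) tables <- predictor_tables(scene)
  num <- function(d) as.matrix(d[, setdiff(names(d), c("site_i", "site_j")),
                                 drop = FALSE])
  fits <- list(
    .fit_approach("GSM", y_t, num(tables$gsm), sites, r_max),
    .fit_approach("PMM3", y_t, num(tables$pmm3), sites, r_max),
    .fit_approach("PMM2", y_t, num(tables$pmm2), sites, r_max),
    .fit_approach("LCP", y_t, num(tables$rbm)[, "lcp", drop = FALSE], sites),
    .fit_approach("CD", y_t, num(tables$rbm)[, "cd", drop = FALSE], sites),
    .fit_approach("IBD", y_t, num(tables$rbm)[, "euclid", drop = FALSE], sites)
  )
  report <- do.call(rbind, lapply(fits, `[[`, "best_row"))
  ca <- cross_approach_delta(report$aic)
  report$delta_aic <- ca$delta_aic
  report$weight <- ca$weight
  report <- report[order(report$aic),
                   c("approach", "formula", "aic", "delta_aic", "weight",
                     "r2m", "r2c", "rho")]
  rownames(report) <- NULL
  top <- do.call(rbind, lapply(fits, function(f) {
    t <- utils::head(f$table, top_n)
    data.frame(approach = f$label, t[, c("formula", "aic", "delta_aic")],
               stringsAsFactors = FALSE)
  }))
  rownames(top) <- NULL
  structure(list(report = report, top = top,
                 approaches = stats::setNames(lapply(fits, `[[`, "table"),
                                              vapply(fits, `[[`, "", "label")),
                 best_fits = stats::setNames(lapply(fits, `[[`, "best"),
                                             vapply(fits, `[[`, "", "label")),
                 boxcox = bc[c("lambda", "shift")], response = response),
            class = "pairscape_report")
}

#' @export
print.pairscape_report <- function(x, ...) {
  cat("Six-approach MLPE connectivity comparison (best model per approach)\n")
  r <- x$report
  r$aic <- round(r$aic, 2); r$delta_aic <- round(r$delta_aic, 2)
  r$weight <- signif(r$weight, 2)
  r$r2m <- round(r$r2m, 3); r$r2c <- round(r$r2c, 3); r$rho <- round(r$rho, 3)
  print(r)
  cat(sprintf("Box-Cox lambda = %.2f (shift %.3g)\n", x$boxcox$lambda,
              x$boxcox$shift))
  invisible(x)
}

#' Cross-approach delta-AIC and Akaike weights
#'
#' `delta_aic = aic - min(aic)`; weights
#' `exp(-delta / 2) / sum(exp(-delta / 2))` over the supplied candidate
#' set (by default the per-approach best models; pass all dredged AICs to
#' normalise over the full candidate set instead).
#'
#' @param aic numeric vector of AIC values.
#' @return list with `delta_aic` and `weight`, aligned with `aic`.
#' @export
cross_approach_delta <- function(aic) {
  delta <- aic - min(aic)
  list(delta_aic = delta,
       weight = exp(-delta / 2) / sum(exp(-delta / 2)))
}
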