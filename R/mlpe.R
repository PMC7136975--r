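#' Box-Cox transform of a pairwise response
#'
#' Shifts the response strictly positive (`shift = max(0, 1e-6 - min(y))`)
#' and picks the power `lambda` maximising the Box-Cox profile
#' log-likelihood over the grid `[-2, 2]` in steps of 0.01. The transform
#' is `((y + shift)^lambda - 1) / lambda`, or `log(y + shift)` at
#' `lambda = 0`. Genetic distances are typically right-skewed and bounded
#' below, so this normalises residuals before mixed-model fitting.
#'
#' @param y numeric response (n >= 10, non-constant).
#' @param grid candidate lambda values.
#' @return list with `lambda`, `shift`, `transformed`.
#' @export
boxcox_transform <- function(y, grid = seq(-2, 2, by = 0.01)) {
  if (any(!is.finite(y))) stop("response must be finite", call. = FALSE)
  if (length(y) < 10L) stop("need at least 10 observations", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  shift <- max(0, 1e-6 - min(y))
  yp <- y + shift
  n <- length(yp)
  slog <- sum(log(yp))
  ll <- vapply(grid, function(l) {
    z <- if (abs(l) < 1e-12) log(yp) else (yp^l - 1) / l
    -n / 2 * log(stats::var(z) * (n - 1) / n) + (l - 1) * slog
  }, numeric(1))
  lambda <- grid[which.max(ll)]
  z <- if (abs(lambda) < 1e-12) log(yp) else (yp^lambda - 1) / lambda
  list(lambda = lambda, shift = shift, transformed = z)
}

#' Iterative variance-inflation-factor pruning
#'
#' Repeatedly drops the single predictor with the highest VIF
#' (`VIF_j = 1 / (1 - R2_j)` from regressing column j on the others)
#' until every VIF is below `threshold`. Perfect collinearity gives an
#' infinite VIF, which sorts first; ties drop the later column.
#'
#' @param X numeric matrix or data frame of predictors (no intercept
#'   column), more rows than columns.
#' @param threshold VIF threshold (default 10).
#' @return list with `X` (retained columns, original order), `kept`,
#'   `dropped` (in removal order), `vif` (final VIFs).
#' @export
vif_prune <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L) {
    return(list(X = X, kept = colnames(X), dropped = character(0),
                vif = stats::setNames(rep(1, ncol(X)), colnames(X))))
  }
  dropped <- character(0)
  repeat {
    vifs <- .vif_values(X)
    if (ncol(X) < 2L || max(vifs) < threshold) break
    # which.max on the reversed vector drops the *later* column on ties
    worst <- length(vifs) + 1L - which.max(rev(vifs))
    dropped <- c(dropped, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  list(X = X, kept = colnames(X), dropped = dropped, vif = .vif_values(X))
}

.vif_values <- function(X) {
  if (ncol(X) < 2L) return(stats::setNames(1, colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

# site-incidence matrix: n_pairs x n_sites, two unit entries per row
mlpe_incidence <- function(sites) {
  idx <- pair_index(sites)
  Z <- matrix(0, nrow(idx), nrow(sites))
  Z[cbind(seq_len(nrow(idx)), idx$i)] <- 1
  Z[cbind(seq_len(nrow(idx)), idx$j)] <- 1
  Z
}

#' Fit a maximum-likelihood-population-effects (MLPE) mixed model
#'
#' The model is `y = X beta + Z u + e` where `Z` is the pair-to-site
#' incidence matrix (two unit entries per row, one for each member site
#' of the pair), `u ~ N(0, sigma_u^2 I)` over sites and
#' `e ~ N(0, sigma_e^2 I)` over pairs. Pairs sharing a site are thereby
#' correlated, which is what distinguishes MLPE from ordinary regression
#' on pairwise distances. Estimation profiles the likelihood over the
#' variance ratio `theta = sigma_u^2 / sigma_e^2`: for fixed theta the
#' marginal covariance is `sigma_e^2 (I + theta Z Z')`, beta has a closed
#' GLS form and `sigma_e^2` a closed form, so a one-dimensional
#' optimisation over `log(theta)` (plus the `theta = 0` boundary, where
#' the model reduces to OLS) completes the fit. `AIC = -2 logLik_ML + 2 k`
#' with `k = length(beta) + 2` (two variance parameters).
#'
#' @param y numeric response, one value per pair in [pair_index()] order.
#' @param X numeric predictor matrix (no intercept column; one is added),
#'   or `NULL` for the intercept-only model.
#' @param sites a [site_set()].
#' @param method `"ML"` (used for AIC/model selection) or `"REML"` (used
#'   for variance-component reporting).
#' @param eig optional precomputed `eigen(Z %*% t(Z))` to amortise
#'   repeated fits over the same site set.
#' @param theta_fixed optional fixed variance ratio
#'   `sigma_u^2 / sigma_e^2`; `0` reduces the fit to ordinary least
#'   squares. `NULL` (default) profiles theta out by likelihood.
#' @return object of class `pairscape_mlpe`: `beta`, `vcov_beta`,
#'   `sigma_u2`, `sigma_e2`, `theta`, `loglik`, `loglik_ml`, `aic`,
#'   `fitted`, `residuals`, `method`, `n_pairs`, `n_sites`, `predictors`.
#' @export
fit_mlpe <- function(y, X = NULL, sites, method = c("ML", "REML"),
                     eig = NULL, theta_fixed = NULL) {
  method <- match.arg(method)
  n_sites <- nrow(sites)
  n <- length(y)
  if (n != n_sites * (n_sites - 1) / 2) {
    stop("y must cover the complete pair universe of the site set",
         call. = FALSE)
  }
  predictors <- if (is.null(X)) character(0) else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    colnames(X)
  }
  Xf <- cbind(`(Intercept)` = rep(1, n), X)
  p <- ncol(Xf)
  if (is.null(eig)) eig <- eigen(tcrossprod(mlpe_incidence(sites)),
                                 symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  Q <- eig$vectors
  yt <- crossprod(Q, y)
  Xt <- crossprod(Q, Xf)

  profile <- function(theta, reml) {
    wl <- 1 + theta * lam
    w <- 1 / wl
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    XtWy <- crossprod(XtW, yt)
    ok <- tryCatch({ beta <- solve(XtWX, XtWy); TRUE },
                   error = function(e) FALSE)
    if (!ok) return(list(ll = -Inf))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    logdetV <- sum(log(wl))
    if (reml) {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + logdetV +
                      determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
    } else {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdetV + n)
    }
    list(ll = as.numeric(ll), beta = drop(beta), s2 = s2, XtWX = XtWX, w = w)
  }

  reml <- method == "REML"
  if (!is.null(theta_fixed)) {
    theta <- theta_fixed
    at_opt <- profile(theta, reml)
  } else {
    obj <- function(lt) -profile(exp(lt), reml)$ll
    opt <- stats::optimize(obj, interval = c(-14, 10), tol = 1e-8)
    theta <- exp(opt$minimum)
    at_opt <- profile(theta, reml)
    at_zero <- profile(0, reml)
    if (at_zero$ll >= at_opt$ll) {  # boundary: no site effect
      theta <- 0
      at_opt <- at_zero
    }
  }
  fit <- at_opt
  loglik_ml <- if (reml) profile(theta, FALSE)$ll else fit$ll
  # refit beta at theta under ML weights for reporting consistency:
  # beta is identical under ML/REML for fixed theta, so no refit needed
  beta <- fit$beta
  names(beta) <- colnames(Xf)
  sigma_e2 <- fit$s2
  vcov_beta <- sigma_e2 * solve(fit$XtWX)
  dimnames(vcov_beta) <- list(colnames(Xf), colnames(Xf))
  fitted <- drop(Xf %*% beta)
  structure(list(
    beta = beta, vcov_beta = vcov_beta,
    sigma_u2 = theta * sigma_e2, sigma_e2 = sigma_e2, theta = theta,
    loglik = fit$ll, loglik_ml = loglik_ml,
    aic = -2 * loglik_ml + 2 * (p + 2),
    fitted = fitted, residuals = y - fitted,
    method = method, n_pairs = n, n_sites = n_sites,
    predictors = predictors, y = y, X = X, sites = sites
  ), class = "pairscape_mlpe")
}

#' @export
print.pairscape_mlpe <- function(x, ...) {
  cat(sprintf("MLPE fit (%s), %d pairs over %d sites\n", x$method,
              x$n_pairs, x$n_sites))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  cat(sprintf("  sigma_u^2 = %.4g, sigma_e^2 = %.4g, logLik = %.3f, AIC = %.2f\n",
              x$sigma_u2, x$sigma_e2, x$loglik, x$aic))
  invisible(x)
}

#' Marginal and conditional R-squared of an MLPE fit
#'
#' Variance-component decomposition for mixed models: with
#' `sigma_f^2 = var(X beta_hat)` (fixed-effect predictor variance) and a
#' per-observation random-effect variance of `2 sigma_u^2` (each pair
#' carries two unit site loadings),
#' `marginal = sigma_f^2 / (sigma_f^2 + 2 sigma_u^2 + sigma_e^2)` and
#' `conditional = (sigma_f^2 + 2 sigma_u^2) / (...)`. Variance
#' components are taken from a REML refit, the usual reporting
#' convention.
#'
#' @param fit a [fit_mlpe()] result.
#' @return named numeric: `marginal`, `conditional`.
#' @export
r2_nakagawa <- function(fit) {
  if (fit$method != "REML") {
    fit <- fit_mlpe(fit$y, fit$X, fit$sites, method = "REML")
  }
  sf2 <- stats::var(fit$fitted) * (fit$n_pairs - 1) / fit$n_pairs
  tot <- sf2 + 2 * fit$sigma_u2 + fit$sigma_e2
  c(marginal = sf2 / tot, conditional = (sf2 + 2 * fit$sigma_u2) / tot)
}

#' Pairwise-dependency correlation rho
#'
#' The model-implied correlation between two pairwise observations that
#' share exactly one site: `rho = sigma_u^2 / (2 sigma_u^2 + sigma_e^2)`,
#' in [0, 0.5). A rho near 0 means the population effects were
#' unnecessary; the closer to its upper bound, the stronger the
#' dependency among pairs sharing a site.
#'
#' @param fit a [fit_mlpe()] result (REML components used, as for R2).
#' @return rho (scalar).
#' @export
dependency_rho <- function(fit) {
  if (fit$method != "REML") {
    fit <- fit_mlpe(fit$y, fit$X, fit$sites, method = "REML")
  }
  fit$sigma_u2 / (2 * fit$sigma_u2 + fit$sigma_e2)
}

#' Dredge: exhaustive MLPE submodel selection under a collinearity cap
#'
#' Enumerates every predictor subset (including the intercept-only
#' model), discards subsets containing any pair of predictors with
#' `|r| >= r_max`, fits each retained candidate by ML, and ranks by AIC
#' with `delta_aic` and Akaike weights
#' `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))` over the retained
#' candidate set.
#'
#' @param y response (one value per pair).
#' @param X predictor matrix (scaled); at most 12 columns.
#' @param sites a [site_set()].
#' @param r_max pairwise-correlation cap (default 0.6).
#' @return data frame of class `pairscape_modeltable`, sorted by AIC:
#'   `formula`, `k`, `aic`, `delta_aic`, `weight`, plus a `fits`
#'   attribute (list of the fitted models, same order).
#' @export
dredge_mlpe <- function(y, X, sites, r_max = 0.6) {
  X <- as.matrix(X)
  if (ncol(X) > 12L) stop("dredge enumerates at most 12 predictors", call. = FALSE)
  if (ncol(X) && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  p <- ncol(X)
  cors <- if (p > 1) abs(stats::cor(X)) else matrix(0, 1, 1)
  eig <- eigen(tcrossprod(mlpe_incidence(sites)), symmetric = TRUE)
  subsets <- list()
  for (size in 0:p) {
    if (size == 0) { subsets <- c(subsets, list(integer(0))); next }
    cmb <- utils::combn(p, size, simplify = FALSE)
    for (s in cmb) {
      if (size < 2 || max(cors[s, s][upper.tri(cors[s, s])]) < r_max) {
        subsets <- c(subsets, list(s))
      }
    }
  }
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (k in seq_along(subsets)) {
    s <- subsets[[k]]
    Xs <- if (length(s)) X[, s, drop = FALSE] else NULL
    f <- tryCatch(fit_mlpe(y, Xs, sites, method = "ML", eig = eig),
                  error = function(e) {
                    warning("candidate fit failed (",
                            paste(colnames(X)[s], collapse = " + "), "): ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(f)) next
    fits[[k]] <- f
    rows[[k]] <- data.frame(
      formula = if (length(s)) paste("~", paste(colnames(X)[s], collapse = " + "))
                else "~ 1",
      k = length(s) + 1L, aic = f$aic, stringsAsFactors = FALSE)
  }
  ok <- !vapply(rows, is.null, logical(1))
  tab <- do.call(rbind, rows[ok])
  fits <- fits[ok]
  ord <- order(tab$aic)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$weight <- exp(-tab$delta_aic / 2) / sum(exp(-tab$delta_aic / 2))
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("pairscape_modeltable", "data.frame")
  tab
}

#' Moran's I test for residual spatial autocorrelation
#'
#' Residuals of the full MLPE model are averaged per site (each site
#' contributes to n-1 pairs); Moran's I is computed with inverse-distance
#' weights (zero diagonal, row-standardised) and its one-sided p-value
#' obtained from `n_perm` random permutations of the site residuals.
#'
#' @param fit a [fit_mlpe()] result for the full model.
#' @param sites a [site_set()] (defaults to the fit's own).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list with `I` (observed statistic), `p` (permutation p-value
#'   in [1/(n_perm+1), 1]), `site_residuals`.
#' @export
residual_autocorrelation <- function(fit, sites = fit$sites, n_perm = 999,
                                     seed = 1L) {
  if (nrow(sites) < 5L) stop("need at least 5 sites", call. = FALSE)
  idx <- pair_index(sites)
  r <- fit$residuals
  sr <- vapply(seq_len(nrow(sites)), function(k)
    mean(r[idx$i == k | idx$j == k]), numeric(1))
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  W <- 1 / d
  diag(W) <- 0
  W <- W / rowSums(W)
  moran <- function(x) {
    z <- x - mean(x)
    nrow(sites) / sum(W) * sum(W * outer(z, z)) / sum(z^2)
  }
  I_obs <- moran(sr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  I_perm <- vapply(seq_len(n_perm), function(k) moran(sample(sr)), numeric(1))
  p <- (1 + sum(I_perm >= I_obs)) / (n_perm + 1)
  list(I = I_obs, p = p, site_residuals = sr)
}

#' Standardise predictor columns to zero mean and unit variance
#'
#' @param X numeric matrix or data frame.
#' @return scaled matrix; constant columns are dropped with a warning.
#' @export
scale_predictors <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    warning("dropping constant/NA predictor columns: ",
            paste(colnames(X)[sds == 0 | is.na(sds)], collapse = ", "))
    X <- X[, !(sds == 0 | is.na(sds)), drop = FALSE]
  }
  scale(X)
}
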