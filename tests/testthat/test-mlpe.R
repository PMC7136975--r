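test_that("Box-Cox picks sensible exponents and exact closed forms", {
  set.seed(1)
  y_ln <- exp(rnorm(2000))
  bc <- boxcox_transform(y_ln)
  expect_true(bc$lambda >= -0.15 && bc$lambda <= 0.15)  # log-normal -> ~0
  # cross-check the profile optimum against MASS::boxcox
  mb <- MASS::boxcox(y_ln ~ 1, lambda = seq(-1, 1, 0.01), plotit = FALSE)
  expect_lt(abs(bc$lambda - mb$x[which.max(mb$y)]), 0.05)

  set.seed(2)
  y_n <- rnorm(2000) + 10
  bc_n <- boxcox_transform(y_n)
  expect_true(bc_n$lambda >= 0.7 && bc_n$lambda <= 1.3)  # already normal

  y <- c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  bc1 <- boxcox_transform(y)
  if (bc1$lambda == 1) expect_equal(bc1$transformed, y + bc1$shift - 1)
  # lambda = 1 transform is y + shift - 1 by construction
  z <- ((y + 0)^1 - 1) / 1
  expect_equal(z, y - 1)
  expect_error(boxcox_transform(rep(1, 20)), "constant")
  # shift makes negative responses positive
  bc_neg <- boxcox_transform(c(-0.5, rnorm(49)))
  expect_gte(min(c(-0.5, rnorm(49)) + bc_neg$shift), 0)
})

test_that("VIF pruning matches a brute-force recompute oracle", {
  ortho <- unclass(poly(1:100, 3))  # orthogonal also to the intercept
  colnames(ortho) <- c("a", "b", "c")
  res <- vif_prune(ortho)
  expect_equal(res$dropped, character(0))
  expect_true(all(abs(res$vif - 1) < 1e-10))

  # exact collinearity: x3 = x1 + x2
  X <- matrix(rnorm(200), 100, 2)
  X <- cbind(X, X[, 1] + X[, 2])
  colnames(X) <- c("x1", "x2", "x3")
  res <- vif_prune(X)
  expect_equal(length(res$dropped), 1)
  expect_true(res$dropped %in% c("x1", "x2", "x3"))
  expect_true(all(res$vif < 10))

  # correlated Gaussians: removal sequence equals the oracle's
  set.seed(4)
  S <- matrix(0.95, 3, 3); diag(S) <- 1
  Xc <- matrix(rnorm(200 * 3), 200, 3) %*% chol(S)
  colnames(Xc) <- c("g1", "g2", "g3")
  oracle <- function(X, thr) {
    dropped <- character(0)
    repeat {
      if (ncol(X) < 2) break
      vifs <- sapply(seq_len(ncol(X)), function(j) {
        r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
        1 / (1 - r2)
      })
      if (max(vifs) < thr) break
      w <- max(which(vifs == max(vifs)))  # ties -> later column
      dropped <- c(dropped, colnames(X)[w])
      X <- X[, -w, drop = FALSE]
    }
    dropped
  }
  expect_equal(vif_prune(Xc)$dropped, oracle(Xc, 10))
  # final VIFs agree with car::vif on a regression including all kept cols
  # final VIFs agree with car::vif on the full column set
  y <- rnorm(200)
  d <- data.frame(y = y, Xc)
  expect_equal(unname(pairscape:::.vif_values(Xc)),
               unname(car::vif(lm(y ~ g1 + g2 + g3, data = d))),
               tolerance = 1e-6)
})

test_that("MLPE profiled likelihood equals the direct MVN likelihood", {
  s <- rand_sites(8, seed = 5)
  set.seed(6)
  X <- matrix(rnorm(28 * 2), 28, 2, dimnames = list(NULL, c("a", "b")))
  y <- simulate_mlpe_response(cbind(1, X), s, c(0.2, 1, -0.5),
                              sigma_u = 0.4, sigma_e = 0.6, seed = 3)
  f <- fit_mlpe(y, X, s, method = "ML")
  ll_direct <- mvn_mlpe_loglik(y, cbind(1, X), s, f$beta, f$sigma_u2,
                               f$sigma_e2)
  expect_equal(f$loglik, ll_direct, tolerance = 1e-8)
  expect_equal(f$aic, -2 * f$loglik + 2 * (3 + 2))

  # the optimum beats 50 random parameter perturbations
  set.seed(7)
  better <- vapply(1:50, function(k) {
    b <- f$beta + rnorm(3, 0, 0.2)
    su <- max(f$sigma_u2 * runif(1, 0.3, 3), 1e-8)
    se <- max(f$sigma_e2 * runif(1, 0.3, 3), 1e-8)
    mvn_mlpe_loglik(y, cbind(1, X), s, b, su, se) > f$loglik + 1e-8
  }, logical(1))
  expect_false(any(better))
})

test_that("theta = 0 reduces MLPE to ordinary least squares", {
  s <- rand_sites(10, seed = 8)
  set.seed(9)
  X <- matrix(rnorm(45 * 2), 45, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(cbind(1, X) %*% c(1, 0.5, -0.3)) + rnorm(45, 0, 0.4)
  f0 <- fit_mlpe(y, X, s, theta_fixed = 0)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(f0$beta - ols)), 1e-8)
  expect_equal(f0$sigma_u2, 0)
})

test_that("planted sigma_u = 0 is recovered at the boundary", {
  # theta-hat under a true zero site variance has half its mass exactly at
  # the boundary and a half-normal spill-over; most replicates should sit
  # at (or within 2% of sigma_e^2 of) zero, with the median exactly 0
  s <- rand_sites(17, seed = 10)
  eig <- eigen(tcrossprod(pairscape:::mlpe_incidence(s)), symmetric = TRUE)
  set.seed(11)
  X <- matrix(rnorm(136), 136, 1, dimnames = list(NULL, "a"))
  theta <- vapply(1:100, function(k) {
    y <- simulate_mlpe_response(cbind(1, X), s, c(0, 1), sigma_u = 0,
                                sigma_e = 1, seed = 1000 + k)
    fit_mlpe(y, X, s, eig = eig)$theta
  }, numeric(1))
  expect_gte(mean(theta <= 0.02), 0.6)
  expect_equal(median(theta), 0)
  expect_lt(mean(theta), 0.05)
})

test_that("dredge enumerates, filters collinear subsets, and ranks", {
  s <- rand_sites(10, seed = 12)
  set.seed(13)
  Xo <- qr.Q(qr(matrix(rnorm(45 * 3), 45, 3)))
  colnames(Xo) <- c("a", "b", "c")
  y <- simulate_mlpe_response(cbind(1, Xo), s, c(0, 1, 0, 0),
                              sigma_u = 0.3, sigma_e = 0.3, seed = 2)
  tab <- dredge_mlpe(y, Xo, s)
  expect_equal(nrow(tab), 8)  # 2^3 subsets, none filtered
  expect_equal(tab$delta_aic[1], 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(tab$aic) >= 0))

  # two highly correlated predictors never co-occur
  set.seed(14)
  x1 <- rnorm(45)
  X2 <- cbind(p = x1, q = x1 + rnorm(45, 0, 0.2), r = rnorm(45))
  stopifnot(abs(cor(X2[, "p"], X2[, "q"])) > 0.9)
  tab2 <- dredge_mlpe(y, X2, s)
  # subset-filter oracle: all subsets minus those holding both p and q
  n_keep <- sum(sapply(0:7, function(m) {
    sel <- as.logical(intToBits(m)[1:3])
    !(sel[1] && sel[2])
  }))
  expect_equal(nrow(tab2), n_keep)
  expect_false(any(grepl("p", tab2$formula) & grepl("q", tab2$formula)))
})

test_that("R2 decomposition and rho follow their plug-in identities", {
  # intercept-only: marginal 0; sigma_u = 0: conditional = marginal
  s <- rand_sites(10, seed = 15)
  y <- simulate_mlpe_response(matrix(1, 45, 1), s, 1, sigma_u = 0.5,
                              sigma_e = 0.5, seed = 4)
  f <- fit_mlpe(y, NULL, s)
  r2 <- r2_nakagawa(f)
  expect_equal(unname(r2["marginal"]), 0)
  expect_equal(dependency_rho(f) <= 0.5, TRUE)

  # planted variance shares: sigma_f2 = 1, 2 sigma_u2 = 1, sigma_e2 = 2
  s30 <- rand_sites(30, seed = 16)
  np <- nrow(pair_index(s30))
  reps <- t(sapply(1:20, function(k) {
    set.seed(100 + k)
    x <- rnorm(np)  # unit-variance predictor, beta = 1 -> sigma_f2 = 1
    y <- simulate_mlpe_response(cbind(1, x), s30, c(0, 1),
                                sigma_u = sqrt(0.5), sigma_e = sqrt(2),
                                seed = 200 + k)
    f <- fit_mlpe(y, matrix(x, dimnames = list(NULL, "x")), s30,
                  method = "REML")
    c(r2_nakagawa(f), rho = dependency_rho(f))
  }))
  expect_lt(abs(mean(reps[, "marginal"]) - 0.25), 0.05)
  expect_lt(abs(mean(reps[, "conditional"]) - 0.5), 0.05)
  # rho = sigma_u2 / (2 sigma_u2 + sigma_e2) = 0.5 / 3
  expect_lt(abs(mean(reps[, "rho"]) - 0.5 / 3), 0.05)

  # closed forms
  f$sigma_u2 <- 0.3; f$sigma_e2 <- 0.3; f$method <- "REML"
  expect_equal(dependency_rho(f), 1 / 3)
  f$sigma_u2 <- 0
  expect_equal(dependency_rho(f), 0)
})

test_that("rho matches the empirical shared-site residual correlation", {
  s30 <- rand_sites(30, seed = 17)
  idx <- pair_index(s30)
  np <- nrow(idx)
  # all pairs of observations sharing exactly one site
  set.seed(18)
  take <- sample(np, 60)
  shared <- list()
  for (a in take) for (b in take) {
    if (a < b) {
      common <- length(intersect(c(idx$i[a], idx$j[a]),
                                 c(idx$i[b], idx$j[b])))
      if (common == 1) shared[[length(shared) + 1]] <- c(a, b)
    }
  }
  shared <- do.call(rbind, shared)
  sims <- sapply(1:300, function(k)
    simulate_mlpe_response(matrix(1, np, 1), s30, 0, sigma_u = 0.5,
                           sigma_e = 0.5, seed = 3000 + k))
  v1 <- as.vector(sims[shared[, 1], ])
  v2 <- as.vector(sims[shared[, 2], ])
  rho_true <- 0.25 / (2 * 0.25 + 0.25)
  expect_lt(abs(cor(v1, v2) - rho_true), 0.05)
})

test_that("Moran's I permutation test is calibrated and powered", {
  s <- rand_sites(17, seed = 19)
  np <- nrow(pair_index(s))
  eig <- eigen(tcrossprod(pairscape:::mlpe_incidence(s)), symmetric = TRUE)
  # bounds of the permutation p-value
  y <- simulate_mlpe_response(matrix(1, np, 1), s, 0, 0.3, 0.5, seed = 1)
  f <- fit_mlpe(y, NULL, s, eig = eig)
  m <- residual_autocorrelation(f, n_perm = 99, seed = 2)
  expect_gte(m$p, 1 / 100)
  expect_lte(m$p, 1)
  # observed statistic agrees with the ape implementation
  W <- 1 / as.matrix(dist(cbind(s$x, s$y)))
  diag(W) <- 0
  W <- W / rowSums(W)
  expect_equal(m$I, ape::Moran.I(m$site_residuals, W)$observed,
               tolerance = 1e-12)

  # power: site residuals trending in x are detected
  idx <- pair_index(s)
  hits <- vapply(1:30, function(k) {
    set.seed(400 + k)
    trend <- scale(s$x)[, 1]
    y <- trend[idx$i] + trend[idx$j] + rnorm(np, 0, 0.1)
    f <- fit_mlpe(y, NULL, s, eig = eig, theta_fixed = 0)
    residual_autocorrelation(f, n_perm = 199, seed = k)$p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(residual_autocorrelation(f, sites = rand_sites(4)), "5 sites")
})
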