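test_that("surface generator is seeded, bounded, and roughness-controlled", {
  a <- generate_surface(32, 32, hurst = 0.5, seed = 3)
  b <- generate_surface(32, 32, hurst = 0.5, seed = 3)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0 & a$values <= 1))
  expect_error(generate_surface(32, 32, hurst = 1.2), "hurst")
  expect_error(generate_surface(8, 8), "16")

  # high hurst = smoother: smaller mean |increment| and steeper PSD slope,
  # measured with an independent periodogram regression
  psd_slope <- function(r) {
    z <- r$values - mean(r$values)
    P <- Mod(fft(z))^2
    n <- nrow(z)
    f <- pairscape:::fft_freq(n)
    ring <- round(sqrt(outer(f^2, f^2, `+`)) * n)
    keep <- ring >= 2 & ring <= n / 4
    pr <- tapply(P[keep], ring[keep], mean)
    unname(coef(lm(log(pr) ~ log(as.numeric(names(pr)))))[2])
  }
  smooth <- generate_surface(256, 256, hurst = 0.9, seed = 2)
  rough <- generate_surface(256, 256, hurst = 0.2, seed = 2)
  expect_lt(mean(abs(diff(smooth$values))), mean(abs(diff(rough$values))))
  expect_lt(psd_slope(smooth), psd_slope(rough))  # steeper (more negative)
  # slope recovers -(2 hurst + 2) within 0.4
  expect_lt(abs(psd_slope(smooth) - (-3.8)), 0.4)
  expect_lt(abs(psd_slope(rough) - (-2.4)), 0.4)
})

test_that("land-cover classification thresholds correctly", {
  const <- raster_grid(matrix(0.9, 4, 4))
  expect_true(all(classify_landcover(const, c(0.3, 0.6))$values == 1))
  set.seed(5)
  unif <- raster_grid(matrix(runif(128 * 128), 128, 128))
  cls <- classify_landcover(unif, c(1 / 3, 2 / 3))$values
  n <- length(cls)
  shares <- tabulate(cls, 3) / n
  # each share within 3 binomial standard errors of 1/3
  tol <- 3 * sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(shares - 1 / 3) < tol))
  expect_error(classify_landcover(unif, c(0.7, 0.3)), "breaks")
})

test_that("moving-window mean matches direct summation and handles NA", {
  const <- raster_grid(matrix(4.2, 6, 6), cell_size = 10)
  expect_equal(moving_window_mean(const, 30)$values, const$values)

  r <- rand_raster(3, 3, seed = 2, cell_size = 10)
  mw <- moving_window_mean(r, 30)
  expect_equal(mw$values[2, 2], mean(r$values))

  r <- rand_raster(5, 5, seed = 4, cell_size = 10)
  r$values[3, 3] <- NA
  r <- raster_grid(r$values, cell_size = 10)
  mw <- moving_window_mean(r, 30)
  # direct summation oracle at a neighbour of the NA cell
  win <- r$values[1:3, 1:3]
  expect_equal(mw$values[2, 2], mean(win, na.rm = TRUE))
  expect_true(is.na(mw$values[3, 3]))  # masked stays masked
  expect_error(moving_window_mean(r, 200), "larger than raster")
})

test_that("site placement respects separation and is seed-deterministic", {
  r <- generate_surface(256, 256, seed = 1, cell_size = 30)
  s <- place_sites(r, n = 17, min_sep = 10 * 30, seed = 9)
  expect_equal(nrow(s), 17)
  expect_equal(nrow(pair_index(s)), 136)
  expect_true(min(dist(cbind(s$x, s$y))) >= 300)
  expect_identical(place_sites(r, 17, 300, seed = 9), s)
  s1 <- place_sites(r, n = 1, min_sep = 300, seed = 2)
  expect_equal(nrow(s1), 1)
  expect_error(place_sites(r, n = 3, min_sep = 1e9, max_tries = 200),
               "infeasible")
})

test_that("planted MLPE response has the advertised moments", {
  s <- rand_sites(10, seed = 3)
  idx <- pair_index(s)
  X <- cbind(1, scale(idx$i + idx$j), scale(idx$i * idx$j))
  beta <- c(0.5, 1, -2)
  # noise-free limit reproduces the linear predictor
  y0 <- simulate_mlpe_response(X, s, beta, sigma_u = 0, sigma_e = 1e-8,
                               seed = 1)
  expect_lt(max(abs(y0 - X %*% beta)), 1e-6)
  expect_identical(simulate_mlpe_response(X, s, beta, seed = 5),
                   simulate_mlpe_response(X, s, beta, seed = 5))
  expect_error(simulate_mlpe_response(X[1:5, ], s, beta), "pair universe")

  # cov(y_ij, y_ik) = sigma_u^2 for pairs sharing one site
  share <- which(idx$i[1] == idx$i | idx$j[1] == idx$i |
                   idx$i[1] == idx$j | idx$j[1] == idx$j)
  share <- setdiff(share, 1)[1]
  draws <- vapply(1:500, function(k)
    simulate_mlpe_response(X[, 1, drop = FALSE], s, 0, sigma_u = 1,
                           sigma_e = 1, seed = k)[c(1, share)],
    numeric(2))
  expect_lt(abs(cov(draws[1, ], draws[2, ]) - 1), 3 * sqrt(3 / 500) + 0.05)
})

test_that("microsatellite simulator differentiates with isolation", {
  s <- site_set(c("A", "B", "C", "D"), c(0, 1e4, 0, 1e4), c(0, 0, 1e4, 1e4))
  pan <- vapply(1:8, function(k) {
    g <- simulate_microsatellites(s, n_ind_per_site = 20, n_loci = 5,
                                  migration_scale = Inf,
                                  mutation_rate = 1e-3,
                                  n_generations = 40, seed = k)
    m <- rst_matrix(g)
    mean(m[upper.tri(m)])
  }, numeric(1))
  expect_lte(mean(pan), 0.02)

  iso <- vapply(1:8, function(k) {
    g <- simulate_microsatellites(s, n_ind_per_site = 20, n_loci = 5,
                                  migration_scale = 1,  # << min distance
                                  mutation_rate = 1e-3,
                                  n_generations = 40, seed = k)
    m <- rst_matrix(g)
    mean(m[upper.tri(m)])
  }, numeric(1))
  # drift under isolation exceeds the panmictic level (one-sided)
  expect_gt(mean(iso), mean(pan))
  expect_gt(t.test(iso, pan, alternative = "greater")$statistic, 0)

  g1 <- simulate_microsatellites(s, 5, 2, 1e4, 1e-3, 5, seed = 11)
  g2 <- simulate_microsatellites(s, 5, 2, 1e4, 1e-3, 5, seed = 11)
  expect_identical(g1, g2)
})
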