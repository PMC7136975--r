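#' Generate a fractional-Brownian habitat-suitability surface
#'
#' Spectral synthesis: white Gaussian noise is filtered in the Fourier
#' domain with radial amplitude `f^-(hurst + 1)`, giving a field whose
#' power spectral density falls off as `f^-beta` with
#' `beta = 2 * hurst + 2`. The inverse transform is real because the
#' filter preserves the Hermitian symmetry of the noise spectrum. The
#' result is min-max rescaled to [0, 1], mimicking a continuous
#' habitat-suitability model.
#'
#' @param nrows,ncols grid dimensions (each >= 16).
#' @param hurst roughness exponent in (0, 1); larger = smoother.
#' @param cell_size cell edge length in metres.
#' @param seed integer RNG seed; output is a pure function of the arguments.
#' @return a [raster_grid()] with values in [0, 1].
#' @export
generate_surface <- function(nrows, ncols, hurst = 0.5, cell_size = 30,
                             seed = 1L) {
  if (hurst <= 0 || hurst >= 1) stop("hurst must be in (0, 1)", call. = FALSE)
  if (nrows < 16L || ncols < 16L) {
    stop("spectral synthesis needs at least a 16 x 16 grid", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
  fu <- fft_freq(nrows)
  fv <- fft_freq(ncols)
  r <- sqrt(outer(fu^2, fv^2, `+`))
  amp <- r^(-(hurst + 1))
  amp[1, 1] <- 0  # zero the DC component
  z <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (nrows * ncols)
  z <- (z - min(z)) / (max(z) - min(z))
  raster_grid(z, cell_size = cell_size, origin = c(0, nrows * cell_size))
}

# DFT frequencies in cycles per sample, fftshift-free ordering
fft_freq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Threshold a continuous surface into a three-class land-cover mosaic
#'
#' Emulates reclassifying a land-cover map into forest habitat
#' (class 1), complementary habitat such as shrubland, grassland or
#' pasture (class 2), and non-habitat (class 3): cells with suitability
#' below `t1` become class 3, `[t1, t2)` class 2, and `>= t2` class 1.
#'
#' @param surface a [raster_grid()] with values in [0, 1].
#' @param breaks numeric length 2, thresholds `0 < t1 < t2 < 1`.
#' @return a categorical [raster_grid()] with integer classes 1..3.
#' @export
classify_landcover <- function(surface, breaks = c(1 / 3, 2 / 3)) {
  t1 <- breaks[1]; t2 <- breaks[2]
  if (!(t1 > 0 && t1 < t2 && t2 < 1)) {
    stop("breaks must satisfy 0 < t1 < t2 < 1", call. = FALSE)
  }
  v <- surface$values
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  cls[v < t1] <- 3
  cls[v >= t1 & v < t2] <- 2
  cls[v >= t2] <- 1
  raster_grid(cls, cell_size = surface$cell_size, origin = surface$origin,
              nodata_mask = surface$nodata_mask)
}

#' Square moving-window (focal) mean
#'
#' Each cell receives the mean of the valid cells in the centred square
#' window of the given edge length; the edge is rounded to the nearest odd
#' number of cells. Masked cells stay masked. Implemented with summed-area
#' tables so cost is independent of window size.
#'
#' @param layer a [raster_grid()].
#' @param window_edge window edge length in metres (>= cell_size).
#' @return a [raster_grid()] of focal means.
#' @export
moving_window_mean <- function(layer, window_edge) {
  cs <- layer$cell_size
  if (window_edge < cs) stop("window_edge must be >= cell_size", call. = FALSE)
  k <- round(window_edge / cs)
  if (k %% 2 == 0) k <- k + 1L
  h <- (k - 1L) / 2L
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  if (k > nr || k > nc) stop("window larger than raster", call. = FALSE)
  v <- layer$values
  valid <- !layer$nodata_mask
  v0 <- ifelse(valid, v, 0)
  sat <- function(m) {  # summed-area table with zero-padded first row/col
    s <- apply(apply(m, 2, cumsum), 1, cumsum)  # t(cumsum both ways)
    rbind(0, cbind(0, t(s)))
  }
  S <- sat(v0); C <- sat(valid + 0)
  r1 <- pmax(1L, seq_len(nr) - h); r2 <- pmin(nr, seq_len(nr) + h)
  c1 <- pmax(1L, seq_len(nc) - h); c2 <- pmin(nc, seq_len(nc) + h)
  boxsum <- function(A) {
    A[r2 + 1L, c2 + 1L, drop = FALSE] - A[r1, c2 + 1L, drop = FALSE] -
      A[r2 + 1L, c1, drop = FALSE] + A[r1, c1, drop = FALSE]
  }
  means <- boxsum(S) / pmax(boxsum(C), 1)
  means[boxsum(C) == 0] <- NA_real_
  means[!valid] <- NA_real_
  raster_grid(means, cell_size = cs, origin = layer$origin,
              nodata_mask = layer$nodata_mask)
}

#' Place sampling sites with a minimum separation
#'
#' Rejection sampling on valid cells: candidate cell centres are drawn
#' uniformly and accepted when at least `min_sep` from every accepted
#' site. Deterministic given `seed`.
#'
#' @param raster a [raster_grid()]; sites land on valid cell centres.
#' @param n number of sites.
#' @param min_sep minimum pairwise separation in metres.
#' @param seed integer RNG seed.
#' @param max_tries rejection-sampling budget.
#' @return a [site_set()] with ids `S01`, `S02`, ...
#' @export
place_sites <- function(raster, n, min_sep, seed = 1L, max_tries = 10000L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ok <- which(!raster$nodata_mask, arr.ind = TRUE)
  if (nrow(ok) < n) stop("not enough valid cells", call. = FALSE)
  xy <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "site placement infeasible: %d of %d sites placed in %d tries; reduce min_sep",
        placed, n, max_tries), call. = FALSE)
    }
    cand <- ok[sample.int(nrow(ok), 1L), ]
    p <- cell_centers(raster, cand[1], cand[2])
    if (placed == 0L ||
        all(sqrt((xy[seq_len(placed), 1] - p[1])^2 +
                 (xy[seq_len(placed), 2] - p[2])^2) >= min_sep)) {
      placed <- placed + 1L
      xy[placed, ] <- p
    }
  }
  site_set(sprintf("S%02d", seq_len(n)), xy[, 1], xy[, 2])
}

#' Simulate a pairwise response with planted MLPE structure
#'
#' Draws `y_ij = X beta + u_i + u_j + e_ij` with site effects
#' `u_k ~ N(0, sigma_u^2)` and pair residuals `e_ij ~ N(0, sigma_e^2)`,
#' the generative counterpart of the MLPE mixed model: every pair inherits
#' one random effect from each of its two member sites, so pairs sharing a
#' site are correlated.
#'
#' @param X numeric matrix of predictors *including* an intercept column,
#'   one row per unordered pair in [pair_index()] order.
#' @param sites a [site_set()].
#' @param beta fixed-effect coefficients, `length(beta) == ncol(X)`.
#' @param sigma_u site random-effect standard deviation (>= 0).
#' @param sigma_e residual standard deviation (> 0).
#' @param seed integer RNG seed.
#' @return numeric response vector, one value per pair.
#' @export
simulate_mlpe_response <- function(X, sites, beta, sigma_u = 0.5,
                                   sigma_e = 0.5, seed = 1L) {
  X <- as.matrix(X)
  idx <- pair_index(sites)
  if (nrow(X) != nrow(idx)) {
    stop(sprintf("X has %d rows but the pair universe has %d", nrow(X),
                 nrow(idx)), call. = FALSE)
  }
  if (ncol(X) != length(beta)) stop("length(beta) must equal ncol(X)", call. = FALSE)
  if (sigma_u < 0 || sigma_e <= 0) {
    stop("need sigma_u >= 0 and sigma_e > 0", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- stats::rnorm(nrow(sites), 0, sigma_u)
  e <- stats::rnorm(nrow(idx), 0, sigma_e)
  drop(X %*% beta) + u[idx$i] + u[idx$j] + e
}

#' Forward-simulate microsatellite genotypes under migration by distance
#'
#' A finite-island model simulated forward in time: each population starts
#' from a common founder pool (five alleles per locus, repeat sizes 10,
#' 12, 14, 16, 18, equal frequency — a dinucleotide ladder). Every
#' generation each offspring draws its two parental alleles from a source
#' population chosen with probability proportional to
#' `exp(-d_ij / migration_scale)` (the self term has weight 1 since
#' `d_ii = 0`), then each allele mutates with probability `mutation_rate`
#' by a stepwise +1/-1 repeat change. Large `migration_scale` approaches
#' panmixia; `migration_scale` far below the inter-site distances isolates
#' populations so drift builds differentiation.
#'
#' @param sites a [site_set()]; populations take the site labels.
#' @param n_ind_per_site diploid individuals per population.
#' @param n_loci number of unlinked microsatellite loci.
#' @param migration_scale distance scale of migration decay (metres);
#'   `Inf` gives uniform source choice (panmixia).
#' @param mutation_rate per-allele per-generation stepwise mutation
#'   probability.
#' @param n_generations generations simulated forward.
#' @param seed integer RNG seed.
#' @return long-format genotype data frame with columns `individual_id`,
#'   `population_id`, `locus`, `allele1`, `allele2` (integer repeat sizes).
#' @export
simulate_microsatellites <- function(sites, n_ind_per_site = 25,
                                     n_loci = 10, migration_scale = 2e4,
                                     mutation_rate = 5e-4,
                                     n_generations = 100, seed = 1L) {
  stopifnot(n_ind_per_site > 0, n_loci > 0, n_generations > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  npop <- nrow(sites)
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  w <- if (is.infinite(migration_scale)) matrix(1, npop, npop) else
    exp(-d / migration_scale)
  w <- sweep(w, 1, rowSums(w), `/`)  # row i = source distribution for pop i
  founders <- c(10L, 12L, 14L, 16L, 18L)
  # alleles[pop][[locus]] = integer vector of 2 * n_ind allele copies
  n_al <- 2L * n_ind_per_site
  alleles <- lapply(seq_len(npop), function(p)
    lapply(seq_len(n_loci), function(l) sample(founders, n_al, replace = TRUE)))
  for (gen in seq_len(n_generations)) {
    nxt <- vector("list", npop)
    for (p in seq_len(npop)) {
      src <- sample.int(npop, n_al, replace = TRUE, prob = w[p, ])
      nxt[[p]] <- lapply(seq_len(n_loci), function(l) {
        a <- integer(n_al)
        for (s in unique(src)) {
          pick <- src == s
          a[pick] <- sample(alleles[[s]][[l]], sum(pick), replace = TRUE)
        }
        mut <- stats::runif(n_al) < mutation_rate
        if (any(mut)) {
          a[mut] <- a[mut] + sample(c(-1L, 1L), sum(mut), replace = TRUE)
        }
        a
      })
    }
    alleles <- nxt
  }
  rows <- vector("list", npop)
  for (p in seq_len(npop)) {
    ind <- rep(seq_len(n_ind_per_site), times = n_loci)
    loc <- rep(seq_len(n_loci), each = n_ind_per_site)
    a1 <- unlist(lapply(alleles[[p]], function(a) a[2 * seq_len(n_ind_per_site) - 1L]))
    a2 <- unlist(lapply(alleles[[p]], function(a) a[2 * seq_len(n_ind_per_site)]))
    rows[[p]] <- data.frame(
      individual_id = sprintf("%s_i%03d", sites$site_id[p], ind),
      population_id = sites$site_id[p],
      locus = sprintf("L%02d", loc),
      allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
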