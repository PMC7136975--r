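#' Amplitude metrics: Sa, S10, Ssk
#'
#' Heights `z` are measured from the mean of valid cells.
#' * `Sa` — average surface roughness, `mean(|z|)`.
#' * `Ssk` — skewness, `mean(z^3) / Sq^3` with `Sq = sqrt(mean(z^2))`.
#' * `S10` — ten-point height: the five largest local-maximum heights plus
#'   the five largest local-minimum depths (strict 8-neighbour extrema over
#'   valid cells), divided by 5; if fewer than five extrema exist on a
#'   side, all available are used and the divisor stays 5.
#'
#' @param surface a [raster_grid()] with a continuous variable.
#' @return named list with `Sa`, `S10`, `Ssk` (`Ssk` is `NA` with a
#'   warning on a zero-variance surface).
#' @export
amplitude_metrics <- function(surface) {
  v <- surface$values
  valid <- !surface$nodata_mask
  zv <- v[valid]
  if (length(zv) < 9L) stop("need at least 9 valid cells", call. = FALSE)
  z <- v - mean(zv)
  zval <- z[valid]
  sa <- mean(abs(zval))
  sq <- sqrt(mean(zval^2))
  ssk <- if (sq > 0) mean(zval^3) / sq^3 else {
    warning("zero-variance surface: Ssk undefined")
    NA_real_
  }
  ext <- local_extrema(z, valid)
  peaks <- sort(ext$max_heights, decreasing = TRUE)
  pits <- sort(abs(ext$min_heights), decreasing = TRUE)
  s10 <- (sum(utils::head(peaks, 5L)) + sum(utils::head(pits, 5L))) / 5
  list(Sa = sa, S10 = s10, Ssk = ssk)
}

# strict 8-neighbour local maxima/minima over valid cells
local_extrema <- function(z, valid) {
  nr <- nrow(z); nc <- ncol(z)
  zp <- matrix(NA_real_, nr + 2L, nc + 2L)
  zp[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(valid, z, NA_real_)
  ctr <- zp[2:(nr + 1L), 2:(nc + 1L)]
  is_max <- valid
  is_min <- valid
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- zp[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    cmp_max <- is.na(nb) | ctr > nb
    cmp_min <- is.na(nb) | ctr < nb
    is_max <- is_max & cmp_max
    is_min <- is_min & cmp_min
  }
  list(max_heights = ctr[which(is_max)], min_heights = ctr[which(is_min)])
}

#' Surface area ratio Sdr
#'
#' Each 2x2 quad of valid cell centres is split into two 3-D triangles
#' (x, y in metres, z in the surface's native units);
#' `Sdr = 100 * (A_surface - A_plan) / A_plan` over quads whose four cells
#' are all valid. A flat surface gives 0.
#'
#' @param surface a [raster_grid()].
#' @return Sdr in percent (>= 0).
#' @export
sdr <- function(surface) {
  v <- surface$values
  valid <- !surface$nodata_mask
  nr <- nrow(v); nc <- ncol(v)
  h <- surface$cell_size
  z00 <- v[-nr, -nc]; z01 <- v[-nr, -1]; z10 <- v[-1, -nc]; z11 <- v[-1, -1]
  ok <- valid[-nr, -nc] & valid[-nr, -1] & valid[-1, -nc] & valid[-1, -1]
  if (!any(ok)) stop("no complete 2x2 quad of valid cells", call. = FALSE)
  tri_area <- function(dz1x, dz1y, dz1z, dz2x, dz2y, dz2z) {
    # 0.5 * |cross product|
    cx <- dz1y * dz2z - dz1z * dz2y
    cy <- dz1z * dz2x - dz1x * dz2z
    cz <- dz1x * dz2y - dz1y * dz2x
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  # triangle 1: (0,0)-(0,1)-(1,1); triangle 2: (0,0)-(1,0)-(1,1)
  a1 <- tri_area(h, 0, z01 - z00, h, -h, z11 - z00)
  a2 <- tri_area(0, -h, z10 - z00, h, -h, z11 - z00)
  a_surf <- sum((a1 + a2)[ok])
  a_plan <- sum(ok) * h^2
  100 * (a_surf - a_plan) / a_plan
}

# 2-D Hann taper, Fourier amplitude/power spectra and coordinates.
# Masked cells are filled with the valid-cell mean (adds no power).
surface_spectrum <- function(surface, taper = TRUE) {
  v <- surface$values
  valid <- !surface$nodata_mask
  if (nrow(v) < 16L || ncol(v) < 16L) {
    stop("spectral metrics need at least a 16 x 16 grid", call. = FALSE)
  }
  mu <- mean(v[valid])
  z <- ifelse(valid, v, mu) - mu
  if (max(abs(z)) == 0) stop("texture undefined on a constant surface", call. = FALSE)
  nr <- nrow(z); nc <- ncol(z)
  if (taper) {
    hr <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
    hc <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
    z <- z * outer(hr, hc)
  }
  F <- stats::fft(z)
  A <- Mod(F)
  fu <- fft_freq(nr)  # cycles/sample along rows (southward axis)
  fv <- fft_freq(nc)  # cycles/sample along columns (eastward axis)
  k_east <- outer(rep(1, nr), fv)
  k_north <- outer(-fu, rep(1, nc))  # row index increases southward
  theta <- (atan2(k_north, k_east) * 180 / pi) %% 180
  n_ref <- min(nr, nc)
  radius <- sqrt(outer(fu^2, fv^2, `+`)) * n_ref  # ring units of the short axis
  A[1, 1] <- 0  # exclude DC
  list(A = A, theta = theta, radius = radius, nyquist = floor(n_ref / 2))
}

#' Fourier texture metrics: Std, Stdi, Srwi, Sfd
#'
#' The surface is mean-centred, masked cells are filled with the
#' valid-cell mean, a Hann taper is applied, and the 2-D amplitude
#' spectrum computed (DC excluded).
#' * `Std` — dominant texture direction: amplitudes are averaged within
#'   1-degree bins of spectral angle (0 = east, measured towards north,
#'   modulo 180); Std is the angle of the maximal bin (first maximum on
#'   ties, so ties resolve to the smallest angle). Averaging rather than
#'   summing keeps the angular spectrum flat under isotropy despite the
#'   unequal number of lattice frequencies per bin.
#' * `Stdi` — texture direction index: mean over occupied angle bins of
#'   the binned amplitude, divided by its maximum. Near 1 for isotropic
#'   texture, small when one direction dominates.
#' * `Srwi` — radial wave index: mean amplitude per unit-width annulus of
#'   spectral radius, averaged over annuli up to the Nyquist ring, divided
#'   by its maximum. Near 1 when no wavelength dominates.
#' * `Sfd` — fractal dimension from the periodogram: ordinary least
#'   squares of log radially-averaged power on log radius over rings
#'   `[2, Nyquist/2]`; with slope `s`, `Sfd = 4 + s / 2`, so a
#'   fractional-Brownian surface with roughness exponent `H` gives
#'   `Sfd = 3 - H`.
#'
#' @param surface a [raster_grid()].
#' @param taper apply the Hann window (default `TRUE`).
#' @return named list with `Std` (degrees), `Stdi`, `Srwi`, `Sfd`.
#' @export
fourier_texture_metrics <- function(surface, taper = TRUE) {
  sp <- surface_spectrum(surface, taper = taper)
  nz <- matrix(TRUE, nrow(sp$A), ncol(sp$A))
  nz[1, 1] <- FALSE  # exclude DC
  # mean (not sum) per bin: bins hold unequal numbers of lattice
  # frequencies, so sums would peak on the axes even for isotropic texture
  ang_bin <- floor(sp$theta) %% 180
  Fth <- tapply(sp$A[nz], ang_bin[nz], mean)
  std <- as.numeric(names(Fth)[which.max(Fth)])
  stdi <- mean(Fth) / max(Fth)
  ring <- round(sp$radius)
  keep <- nz & ring >= 1 & ring <= sp$nyquist
  Gr <- tapply(sp$A[keep], ring[keep], mean)
  srwi <- mean(Gr) / max(Gr)
  # radially averaged power for the fractal slope
  P <- sp$A^2
  lo <- 2; hi <- max(lo + 2, floor(sp$nyquist / 2))
  fit_keep <- nz & ring >= lo & ring <= hi
  Pr <- tapply(P[fit_keep], ring[fit_keep], mean)
  r_mid <- as.numeric(names(Pr))
  ok <- Pr > 0
  s <- stats::coef(stats::lm(log(Pr[ok]) ~ log(r_mid[ok])))[2]
  list(Std = std, Stdi = unname(stdi), Srwi = unname(srwi),
       Sfd = unname(4 + s / 2))
}

#' Surface bearing index Sbi
#'
#' The bearing-area (Abbott) curve plots heights sorted in descending
#' order against cumulative area fraction; `z05` is the (mean-referenced)
#' height at bearing fraction 0.05, found by linear interpolation, and
#' `Sbi = Sq / z05`. Invariant to adding a constant or rescaling the
#' surface; about `1 / 1.6449 = 0.608` for Gaussian heights.
#'
#' @param surface a [raster_grid()].
#' @return Sbi (scalar).
#' @export
sbi <- function(surface) {
  zv <- raster_values(surface)
  if (length(zv) < 100L) stop("need at least 100 valid cells", call. = FALSE)
  z <- zv - mean(zv)
  sq <- sqrt(mean(z^2))
  if (sq == 0) stop("zero-variance surface: Sbi undefined", call. = FALSE)
  zs <- sort(z, decreasing = TRUE)
  n <- length(zs)
  frac <- (seq_len(n) - 0.5) / n
  z05 <- stats::approx(frac, zs, xout = 0.05, rule = 2)$y
  if (z05 <= 0) stop("top 5% of the bearing curve lies below the mean: Sbi undefined",
                     call. = FALSE)
  sq / z05
}

#' The nine-metric gradient surface vector
#'
#' Assembles `Sa`, `S10`, `Ssk`, `Sdr`, `Std`, `Stdi`, `Srwi`, `Sfd`,
#' `Sbi` for one (possibly ellipse-clipped) continuous surface.
#' Components whose preconditions fail propagate as `NA` with a warning.
#'
#' @param surface a [raster_grid()].
#' @param taper passed to [fourier_texture_metrics()].
#' @return named numeric vector of the nine metrics.
#' @export
gsm_vector <- function(surface, taper = TRUE) {
  out <- c(Sa = NA_real_, S10 = NA_real_, Ssk = NA_real_, Sdr = NA_real_,
           Std = NA_real_, Stdi = NA_real_, Srwi = NA_real_, Sfd = NA_real_,
           Sbi = NA_real_)
  amp <- tryCatch(amplitude_metrics(surface),
                  error = function(e) { warning(conditionMessage(e)); NULL })
  if (!is.null(amp)) out[c("Sa", "S10", "Ssk")] <- unlist(amp)
  out["Sdr"] <- tryCatch(sdr(surface),
                         error = function(e) { warning(conditionMessage(e)); NA_real_ })
  tex <- tryCatch(fourier_texture_metrics(surface, taper = taper),
                  error = function(e) { warning(conditionMessage(e)); NULL })
  if (!is.null(tex)) out[c("Std", "Stdi", "Srwi", "Sfd")] <- unlist(tex)
  out["Sbi"] <- tryCatch(sbi(surface),
                         error = function(e) { warning(conditionMessage(e)); NA_real_ })
  out
}

#' Gradient surface metrics for every pairwise clip
#'
#' @param clips list of clipped rasters from [pairwise_clips()].
#' @param sites a [site_set()] fixing the pair order.
#' @return data frame: `site_i`, `site_j` plus the nine metric columns.
#' @export
gsm_table <- function(clips, sites) {
  idx <- pair_index(sites)
  stopifnot(length(clips) == nrow(idx))
  m <- t(vapply(clips, function(cl) suppressWarnings(gsm_vector(cl)),
                numeric(9)))
  cbind(idx[, c("site_i", "site_j")], as.data.frame(m))
}
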