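#' Ellipse parameters for a pairwise local landscape
#'
#' @param center numeric (x, y) in metres.
#' @param a,b semi-major and semi-minor axes in metres, `a >= b > 0`.
#' @param orientation major-axis bearing in radians (angle from the +x
#'   axis, mathematical convention).
#' @return list of class `pairscape_ellipse`.
#' @export
ellipse_params <- function(center, a, b, orientation) {
  if (!(a >= b && b > 0)) stop("need a >= b > 0", call. = FALSE)
  structure(list(center = as.numeric(center), a = a, b = b,
                 orientation = orientation), class = "pairscape_ellipse")
}

#' Deterministic pairwise ellipse from an axis ratio
#'
#' Places the ellipse midway between the two sites with its major axis on
#' the inter-site bearing, `a = (d / 2) * (1 + pad)` and
#' `b = a * axis_ratio`. A deterministic stand-in for the correlated
#' random-walk envelope used to delineate the local landscape an animal
#' traverses between two sites; both sites always fall inside.
#'
#' @param p_i,p_j numeric (x, y) of the two sites, distinct.
#' @param axis_ratio `b / a` in (0, 1].
#' @param pad fractional padding of the semi-major axis beyond `d / 2`.
#' @return an [ellipse_params()].
#' @export
ellipse_from_axis_ratio <- function(p_i, p_j, axis_ratio = 0.5, pad = 0.1) {
  if (!(axis_ratio > 0 && axis_ratio <= 1)) {
    stop("axis_ratio must be in (0, 1]", call. = FALSE)
  }
  dx <- p_j[1] - p_i[1]; dy <- p_j[2] - p_i[2]
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) stop("coincident sites: ellipse undefined", call. = FALSE)
  a <- d / 2 * (1 + pad)
  ellipse_params(center = c((p_i[1] + p_j[1]) / 2, (p_i[2] + p_j[2]) / 2),
                 a = a, b = a * axis_ratio, orientation = atan2(dy, dx))
}

#' Pairwise ellipse from a correlated-random-walk envelope
#'
#' Simulates correlated random walks starting at site i (wrapped-normal
#' turning angles with concentration `kappa`, lognormal step lengths). A
#' walk succeeds when it enters the arrival tolerance of site j within
#' `max_steps`. Positions of all successful walks are pooled; the ellipse
#' keeps the midpoint centre and inter-site orientation, with `a` and `b`
#' set to the `q`-quantiles of the absolute projections of pooled
#' positions onto the major/minor axes (measured from the centre), floored
#' so both sites stay inside.
#'
#' @param p_i,p_j site coordinates (metres).
#' @param n_walks walks attempted.
#' @param kappa turning-angle concentration (wrapped-normal `1/sd^2`
#'   scale); larger = straighter walks.
#' @param step_meanlog,step_sdlog lognormal step-length parameters
#'   (metres on the natural scale).
#' @param max_steps maximum steps per walk.
#' @param arrival_tol arrival tolerance radius around site j (metres).
#' @param q coverage quantile in (0, 1] for the envelope axes.
#' @param seed integer RNG seed.
#' @return an [ellipse_params()] with attribute `n_success`.
#' @export
crw_ellipse <- function(p_i, p_j, n_walks = 100, kappa = 5,
                        step_meanlog = log(50), step_sdlog = 0.5,
                        max_steps = 1000, arrival_tol = 100, q = 0.95,
                        seed = 1L) {
  stopifnot(q > 0, q <= 1)
  dx <- p_j[1] - p_i[1]; dy <- p_j[2] - p_i[2]
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) stop("coincident sites", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bearing <- atan2(dy, dx)
  turn_sd <- 1 / sqrt(kappa)
  pooled <- vector("list", n_walks)
  n_success <- 0L
  for (w in seq_len(n_walks)) {
    pos <- matrix(NA_real_, max_steps + 1L, 2)
    pos[1, ] <- p_i
    heading <- bearing  # start headed at the target
    success <- FALSE
    for (s in seq_len(max_steps)) {
      heading <- heading + stats::rnorm(1, 0, turn_sd)
      step <- stats::rlnorm(1, step_meanlog, step_sdlog)
      pos[s + 1L, ] <- pos[s, ] + step * c(cos(heading), sin(heading))
      if (sum((pos[s + 1L, ] - p_j)^2) <= arrival_tol^2) {
        success <- TRUE
        pos <- pos[seq_len(s + 1L), , drop = FALSE]
        break
      }
    }
    if (success) {
      n_success <- n_success + 1L
      pooled[[n_success]] <- pos
    }
  }
  if (n_success == 0L) {
    stop("no successful walk within the attempt budget; ",
         "increase n_walks, max_steps or arrival_tol", call. = FALSE)
  }
  pts <- do.call(rbind, pooled[seq_len(n_success)])
  ctr <- c((p_i[1] + p_j[1]) / 2, (p_i[2] + p_j[2]) / 2)
  rel <- sweep(pts, 2, ctr)
  u_major <- rel[, 1] * cos(bearing) + rel[, 2] * sin(bearing)
  u_minor <- -rel[, 1] * sin(bearing) + rel[, 2] * cos(bearing)
  a <- max(stats::quantile(abs(u_major), q, names = FALSE), d / 2 * 1.001)
  b <- min(stats::quantile(abs(u_minor), q, names = FALSE), a)
  b <- max(b, 1e-6 * a)
  e <- ellipse_params(ctr, a, b, bearing)
  attr(e, "n_success") <- n_success
  e
}

#' Clip a raster to an ellipse
#'
#' Keeps cells whose centres satisfy the ellipse inequality and crops the
#' output to the ellipse bounding box; everything else is masked.
#'
#' @param raster a [raster_grid()].
#' @param e an [ellipse_params()].
#' @param min_dim minimum output window size in cells; thin crops are
#'   padded symmetrically with masked cells (never below 2).
#' @return a cropped, masked [raster_grid()].
#' @export
clip_to_ellipse <- function(raster, e, min_dim = 2L) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  ct <- cos(e$orientation); st <- sin(e$orientation)
  # bounding half-extents of a rotated ellipse
  hx <- sqrt((e$a * ct)^2 + (e$b * st)^2)
  hy <- sqrt((e$a * st)^2 + (e$b * ct)^2)
  cs <- raster$cell_size
  c1 <- max(1L, floor((e$center[1] - hx - raster$origin[1]) / cs) + 1L)
  c2 <- min(nc, floor((e$center[1] + hx - raster$origin[1]) / cs) + 1L)
  r1 <- max(1L, floor((raster$origin[2] - (e$center[2] + hy)) / cs) + 1L)
  r2 <- min(nr, floor((raster$origin[2] - (e$center[2] - hy)) / cs) + 1L)
  if (c1 > c2 || r1 > r2) stop("ellipse does not intersect raster", call. = FALSE)
  min_dim <- max(2L, as.integer(min_dim))
  while (r2 - r1 + 1L < min_dim && (r1 > 1L || r2 < nr)) {
    if (r1 > 1L) r1 <- r1 - 1L
    if (r2 - r1 + 1L < min_dim && r2 < nr) r2 <- r2 + 1L
  }
  while (c2 - c1 + 1L < min_dim && (c1 > 1L || c2 < nc)) {
    if (c1 > 1L) c1 <- c1 - 1L
    if (c2 - c1 + 1L < min_dim && c2 < nc) c2 <- c2 + 1L
  }
  rows <- r1:r2; cols <- c1:c2
  cx <- raster$origin[1] + (cols - 0.5) * cs
  cy <- raster$origin[2] - (rows - 0.5) * cs
  dx <- outer(rep(1, length(rows)), cx - e$center[1])
  dy <- outer(cy - e$center[2], rep(1, length(cols)))
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  inside <- (u / e$a)^2 + (v / e$b)^2 <= 1
  if (!any(inside)) stop("ellipse does not cover any cell centre", call. = FALSE)
  vals <- raster$values[rows, cols, drop = FALSE]
  mask <- raster$nodata_mask[rows, cols, drop = FALSE] | !inside
  raster_grid(vals, cell_size = cs,
              origin = c(raster$origin[1] + (c1 - 1L) * cs,
                         raster$origin[2] - (r1 - 1L) * cs),
              nodata_mask = mask)
}

#' Clip one raster to every pairwise ellipse
#'
#' @param raster a [raster_grid()].
#' @param sites a [site_set()].
#' @param axis_ratio passed to [ellipse_from_axis_ratio()].
#' @param min_dim passed to [clip_to_ellipse()]; the default 16 keeps
#'   every clip large enough for the spectral surface metrics.
#' @return named list of clipped rasters, one per [pair_index()] row,
#'   names `"<site_i>|<site_j>"`.
#' @export
pairwise_clips <- function(raster, sites, axis_ratio = 0.5, min_dim = 16L) {
  idx <- pair_index(sites)
  out <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    e <- ellipse_from_axis_ratio(
      c(sites$x[idx$i[k]], sites$y[idx$i[k]]),
      c(sites$x[idx$j[k]], sites$y[idx$j[k]]), axis_ratio = axis_ratio)
    out[[k]] <- clip_to_ellipse(raster, e, min_dim = min_dim)
  }
  names(out) <- paste(idx$site_i, idx$site_j, sep = "|")
  out
}
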