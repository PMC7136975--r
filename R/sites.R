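#' Sampling-site sets and the unordered-pair universe
#'
#' A site set is a data frame with columns `site_id` (unique labels), `x`,
#' `y` (projected coordinates in metres). Its row order fixes the order of
#' the unordered-pair universe used by every pairwise table downstream, so
#' joins across metric tables are reproducible.
#'
#' @param site_id character vector of unique labels.
#' @param x,y numeric projected coordinates (metres).
#' @return a data frame of class `pairscape_sites`.
#' @export
site_set <- function(site_id, x, y) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id)) stop("site_ids must be unique", call. = FALSE)
  if (length(site_id) != length(x) || length(x) != length(y)) {
    stop("site_id, x, y must have equal length", call. = FALSE)
  }
  out <- data.frame(site_id = site_id, x = as.numeric(x), y = as.numeric(y),
                    stringsAsFactors = FALSE)
  class(out) <- c("pairscape_sites", "data.frame")
  out
}

#' Read a site table from CSV
#'
#' Expects columns `site_id`, `x`, `y`.
#' @param path CSV file path.
#' @return a [site_set()].
#' @export
read_sites <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "x", "y")
  if (!all(need %in% names(d))) {
    stop("site CSV must have columns site_id, x, y", call. = FALSE)
  }
  site_set(d$site_id, d$x, d$y)
}

#' All unordered site pairs, in canonical order
#'
#' The pair universe over `n` sites has `n (n - 1) / 2` members (136 for 17
#' sites). Ordering is lexicographic in site *order* (not alphabetical):
#' (1,2), (1,3), ..., (1,n), (2,3), ...
#'
#' @param sites a [site_set()] (or anything with `n >= 2` rows).
#' @return data frame with columns `site_i`, `site_j` (labels) and
#'   `i`, `j` (integer positions, `i < j`).
#' @export
pair_index <- function(sites) {
  n <- nrow(sites)
  if (is.null(n) || n < 2L) stop("need at least 2 sites", call. = FALSE)
  ij <- utils::combn(n, 2L)
  data.frame(site_i = sites$site_id[ij[1, ]], site_j = sites$site_id[ij[2, ]],
             i = ij[1, ], j = ij[2, ], stringsAsFactors = FALSE)
}

#' Flatten a square distance matrix to a pairwise column
#'
#' @param m square symmetric matrix whose row/col order matches `sites`.
#' @param sites a [site_set()].
#' @return numeric vector aligned with [pair_index()] rows.
#' @export
pairwise_column <- function(m, sites) {
  idx <- pair_index(sites)
  m[cbind(idx$i, idx$j)]
}

#' Read a square pairwise distance matrix from CSV
#'
#' The CSV must carry identical row and column labels and be symmetric to
#' within `tol`; the lower triangle is flattened to one record per
#' unordered pair in the order given by `sites` (or by the matrix labels if
#' `sites` is `NULL`).
#'
#' @param path CSV path with header row and first column holding labels.
#' @param sites optional [site_set()] fixing the pair order; its labels must
#'   match the matrix labels as a set.
#' @param tol symmetry tolerance (absolute).
#' @return data frame with columns `site_i`, `site_j`, `value`.
#' @export
read_square_matrix <- function(path, sites = NULL, tol = 1e-9) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("matrix is not square", call. = FALSE)
  if (!identical(rownames(m), colnames(m))) {
    stop("row labels do not match column labels", call. = FALSE)
  }
  asym <- abs(m - t(m))
  if (any(asym > tol, na.rm = TRUE)) {
    w <- which(asym == max(asym, na.rm = TRUE), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "matrix asymmetric beyond tolerance: worst cell (%s, %s), |M - t(M)| = %g",
      rownames(m)[w[1]], colnames(m)[w[2]], max(asym, na.rm = TRUE)),
      call. = FALSE)
  }
  if (is.null(sites)) {
    sites <- site_set(rownames(m), x = seq_len(nrow(m)), y = seq_len(nrow(m)))
  } else {
    if (!setequal(sites$site_id, rownames(m))) {
      stop("matrix labels do not match site set", call. = FALSE)
    }
    m <- m[sites$site_id, sites$site_id]
  }
  idx <- pair_index(sites)
  data.frame(site_i = idx$site_i, site_j = idx$site_j,
             value = m[cbind(idx$i, idx$j)], stringsAsFactors = FALSE)
}
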