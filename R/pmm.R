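#' Reclassify a land-cover raster into the PMM3 or PMM2 scheme
#'
#' PMM3 maps source classes onto forest habitat (1), complementary
#' habitat (2) and non-habitat (3). PMM2 uses the same mapping but masks
#' the non-habitat class as missing, leaving a two-class mosaic.
#'
#' @param landcover categorical [raster_grid()].
#' @param class_map named numeric vector: `names` are source class codes,
#'   values in `{1, 2, 3}`.
#' @param scheme `"pmm3"` or `"pmm2"`.
#' @return reclassified [raster_grid()].
#' @export
reclassify <- function(landcover, class_map, scheme = c("pmm3", "pmm2")) {
  scheme <- match.arg(scheme)
  v <- landcover$values
  present <- unique(v[!landcover$nodata_mask])
  unmapped <- setdiff(as.character(present), names(class_map))
  if (length(unmapped)) {
    stop("unmapped land-cover classes: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !landcover$nodata_mask
  out[ok] <- unname(class_map[as.character(v[ok])])
  if (scheme == "pmm2") out[!is.na(out) & out == 3] <- NA_real_
  raster_grid(out, cell_size = landcover$cell_size, origin = landcover$origin)
}

#' Label patches (connected components per class)
#'
#' Connected components are computed per class under 4- (rook) or 8-
#' (queen) adjacency. Patch area is `cells * cell_size^2 / 10000` ha.
#' Core cells are valid same-class cells whose full 8-neighbourhood is
#' valid and same-class, eroded to `edge_depth` cells. Edge length counts
#' 4-adjacent cell faces between differing classes (and, optionally,
#' between a class and the landscape boundary or masked cells), times
#' `cell_size` metres.
#'
#' @param classraster categorical [raster_grid()].
#' @param connectivity 4 or 8 (default 8, the common landscape-metrics
#'   default).
#' @param edge_depth core erosion depth in cells.
#' @param include_boundary_edge count faces against masked cells/raster
#'   boundary in edge length (default `FALSE`).
#' @return list of class `pairscape_patches`: `labels` (integer matrix,
#'   `NA` = masked), `patches` (data frame: `patch_id`, `class`, `cells`,
#'   `area_ha`, `core_cells`, `core_ha`), `edges` (data frame of
#'   inter-class face counts: `class_a`, `class_b`, `length_m`),
#'   `boundary_length_m`, `cell_size`, `total_area_ha`.
#' @export
label_patches <- function(classraster, connectivity = 8, edge_depth = 1,
                          include_boundary_edge = FALSE) {
  stopifnot(connectivity %in% c(4, 8))
  v <- classraster$values
  valid <- !classraster$nodata_mask
  if (!any(valid)) stop("no valid cells", call. = FALSE)
  nr <- nrow(v); nc <- ncol(v)
  cs <- classraster$cell_size
  idx <- which(valid)
  node_of <- integer(nr * nc)
  node_of[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))          # S, E (each undirected face once)
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- valid[j] & v[j] == v[idx[ok]]
    from <- c(from, node_of[idx[ok]][keep])
    to <- c(to, node_of[j][keep])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, as.vector(rbind(from, to)))
  comp <- igraph::components(g)$membership
  labels <- matrix(NA_integer_, nr, nc)
  labels[idx] <- comp
  # core cells by iterated 8-neighbour erosion within same class
  core <- valid
  for (d in seq_len(edge_depth)) {
    vp <- matrix(NA_real_, nr + 2L, nc + 2L); vp[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(valid, v, NA)
    cp <- matrix(FALSE, nr + 2L, nc + 2L); cp[2:(nr + 1L), 2:(nc + 1L)] <- core
    ctr <- vp[2:(nr + 1L), 2:(nc + 1L)]
    new_core <- core
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nbv <- vp[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
      nbc <- cp[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
      new_core <- new_core & !is.na(nbv) & nbv == ctr & nbc
    }
    core <- new_core
  }
  cells <- tabulate(comp, nbins = max(comp))
  core_cells <- tabulate(comp[core[idx]], nbins = max(comp))
  cls <- v[idx][match(seq_len(max(comp)), comp)]
  patches <- data.frame(patch_id = seq_len(max(comp)), class = cls,
                        cells = cells, area_ha = cells * cs^2 / 1e4,
                        core_cells = core_cells,
                        core_ha = core_cells * cs^2 / 1e4)
  # inter-class faces (rook) and boundary faces
  face_a <- numeric(0); face_b <- numeric(0)
  n_boundary <- 0L
  for (o in list(c(1L, 0L), c(0L, 1L))) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    inb <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[inb] - 1L) * nr + r2[inb]
    vj_valid <- valid[j]
    diffc <- vj_valid & v[j] != v[idx[inb]]
    face_a <- c(face_a, v[idx[inb]][diffc])
    face_b <- c(face_b, v[j][diffc])
    n_boundary <- n_boundary + sum(!inb) + sum(!vj_valid)
  }
  # faces against the N and W raster boundary / masked cells, not covered above
  for (o in list(c(-1L, 0L), c(0L, -1L))) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    inb <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[inb] - 1L) * nr + r2[inb]
    n_boundary <- n_boundary + sum(!inb) + sum(!valid[j])
  }
  edges <- if (length(face_a)) {
    ab <- cbind(pmin(face_a, face_b), pmax(face_a, face_b))
    agg <- stats::aggregate(list(n = rep(1, nrow(ab))),
                            by = list(class_a = ab[, 1], class_b = ab[, 2]),
                            FUN = sum)
    data.frame(class_a = agg$class_a, class_b = agg$class_b,
               length_m = agg$n * cs)
  } else {
    data.frame(class_a = numeric(0), class_b = numeric(0),
               length_m = numeric(0))
  }
  structure(list(labels = labels, patches = patches, edges = edges,
                 boundary_length_m = n_boundary * cs, cell_size = cs,
                 total_area_ha = length(idx) * cs^2 / 1e4,
                 include_boundary_edge = include_boundary_edge),
            class = "pairscape_patches")
}

#' Landscape-level patch-mosaic metrics
#'
#' Computes the ten landscape-level metrics used by the patch-mosaic
#' comparison, with `A` = total valid area (ha), `E` = total inter-class
#' edge length (m), `m` = number of classes present and `a_i` = patch
#' areas (ha):
#' `np` (patch count), `pd = 100 np / A` (patches per 100 ha),
#' `ed = E / A` (m/ha), `area_mn = mean(a_i)`, `core_mn` (mean core area,
#' ha), `cai_mn` (mean of `100 core_i / a_i`), `prd = 100 m / A`,
#' `split = A^2 / sum(a_i^2)`, `mesh = sum(a_i^2) / A` (so
#' `mesh * split = A` identically), and the interspersion and
#' juxtaposition index
#' `iji = -sum_{i<k} (e_ik / E) ln(e_ik / E) / ln(m (m - 1) / 2) * 100`,
#' which is undefined for fewer than three classes and therefore omitted
#' under PMM2.
#'
#' @param patches a [label_patches()] result.
#' @param scheme `"pmm3"` or `"pmm2"`; under `"pmm2"` `iji` is dropped
#'   rather than raising an error.
#' @param strict raise an error when `iji` is requested (PMM3) but fewer
#'   than three classes are present; with `strict = FALSE` the metric is
#'   returned as `NA` instead (used by [pmm_table()] so one degenerate
#'   clip does not abort a whole batch).
#' @return named numeric vector `np, pd, ed, area_mn, core_mn, cai_mn,
#'   prd, split, mesh` plus `iji` when defined.
#' @export
pmm_vector <- function(patches, scheme = c("pmm3", "pmm2"), strict = TRUE) {
  scheme <- match.arg(scheme)
  p <- patches$patches
  A <- patches$total_area_ha
  E <- sum(patches$edges$length_m)
  if (patches$include_boundary_edge) E <- E + patches$boundary_length_m
  m <- length(unique(p$class))
  np <- nrow(p)
  out <- c(np = np,
           pd = np / A * 100,
           ed = E / A,
           area_mn = mean(p$area_ha),
           core_mn = mean(p$core_ha),
           cai_mn = mean(100 * p$core_cells / p$cells),
           prd = m / A * 100,
           split = A^2 / sum(p$area_ha^2),
           mesh = sum(p$area_ha^2) / A)
  if (m >= 3) {
    e <- patches$edges$length_m
    if (E > 0 && length(e)) {
      frac <- e / E
      out["iji"] <- -sum(frac * log(frac)) / log(m * (m - 1) / 2) * 100
    } else {
      out["iji"] <- NA_real_
    }
  } else if (scheme == "pmm3") {
    if (strict) {
      stop("iji is undefined for landscapes with fewer than 3 classes",
           call. = FALSE)
    }
    out["iji"] <- NA_real_
  }
  out
}

#' Patch-mosaic metrics for every pairwise clip
#'
#' @param clips list of clipped categorical rasters (classes 1..3).
#' @param sites a [site_set()] fixing the pair order.
#' @param scheme `"pmm3"` or `"pmm2"`; under `"pmm2"` class 3 is masked
#'   before labelling and `iji` is omitted.
#' @param connectivity,edge_depth,include_boundary_edge passed to
#'   [label_patches()].
#' @return data frame: `site_i`, `site_j` plus metric columns.
#' @export
pmm_table <- function(clips, sites, scheme = c("pmm3", "pmm2"),
                      connectivity = 8, edge_depth = 1,
                      include_boundary_edge = FALSE) {
  scheme <- match.arg(scheme)
  idx <- pair_index(sites)
  stopifnot(length(clips) == nrow(idx))
  cols <- c("np", "pd", "ed", "area_mn", "core_mn", "cai_mn", "prd",
            "split", "mesh")
  if (scheme == "pmm3") cols <- c(cols, "iji")
  rows <- lapply(clips, function(cl) {
    if (scheme == "pmm2") {
      v <- cl$values
      v[!is.na(v) & v == 3] <- NA_real_
      cl <- raster_grid(v, cell_size = cl$cell_size, origin = cl$origin)
    }
    pv <- tryCatch(
      pmm_vector(label_patches(cl, connectivity = connectivity,
                               edge_depth = edge_depth,
                               include_boundary_edge = include_boundary_edge),
                 scheme = scheme, strict = FALSE),
      error = function(e) stats::setNames(rep(NA_real_, length(cols)), cols))
    pv[cols]
  })
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  cbind(idx[, c("site_i", "site_j")], as.data.frame(m))
}
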