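nlcd_map <- c("41" = 1, "42" = 1, "43" = 1, "52" = 2, "71" = 2, "81" = 2,
              "82" = 3, "11" = 3)

test_that("reclassification maps NLCD-style codes and masks under PMM2", {
  set.seed(1)
  codes <- as.numeric(names(nlcd_map))
  lc <- raster_grid(matrix(sample(codes, 100, TRUE), 10, 10), cell_size = 30)
  r3 <- reclassify(lc, nlcd_map, scheme = "pmm3")
  expect_setequal(unique(raster_values(r3)), c(1, 2, 3))
  expect_equal(sum(r3$nodata_mask), 0)
  r2 <- reclassify(lc, nlcd_map, scheme = "pmm2")
  expect_setequal(unique(raster_values(r2)), c(1, 2))
  expect_equal(sum(r2$nodata_mask), sum(r3$values == 3))
  lc$values[2, 2] <- 95
  expect_error(reclassify(lc, nlcd_map), "95")
})

test_that("patch labelling: single class, checkerboard under 4 vs 8", {
  one <- raster_grid(matrix(1, 10, 10), cell_size = 30)
  p <- label_patches(one)
  expect_equal(nrow(p$patches), 1)
  expect_equal(p$patches$area_ha, 100 * 30^2 / 1e4)

  chk <- raster_grid(outer(1:10, 1:10, function(i, j) (i + j) %% 2 + 1),
                     cell_size = 10)
  p4 <- label_patches(chk, connectivity = 4)
  expect_equal(nrow(p4$patches), 100)  # every cell its own patch
  p8 <- label_patches(chk, connectivity = 8)
  expect_equal(nrow(p8$patches), 2)    # each colour diagonally connected
})

test_that("split and mesh follow patch-area algebra", {
  one <- raster_grid(matrix(1, 10, 10), cell_size = 30)
  # single patch: split = 1, mesh = A (iji undefined, non-strict)
  v1 <- pmm_vector(label_patches(one), strict = FALSE)
  A <- 100 * 30^2 / 1e4
  expect_equal(unname(v1["split"]), 1)
  expect_equal(unname(v1["mesh"]), A)
  expect_equal(unname(v1["np"]), 1)

  # two equal patches tiling the area: split = 2
  two <- raster_grid(cbind(matrix(1, 10, 5), matrix(2, 10, 5)),
                     cell_size = 30)
  v2 <- pmm_vector(label_patches(two), strict = FALSE)
  expect_equal(unname(v2["split"]), 2)
  expect_equal(unname(v2["mesh"]), A / 2)
})

test_that("iji demands three classes and is bounded by 100", {
  two <- raster_grid(cbind(matrix(1, 6, 3), matrix(2, 6, 3)), cell_size = 30)
  expect_error(pmm_vector(label_patches(two), scheme = "pmm3"), "iji")
  expect_false("iji" %in% names(pmm_vector(label_patches(two),
                                           scheme = "pmm2")))
  three <- raster_grid(cbind(matrix(1, 6, 2), matrix(2, 6, 2),
                             matrix(3, 6, 2)), cell_size = 30)
  v <- pmm_vector(label_patches(three), scheme = "pmm3")
  expect_true(v["iji"] > 0 && v["iji"] <= 100)
  # stripes 1|2|3: edges only 1-2 and 2-3, equally long -> even
  # interspersion of 2 of the 3 possible adjacencies
  e <- c(0.5, 0.5)
  expect_equal(unname(v["iji"]), -sum(e * log(e)) / log(3) * 100)
})

test_that("mesh * split = A identically; metrics class-label invariant", {
  for (seed in 1:20) {
    set.seed(seed)
    nr <- sample(6:15, 1); nc <- sample(6:15, 1)
    v <- matrix(sample(1:3, nr * nc, TRUE), nr, nc)
    v[matrix(runif(nr * nc) < 0.1, nr, nc)] <- NA
    if (all(is.na(v))) next
    r <- raster_grid(v, cell_size = sample(c(10, 30), 1))
    p <- label_patches(r)
    m <- pmm_vector(p, strict = FALSE)
    expect_equal(unname(m["mesh"] * m["split"]), p$total_area_ha,
                 tolerance = 1e-12)
    # permute class labels: np and ed unchanged
    v2 <- r$values
    perm <- c(2, 3, 1)
    v2[!is.na(v2)] <- perm[v2[!is.na(v2)]]
    m2 <- pmm_vector(label_patches(raster_grid(v2, cell_size = r$cell_size)),
                     strict = FALSE)
    expect_equal(m2["np"], m["np"])
    expect_equal(m2["ed"], m["ed"])
  }
})

test_that("2x grid refinement preserves area metrics and axis-aligned ed", {
  set.seed(4)
  v <- matrix(sample(1:3, 8 * 8, TRUE), 8, 8)
  coarse <- raster_grid(v, cell_size = 20)
  fine <- raster_grid(v[rep(1:8, each = 2), rep(1:8, each = 2)],
                      cell_size = 10)
  mc <- pmm_vector(label_patches(coarse), strict = FALSE)
  mf <- pmm_vector(label_patches(fine), strict = FALSE)
  for (k in c("area_mn", "mesh", "split")) {
    expect_equal(unname(mf[k]), unname(mc[k]), tolerance = 1e-9)
  }
  expect_equal(unname(mf["ed"]), unname(mc["ed"]), tolerance = 1e-9)
})

test_that("edge accounting: boundary faces only when requested", {
  two <- raster_grid(cbind(matrix(1, 4, 2), matrix(2, 4, 2)), cell_size = 10)
  p_no <- label_patches(two, include_boundary_edge = FALSE)
  v_no <- pmm_vector(p_no, scheme = "pmm2")
  # internal 1|2 interface: 4 faces of 10 m over A = 16 cells * 100 m2
  A <- 16 * 100 / 1e4
  expect_equal(unname(v_no["ed"]), 40 / A)
  p_yes <- label_patches(two, include_boundary_edge = TRUE)
  v_yes <- pmm_vector(p_yes, scheme = "pmm2")
  # plus the 16-face outer perimeter
  expect_equal(unname(v_yes["ed"]), (40 + 160) / A)
})

test_that("core area follows erosion depth", {
  v <- matrix(1, 5, 5); v[1, ] <- 2  # a 4x5 block of class 1 under a class-2 row
  p <- label_patches(raster_grid(v, cell_size = 10))
  pat <- p$patches
  # class-1 core: rows 3-4 x cols 2-4 (away from boundary and class 2)
  expect_equal(pat$core_cells[pat$class == 1], 6)
  expect_equal(pat$core_cells[pat$class == 2], 0)   # one-cell-thick stripe
})
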