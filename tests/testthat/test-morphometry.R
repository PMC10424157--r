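# The measurement battery on constructed cases with known answers, plus
# light ground-truth recovery (the full multi-seed recovery runs in the
# acceptance suite).

px_um <- 212.13 / 256  # default lateral pixel

test_that("marker detection handles flat, unimodal and low-prominence cases", {
  expect_equal(nrow(find_nuclei_markers(matrix(0, 40, 40))), 0)
  expect_equal(nrow(find_nuclei_markers(matrix(7.5, 40, 40))), 0)
  # one isotropic blob -> one marker at its center (+- 1 px)
  blob <- exp(-0.5 * outer((1:61 - 31)^2, (1:61 - 31)^2, "+") / 5^2)
  m <- find_nuclei_markers(blob, pixel_size = 1)
  expect_equal(nrow(m), 1)
  expect_lte(max(abs(m[1, ] - c(31, 31))), 1)
  # a second bump below the prominence cutoff is not reported
  two <- blob + 0.05 * exp(-0.5 * outer((1:61 - 10)^2, (1:61 - 50)^2, "+") / 3^2)
  m2 <- find_nuclei_markers(two, prominence = 0.2, pixel_size = 1)
  expect_equal(nrow(m2), 1)
  # raising both bumps above the cutoff reports both
  two_hi <- blob + 0.6 * exp(-0.5 * outer((1:61 - 10)^2, (1:61 - 50)^2, "+") / 3^2)
  expect_equal(nrow(find_nuclei_markers(two_hi, prominence = 0.2,
                                        pixel_size = 1)), 2)
})

test_that("segmentation is marker-conservative and splits uniform fields
           along the perpendicular bisector", {
  u <- matrix(1, 60, 60)
  seg <- segment_cells(u, rbind(c(15, 30), c(45, 30)), smooth_sigma_um = 0)
  expect_equal(sort(unique(as.integer(seg$labels))), c(1L, 2L))
  # split row within a pixel of the bisector (row 30)
  r1 <- max(which(rowSums(seg$labels == 1) > 0))
  expect_lte(abs(r1 - 30), 1)
  expect_lt(abs(sum(seg$labels == 1) - sum(seg$labels == 2)) / 3600, 0.05)
  # one marker claims the whole field
  seg1 <- segment_cells(u, rbind(c(10, 10)), smooth_sigma_um = 0)
  expect_true(all(seg1$labels == 1L))
  expect_error(segment_cells(u, rbind(c(0, 10))), "outside")
  expect_error(segment_cells(u, matrix(numeric(0), 0, 2)), "marker")
  # region count equals marker count on arbitrary noisy reliefs
  set.seed(42)
  for (k in c(3, 7, 12)) {
    img <- matrix(runif(80 * 80), 80, 80)
    mk <- cbind(sample(5:75, k), sample(5:75, k))
    sg <- segment_cells(img, mk)
    expect_equal(length(setdiff(unique(as.integer(sg$labels)), 0L)), k)
  }
})

test_that("circularity behaves like the particle-analysis convention", {
  disk <- raster_disk(25)
  sd_ <- cell_shape_stats(disk, pixel_size = 1, area_bounds = c(1, 1e5))
  expect_gte(sd_$cells$circularity[1], 0.95)
  expect_lte(sd_$cells$circularity[1], 1)
  sq <- cell_shape_stats(raster_square(50), pixel_size = 1,
                         area_bounds = c(1, 1e5))
  expect_equal(sq$cells$circularity[1], pi / 4, tolerance = 0.07)
  expect_equal(sq$cells$area_um2[1], 2500)
})

test_that("shape statistics apply area and border exclusion", {
  lab <- matrix(0L, 50, 50)
  lab[10:29, 10:29] <- 1L      # 400 px, retained
  lab[35:37, 35:37] <- 2L      # 9 px, too small
  lab[1:5, 40:49] <- 3L        # touches the border
  st <- cell_shape_stats(lab, pixel_size = 1, area_bounds = c(20, 2000))
  expect_equal(st$n_retained, 1)
  expect_true(st$cells$retained[1])
  expect_false(any(st$cells$retained[2:3]))
  expect_equal(st$mean_area_um2, 400)
  # nothing retained: flagged empty with NA means, not NaN
  st2 <- cell_shape_stats(lab, pixel_size = 1, area_bounds = c(1000, 2000))
  expect_true(st2$empty)
  expect_true(is.na(st2$mean_circularity))
})

test_that("ciliated fraction handles empty channels and missing nuclei", {
  z <- matrix(0, 64, 64)
  nuc <- matrix(0, 64, 64)
  nuc[20:28, 20:28] <- 1  # one 81 px nucleus
  expect_equal(ciliated_fraction(z, nuc, pixel_size = 1), 0)
  expect_true(is.na(ciliated_fraction(z, z, pixel_size = 1)))
})

test_that("thickness of a uniform slab is exact and shift-invariant", {
  st <- slab_stack(nz = 20, planes = 4:11)   # 8 planes -> 3.2 um
  expect_equal(thickness(st, roles = "zo1"), 8 * 0.4, tolerance = 1e-12)
  # empty stack measures zero
  expect_equal(thickness(slab_stack(nz = 20, planes = integer(0)),
                         roles = "zo1"), 0)
  # lateral translation leaves it unchanged
  sh <- st
  a <- sh$voxels$zo1
  sh$voxels$zo1 <- a[c(6:40, 1:5), , ]
  expect_equal(thickness(sh, roles = "zo1"), thickness(st, roles = "zo1"))
  # both projection axes agree for an isotropic slab
  expect_equal(thickness(st, roles = "zo1", axis = "x"),
               thickness(st, roles = "zo1", axis = "y"))
  expect_error(thickness(slab_stack(nz = 1, planes = 1), roles = "zo1"),
               "z-stack")
})

test_that("cilium length reads the apical tubulin extent after subtraction", {
  nz <- 30; n <- 40
  body <- array(0, c(n, n, nz)); body[, , 1:12] <- 800
  nucl <- array(0, c(n, n, nz)); nucl[15:25, 15:25, 4:9] <- 900
  m <- 7
  tub <- array(0, c(n, n, nz)); tub[, , 1:12] <- 300
  tub[20, 20, 13:(12 + m)] <- 1000           # rod spanning m planes
  st <- mk_stack(tubulin = tub, nakatpase = body, nuclei = nucl)
  expect_equal(cilia_length(st), (m - 1) * 0.4, tolerance = 0.4 + 1e-9)
  # tubulin identical to the pump channel cancels completely: missing value
  st2 <- mk_stack(tubulin = body, nakatpase = body, nuclei = nucl)
  expect_true(is.na(cilia_length(st2)))
})

test_that("coverage normalizes to nuclei and is scale-invariant", {
  nz <- 9; n <- 60
  sig <- array(0, c(n, n, nz)); sig[10:39, 10:39, 3:7] <- 500
  one <- array(0, c(n, n, nz)); one[5:13, 5:13, 5] <- 900
  two <- one; two[40:48, 40:48, 5] <- 900
  st1 <- mk_stack(zo1 = sig, nuclei = one)
  st2 <- mk_stack(zo1 = sig, nuclei = two)
  c1 <- coverage_3d(st1, "zo1")
  c2 <- coverage_3d(st2, "zo1")
  expect_equal(c1, 30 * 30 * 5)       # suprathreshold voxels per 1 nucleus
  expect_equal(c2, c1 / 2)            # doubling nuclei halves the value
  # uniform rescaling of the channel leaves the value unchanged exactly
  st3 <- st1; st3$voxels$zo1 <- st3$voxels$zo1 * 2
  expect_identical(coverage_3d(st3, "zo1"), c1)
  # all-zero channel: zero voxels per nucleus
  st4 <- mk_stack(zo1 = array(0, c(n, n, nz)), nuclei = one)
  expect_equal(coverage_3d(st4, "zo1"), 0)
  # no nuclei: missing value
  st5 <- mk_stack(zo1 = sig, nuclei = array(0, c(n, n, nz)))
  expect_true(is.na(coverage_3d(st5, "zo1")))
})

test_that("chip summaries average FOVs with pairwise missing handling", {
  f <- data.frame(tissue_thickness = c(1, 2, 3, 4, 5),
                  pct_ciliated = c(30, NA, 40, NA, 50),
                  cilia_length = rep(NA_real_, 5))
  rec <- chip_summary(f, "chipA", "flow")
  expect_equal(rec$tissue_thickness, 3)
  expect_equal(rec$pct_ciliated, 40)
  expect_equal(rec$n_fov_pct_ciliated, 3)
  expect_true(is.na(rec$cilia_length))
  expect_equal(rec$n_fov_cilia_length, 0)
  # identical FOVs reproduce any single FOV
  g <- data.frame(tissue_thickness = rep(7.7, 5))
  expect_equal(chip_summary(g, "c", "g")$tissue_thickness, 7.7)
})

test_that("the pipeline recovers ground truth on a default-noise field", {
  sim <- generate_monolayer(field_spec(8), tissue_params(), seed = 42)
  truth <- sim$truth
  inf <- truth$cells$in_field
  fov <- analyze_fov(sim$stack)
  nuc <- apply(get_channel(sim$stack, "nuclei"), c(1, 2), max)
  markers <- find_nuclei_markers(nuc, pixel_size = px_um)
  rec <- match_markers(markers,
                       as.matrix(truth$cells[inf, c("centroid_y_px",
                                                    "centroid_x_px")]))
  expect_gte(rec$recall, 0.95)
  seg <- segment_cells(apply(get_channel(sim$stack, "nakatpase"),
                             c(1, 2), max), markers, pixel_size = px_um)
  expect_gte(mean(label_iou(truth$label_map, seg)), 0.7)
  expect_lt(abs(fov$tissue_thickness - truth$tissue$mean_thickness_um) /
            truth$tissue$mean_thickness_um, 0.2)
  expect_lt(abs(fov$pct_ciliated - 100 * mean(truth$cells$ciliated[inf])), 10)
  expect_lt(abs(fov$cilia_length - 3), 1)
  expect_lt(abs(fov$mean_circularity - mean(truth$cells$circularity[inf])),
            0.05)
})

test_that("all metrics are identical on axis-flipped stacks", {
  sim <- generate_monolayer(small_spec(nz = 28, n = 128), tissue_params(),
                            seed = 5)
  f0 <- analyze_fov(sim$stack)
  f1 <- analyze_fov(flip_stack(sim$stack, 1))
  f2 <- analyze_fov(flip_stack(sim$stack, 2))
  expect_identical(f0, f1)
  expect_identical(f0, f2)
})
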