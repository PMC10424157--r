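# The synthetic monolayer forward model: determinism, density, tiling,
# rendering semantics, cohort structure.

test_that("a fixed seed reproduces the stack and truth bit for bit", {
  spec <- small_spec(nz = 20, n = 64)
  a <- generate_monolayer(spec, tissue_params(), seed = 9)
  b <- generate_monolayer(spec, tissue_params(), seed = 9)
  expect_identical(a, b)
  c <- generate_monolayer(spec, tissue_params(), seed = 10)
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("realized cell count tracks seeding density times field area", {
  # 200,000 cells/cm^2 over a 212.13 um square field: ~90 cells expected
  spec <- stack_spec(shape = c(6, 256, 256),
                     voxel_size = c(0.4, 212.13 / 256, 212.13 / 256),
                     channels = "nuclei")
  expected <- 2e5 / 1e8 * 212.13^2
  for (s in 1:3) {
    tr <- generate_monolayer(spec, tissue_params(), seed = s)$truth
    expect_lt(abs(tr$tissue$n_cells_in_field - expected) / expected, 0.20)
  }
})

test_that("cell footprints tile the field without gaps or overlap", {
  sim <- generate_monolayer(small_spec(nz = 6, n = 80), tissue_params(),
                            seed = 3)
  field_area <- prod(dim(sim$truth$label_map)) * 0.829^2
  expect_equal(sum(sim$truth$cells$area_um2), field_area, tolerance = 1e-9)
  expect_true(all(sim$truth$label_map >= 1))      # every pixel assigned
  expect_true(all(sim$truth$cells$circularity > 0 &
                  sim$truth$cells$circularity <= 1))
})

test_that("ciliated_fraction zero leaves the apical tubulin volume dark", {
  spec <- small_spec(nz = 40, n = 64)   # 16 um of z over ~7 um of tissue
  quiet <- tissue_params(mean_cell_height = 6, ciliated_fraction = 0,
                         noise = list(gaussian_sd = 1e-4,
                                      poisson_scale = 1e6))
  sim <- generate_monolayer(spec, quiet, seed = 4)
  expect_false(any(sim$truth$cells$ciliated))
  tub <- get_channel(sim$stack, "tubulin")
  z_top <- max(sim$truth$cells$height_um) + 1  # tallest cell + laminin
  above <- which((seq_len(dim(tub)[3]) - 0.5) * 0.4 > z_top + 2.5)
  expect_gt(length(above), 0)
  # nothing above the apical surface beyond PSF reach (tiny quantization floor)
  expect_lt(max(tub[, , above]), 0.005 * (2^16 - 1))
})

test_that("intensities respect the bit depth without saturating", {
  sim <- generate_monolayer(small_spec(nz = 20, n = 64), tissue_params(),
                            seed = 5)
  for (arr in sim$stack$voxels) {
    expect_gte(min(arr), 0)
    expect_lte(max(arr), 2^16 - 1)
    expect_lt(stats::quantile(arr, 0.999), 2^16 - 1)  # no clipping plateau
  }
})

test_that("taller tissue parameters raise the true thickness monotonically", {
  spec <- small_spec(nz = 10, n = 48)
  th <- vapply(c(5, 8, 12), function(h) {
    generate_monolayer(spec, tissue_params(mean_cell_height = h),
                       seed = 7)$truth$tissue$mean_thickness_um
  }, numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("higher ciliated fraction yields more rendered cilia over seeds", {
  spec <- small_spec(nz = 8, n = 64)
  more <- vapply(1:5, function(s) {
    lo <- generate_monolayer(spec, tissue_params(ciliated_fraction = 0.15),
                             seed = s)$truth
    hi <- generate_monolayer(spec, tissue_params(ciliated_fraction = 0.75),
                             seed = s)$truth
    sum(hi$cells$ciliated) - sum(lo$cells$ciliated)
  }, numeric(1))
  expect_true(all(more > 0))
})

test_that("cohorts have the full group/chip/FOV hierarchy and reproduce", {
  spec <- small_spec(nz = 8, n = 48)
  pg <- list(a = tissue_params(mean_cell_height = 6),
             b = tissue_params(mean_cell_height = 12))
  coh <- generate_cohort(spec, pg, chips_per_group = 4, fovs_per_chip = 5,
                         seed = 21)
  expect_length(coh$fovs, 2 * 4 * 5)
  expect_equal(nrow(coh$chip_truth), 8)
  expect_setequal(unique(coh$chip_truth$group), c("a", "b"))
  # group truths differ in the direction of the height parameters
  expect_gt(min(coh$chip_truth$thickness_um[coh$chip_truth$group == "b"]),
            max(coh$chip_truth$thickness_um[coh$chip_truth$group == "a"]))
  coh2 <- generate_cohort(spec, pg, chips_per_group = 4, fovs_per_chip = 5,
                          seed = 21)
  expect_identical(coh$chip_truth, coh2$chip_truth)
  expect_identical(coh$fovs[[13]]$stack$voxels, coh2$fovs[[13]]$stack$voxels)
})

test_that("stacks survive a TIFF round trip with sidecar metadata", {
  sim <- generate_monolayer(small_spec(nz = 6, n = 32), tissue_params(),
                            seed = 2)
  path <- tempfile(fileext = ".tif")
  write_stack(sim$stack, path)
  expect_true(file.exists(paste0(path, ".json")))
  rt <- read_stack(path)
  expect_identical(rt$voxels, sim$stack$voxels)
  expect_identical(rt$channel_roles, sim$stack$channel_roles)
  expect_equal(rt$voxel_size, sim$stack$voxel_size)
})

test_that("acquisition specs are validated", {
  expect_error(stack_spec(voxel_size = c(0.5, 0.2, 0.2)), "z-step")
  expect_error(stack_spec(channels = c("nuclei", "gfp")), "channels")
  expect_error(stack_spec(channels = c("nuclei", "nuclei")), "channels")
  expect_error(tissue_params(ciliated_fraction = 1.2))
  expect_error(image_stack(list(a = array(0, c(2, 2, 2))),
                           voxel_size = c(0, 1, 1)), "voxel_size")
})
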