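# shared fixtures: small acquisition specs, raster shapes, stack builders

# small fast field (~80 um) for unit tests
small_spec <- function(nz = 28, n = 96) {
  stack_spec(shape = c(nz, n, n), voxel_size = c(0.4, 0.829, 0.829))
}

# full 212.13 um field, z extent framing the given cell height
field_spec <- function(mean_height = 8) {
  nz <- ceiling((mean_height + 1 + 4 + 2.5) / 0.4)  # tissue + cilia + margin
  stack_spec(shape = c(nz, 256, 256),
             voxel_size = c(0.4, 212.13 / 256, 212.13 / 256))
}

paper_geometry <- function(plan = "ellipse") ibidi_slide_geometry(plan)

q300 <- function() flow_condition(300, "ul/min")

# rasterized disk of radius r (pixels) in a matrix with margin
raster_disk <- function(r, margin = 10) {
  s <- 2 * r + 2 * margin + 1
  ctr <- (s + 1) / 2
  d <- sqrt(outer((1:s - ctr)^2, (1:s - ctr)^2, "+"))
  (d <= r) * 1L
}

raster_square <- function(side, margin = 10) {
  s <- side + 2 * margin
  img <- matrix(0L, s, s)
  img[(margin + 1):(margin + side), (margin + 1):(margin + side)] <- 1L
  img
}

# flip a stack along a lateral axis
flip_stack <- function(stack, axis = 1) {
  stack$voxels <- lapply(stack$voxels, function(a) {
    if (axis == 1) a[dim(a)[1]:1, , , drop = FALSE]
    else a[, dim(a)[2]:1, , drop = FALSE]
  })
  stack
}

# build an image_stack from explicit channel arrays
mk_stack <- function(..., voxel_size = c(0.4, 1, 1)) {
  image_stack(list(...), voxel_size = voxel_size)
}

# uniform slab stack: channel `role` nonzero on z-planes `planes`
slab_stack <- function(role = "zo1", nz = 20, n = 40, planes = 1:10,
                       value = 1000, voxel_size = c(0.4, 1, 1)) {
  arr <- array(0, dim = c(n, n, nz))
  arr[, , planes] <- value
  v <- stats::setNames(list(arr), role)
  image_stack(v, voxel_size = voxel_size)
}

# brute-force two-sided rank-sum p by direct permutation enumeration,
# independent of the package implementation (recursive subset walk)
brute_rank_sum_p <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a)
  w_obs <- sum(r[seq_along(a)])
  mu <- na * mean(r)
  sets <- utils::combn(length(r), na, function(i) sum(r[i]))
  mean(abs(sets - mu) >= abs(w_obs - mu) - 1e-9)
}
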