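# Forward model of an epithelial monolayer imaged as a multi-channel
# confocal z-stack, with per-cell ground truth for recovery testing.

# run expr with a private RNG state seeded by `seed`
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic monolayer stack with ground truth
#'
#' Renders an epithelial monolayer as the five stains would show it, then
#' degrades the ideal image with a Gaussian PSF and mixed Poisson-Gaussian
#' noise. Cell footprints are the Voronoi tessellation of a jittered
#' hexagonal lattice; each cell gets its own height, an ellipsoidal nucleus,
#' tight-junction signal on the apical third of its lateral borders, pump
#' signal on lateral and basal membranes, and (if ciliated) a thin vertical
#' tubulin rod protruding from the apical surface. The basement membrane is
#' a continuous basal laminin sheet. Rendering order is geometry, then PSF
#' blur, then noise, then quantization to the bit depth.
#'
#' @param spec a [stack_spec()].
#' @param params a [tissue_params()].
#' @param seed integer seed; the same seed reproduces the stack bit for bit.
#' @return A list with `stack` (an [image_stack()]) and `truth`
#'   (class `tissue_truth`): `cells`, a per-cell data frame (id, centroid in
#'   um and px, apical area in um^2, circularity, height, ciliated flag,
#'   cilium length), `label_map`, the true footprint labels, and `tissue`,
#'   per-tissue summaries (cell count, mean tissue thickness = basement
#'   membrane + mean cell height, laminin thickness).
#' @export
generate_monolayer <- function(spec, params = tissue_params(), seed = 1) {
  stopifnot(inherits(spec, "stack_spec"), inherits(params, "tissue_params"))
  with_local_seed(seed, generate_monolayer_impl(spec, params))
}

generate_monolayer_impl <- function(spec, params) {
  nz <- unname(spec$shape["z"]); ny <- unname(spec$shape["y"])
  nx <- unname(spec$shape["x"])
  dz <- unname(spec$voxel_size["dz"]); dy <- unname(spec$voxel_size["dy"])
  dx <- unname(spec$voxel_size["dx"])
  Ly <- ny * dy; Lx <- nx * dx

  # --- cell centers: jittered hexagonal lattice at the seeding density ---
  rho <- params$cell_density / 1e8           # cells per um^2
  a <- sqrt(2 / (sqrt(3) * rho))             # lattice spacing, um
  row_h <- a * sqrt(3) / 2
  ys <- seq(-a, Ly + a, by = row_h)
  centers <- NULL
  for (i in seq_along(ys)) {
    off <- if (i %% 2 == 0) a / 2 else 0
    xs <- seq(-a + off, Lx + a, by = a)
    centers <- rbind(centers, cbind(ys[i], xs))
  }
  centers <- centers + matrix(stats::rnorm(length(centers),
                                           sd = params$jitter * a),
                              ncol = 2)

  # --- Voronoi assignment of pixel centers to the nearest cell center ---
  py <- (seq_len(ny) - 0.5) * dy
  px <- (seq_len(nx) - 0.5) * dx
  best <- matrix(Inf, ny, nx)
  lab0 <- matrix(0L, ny, nx)
  for (j in seq_len(nrow(centers))) {
    d2 <- outer((py - centers[j, 1])^2, (px - centers[j, 2])^2, "+")
    hit <- d2 < best
    best[hit] <- d2[hit]
    lab0[hit] <- j
  }
  present <- sort(unique(as.integer(lab0)))
  if (length(present) < 1L) {
    stop("invalid spec: field too small to hold a cell", call. = FALSE)
  }
  relab <- integer(max(present)); relab[present] <- seq_along(present)
  lab <- matrix(relab[lab0], ny, nx)
  K <- length(present)
  centers <- centers[present, , drop = FALSE]

  # --- per-cell attributes ---
  h_mean <- params$mean_cell_height
  heights <- stats::rnorm(K, h_mean, params$height_cv * h_mean)
  heights <- pmax(heights, pmax(1, 0.25 * h_mean))
  in_field <- centers[, 1] >= 0 & centers[, 1] <= Ly &
              centers[, 2] >= 0 & centers[, 2] <= Lx
  # only cells whose body center lies in the field carry a rendered cilium:
  # a cilium sits over its cell center, so off-field centers project outside
  ciliated <- (stats::runif(K) < params$ciliated_fraction) & in_field
  cil_len <- stats::rnorm(K, params$mean_cilium_length,
                          params$cilium_length_cv * params$mean_cilium_length)
  cil_len <- pmax(cil_len, 0.5)
  cil_len[!ciliated] <- NA_real_

  areas_px <- tabulate(lab, nbins = K)
  lam <- params$laminin_thickness
  h_map <- matrix(heights[lab], ny, nx)
  ztop_map <- lam + h_map

  # lateral cell borders: label differs from a 4-neighbour
  bnd <- matrix(FALSE, ny, nx)
  bnd[-1, ] <- bnd[-1, ] | (lab[-1, ] != lab[-ny, ])
  bnd[-ny, ] <- bnd[-ny, ] | (lab[-ny, ] != lab[-1, ])
  bnd[, -1] <- bnd[, -1] | (lab[, -1] != lab[, -nx])
  bnd[, -nx] <- bnd[, -nx] | (lab[, -nx] != lab[, -1])

  zc <- (seq_len(nz) - 0.5) * dz

  render_plane <- function(mask2d) mask2d  # readability helper
  new_ch <- function() array(0, dim = c(ny, nx, nz))

  voxels <- list()
  for (role in spec$channels) {
    arr <- new_ch()
    if (role == "laminin") {
      for (k in which(zc < lam)) arr[, , k] <- 1
    } else if (role == "zo1") {
      z_lo <- lam + (2 / 3) * h_map
      for (k in seq_len(nz)) {
        m <- bnd & (zc[k] >= z_lo) & (zc[k] <= ztop_map)
        if (any(m)) arr[, , k] <- params$junction_intensity * render_plane(m)
      }
    } else if (role == "nakatpase") {
      for (k in seq_len(nz)) {
        m <- bnd & (zc[k] >= lam) & (zc[k] <= ztop_map)
        basal <- (zc[k] >= lam) & (zc[k] <= lam + 0.8)
        pl <- params$pump_intensity * (m + 0.6 * (basal & !m))
        if (any(pl > 0)) arr[, , k] <- pl
      }
    } else if (role == "tubulin") {
      for (k in seq_len(nz)) {
        body <- (zc[k] >= lam) & (zc[k] <= ztop_map)
        if (any(body)) {
          arr[, , k] <- params$tubulin_body_intensity * render_plane(body)
        }
      }
      for (j in which(ciliated)) {
        iy <- pmin(pmax(round(centers[j, 1] / dy + 0.5), 1), ny)
        ix <- pmin(pmax(round(centers[j, 2] / dx + 0.5), 1), nx)
        zt <- lam + heights[j]
        ks <- which(zc > zt & zc <= zt + cil_len[j])
        arr[iy, ix, ks] <- 1
      }
    } else if (role == "nuclei") {
      for (j in seq_len(K)) {
        r_cell <- sqrt(areas_px[j] * dy * dx / pi)
        s_lat <- 0.25 * max(r_cell, 2)
        s_z <- 0.25 * heights[j]
        z_mid <- lam + heights[j] / 2
        wy <- which(abs(py - centers[j, 1]) < 3 * s_lat)
        wx <- which(abs(px - centers[j, 2]) < 3 * s_lat)
        if (!length(wy) || !length(wx)) next
        lat <- exp(-0.5 * outer((py[wy] - centers[j, 1])^2,
                                (px[wx] - centers[j, 2])^2, "+") / s_lat^2)
        zprof <- exp(-0.5 * ((zc - z_mid) / s_z)^2)
        ks <- which(zprof > 0.01)
        for (k in ks) {
          arr[wy, wx, k] <- pmax(arr[wy, wx, k], lat * zprof[k])
        }
      }
    }
    voxels[[role]] <- arr
  }

  # --- optics and noise ---
  sig_vox <- c(params$psf_sigma["y"] / dy, params$psf_sigma["x"] / dx,
               params$psf_sigma["z"] / dz)
  maxdn <- 2^spec$bit_depth - 1
  for (role in names(voxels)) {
    arr <- gauss_blur3d(voxels[[role]], sig_vox)
    lam_ph <- params$noise$poisson_scale * pmax(arr, 0)
    arr <- stats::rpois(length(lam_ph), lam_ph) / params$noise$poisson_scale
    arr <- arr + stats::rnorm(length(arr), sd = params$noise$gaussian_sd)
    arr <- array(arr, dim = c(ny, nx, nz))
    # 0.8 of full scale at nominal brightness keeps headroom against clipping
    voxels[[role]] <- pmin(pmax(round(arr * 0.8 * maxdn), 0), maxdn)
  }

  stack <- image_stack(voxels, voxel_size = spec$voxel_size,
                       bit_depth = spec$bit_depth)

  shp <- footprint_shape(lab, c(dy, dx))
  cells <- data.frame(
    id = seq_len(K),
    centroid_y_um = centers[, 1], centroid_x_um = centers[, 2],
    centroid_y_px = centers[, 1] / dy + 0.5,
    centroid_x_px = centers[, 2] / dx + 0.5,
    area_um2 = areas_px * dy * dx,
    circularity = shp$circularity,
    height_um = heights,
    ciliated = ciliated,
    cilium_length_um = cil_len,
    in_field = in_field
  )
  truth <- structure(
    list(cells = cells, label_map = lab,
         tissue = list(n_cells = K,
                       # centroid-in-field count: the unbiased density count
                       # (regions only clipped by the field edge excluded)
                       n_cells_in_field = sum(in_field),
                       mean_thickness_um = lam + mean(heights),
                       laminin_thickness_um = lam)),
    class = "tissue_truth")
  list(stack = stack, truth = truth)
}

# perimeter of one object's 8-connected contour after a 3-point circular
# moving average of the vertices; the smoothing removes the staircase bias
# of raw chain codes (rasterized disks come out within ~2% of 2*pi*r)
contour_perimeter <- function(xy) {
  n <- nrow(xy)
  if (n < 5) return(max(4, n))
  # 3-point vertex sums kept in exact integer arithmetic (contour
  # coordinates are pixel indices), divided by 3 only once at the end, and
  # segment lengths summed in sorted order: the estimate is then bit-exact
  # under axis flips and independent of traversal direction/start
  sy <- xy[, 1] + xy[c(n, 1:(n - 1)), 1] + xy[c(2:n, 1), 1]
  sx <- xy[, 2] + xy[c(n, 1:(n - 1)), 2] + xy[c(2:n, 1), 2]
  dy <- diff(c(sy, sy[1])); dx <- diff(c(sx, sx[1]))
  sum(sort(sqrt(dy * dy + dx * dx))) / 3
}

# area/circularity of label-map footprints, the same estimator for truth and
# measurement: pixel-count area, smoothed-contour perimeter, circularity
# 4*pi*A/P^2 clamped at 1 (the particle-analysis convention)
footprint_shape <- function(lab, pixel_size) {
  n <- max(lab)
  px2 <- pixel_size[1] * pixel_size[2]
  px1 <- sqrt(px2)
  area_px <- tabulate(lab, nbins = n)
  perim <- numeric(n)
  oc <- EBImage::ocontour(lab)
  # ocontour indexes objects by label
  for (i in seq_len(n)) {
    perim[i] <- if (i <= length(oc) && !is.null(oc[[i]]) && nrow(oc[[i]]) > 0) {
      contour_perimeter(oc[[i]])
    } else {
      sqrt(4 * pi * area_px[i])  # degenerate fallback: treat as disk
    }
  }
  area <- area_px * px2
  list(area_um2 = area,
       circularity = pmin(1, 4 * pi * area / (perim * px1)^2))
}

#' @export
print.tissue_truth <- function(x, ...) {
  cat(sprintf(
    "<tissue_truth> %d cells (%d in field), mean tissue thickness %.2f um (laminin %.2f um), %.0f%% ciliated\n",
    x$tissue$n_cells, x$tissue$n_cells_in_field, x$tissue$mean_thickness_um,
    x$tissue$laminin_thickness_um,
    100 * mean(x$cells$ciliated[x$cells$in_field])))
  invisible(x)
}

# separable Gaussian blur of a 3D array, replicate padding at the edges
gauss_blur3d <- function(arr, sigma_vox) {
  for (d in 1:3) {
    s <- sigma_vox[d]
    if (s < 0.05) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    n <- dim(arr)[d]
    out <- array(0, dim(arr))
    for (j in seq_along(k)) {
      idx <- pmin(pmax(seq_len(n) + (j - r - 1L), 1L), n)
      out <- out + k[j] * switch(d,
        arr[idx, , , drop = FALSE],
        arr[, idx, , drop = FALSE],
        arr[, , idx, drop = FALSE])
    }
    arr <- out
  }
  arr
}

#' Generate a hierarchical cohort of synthetic stacks
#'
#' Emulates the study design used for the imaging statistics: several chips
#' per condition, five fields of view per chip, each field averaged into one
#' chip-level datapoint. Every field gets an independent sub-seed derived
#' deterministically from the master seed, so a cohort is reproducible and
#' any single field can be regenerated.
#'
#' @param spec a [stack_spec()] shared by all fields.
#' @param params_by_group named list of [tissue_params()], one per group.
#' @param chips_per_group chips (statistical units) per group; default 4.
#' @param fovs_per_chip fields of view per chip; default 5.
#' @param seed master seed.
#' @param out_dir if non-`NULL`, stacks are written there as TIFF + JSON
#'   sidecar (plus a per-stack truth CSV and a cohort manifest JSON) and the
#'   returned records carry file paths instead of in-memory stacks.
#' @return A list of class `synthetic_cohort`: `fovs` (one record per field:
#'   group, chip, fov, seed, stack or path, truth), `chip_truth` (data frame
#'   of ground-truth chip-level means), and `manifest`.
#' @export
generate_cohort <- function(spec, params_by_group, chips_per_group = 4,
                            fovs_per_chip = 5, seed = 1, out_dir = NULL) {
  stopifnot(inherits(spec, "stack_spec"), is.list(params_by_group),
            length(names(params_by_group)) == length(params_by_group),
            chips_per_group >= 1, fovs_per_chip >= 1)
  groups <- names(params_by_group)
  n_fov <- length(groups) * chips_per_group * fovs_per_chip
  sub_seeds <- with_local_seed(seed, sample.int(2^31 - 2, n_fov))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  fovs <- vector("list", n_fov)
  i <- 0L
  for (g in groups) for (ch in seq_len(chips_per_group)) {
    for (fv in seq_len(fovs_per_chip)) {
      i <- i + 1L
      sim <- generate_monolayer(spec, params_by_group[[g]], sub_seeds[i])
      rec <- list(group = g, chip = paste0(g, "_chip", ch), fov = fv,
                  seed = sub_seeds[i], truth = sim$truth)
      if (is.null(out_dir)) {
        rec$stack <- sim$stack
      } else {
        base <- file.path(out_dir, sprintf("%s_chip%d_fov%d", g, ch, fv))
        write_stack(sim$stack, paste0(base, ".tif"))
        utils::write.csv(sim$truth$cells, paste0(base, "_truth.csv"),
                         row.names = FALSE)
        rec$path <- paste0(base, ".tif")
      }
      fovs[[i]] <- rec
    }
  }
  chip_truth <- do.call(rbind, lapply(split(fovs, vapply(fovs, `[[`,
                                                         "", "chip")),
                                      chip_truth_row))
  rownames(chip_truth) <- NULL
  manifest <- list(seed = seed, groups = groups,
                   chips_per_group = chips_per_group,
                   fovs_per_chip = fovs_per_chip,
                   shape = as.integer(spec$shape),
                   voxel_size_um = as.numeric(spec$voxel_size))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "cohort_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(fovs = fovs, chip_truth = chip_truth, manifest = manifest),
            class = "synthetic_cohort")
}

chip_truth_row <- function(recs) {
  tr <- lapply(recs, `[[`, "truth")
  cil <- unlist(lapply(tr, function(t) t$cells$cilium_length_um))
  # in-field cells: the population the measured per-FOV metrics refer to
  infld <- function(t, col) t$cells[[col]][t$cells$in_field]
  data.frame(
    chip = recs[[1]]$chip, group = recs[[1]]$group,
    n_fov = length(recs),
    n_cells = mean(vapply(tr, function(t) t$tissue$n_cells_in_field, 1)),
    thickness_um = mean(vapply(tr, function(t) t$tissue$mean_thickness_um, 1)),
    laminin_um = mean(vapply(tr, function(t) t$tissue$laminin_thickness_um, 1)),
    pct_ciliated = 100 * mean(vapply(tr, function(t) mean(infld(t, "ciliated")),
                                     1)),
    cilium_length_um = if (all(is.na(cil))) NA_real_ else mean(cil, na.rm = TRUE),
    mean_area_um2 = mean(vapply(tr, function(t) mean(infld(t, "area_um2")), 1)),
    mean_circularity = mean(vapply(tr, function(t)
      mean(infld(t, "circularity")), 1))
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d group(s) x %d chip(s) x %d FOV(s) = %d stacks (seed %d)\n",
    length(x$manifest$groups), x$manifest$chips_per_group,
    x$manifest$fovs_per_chip, length(x$fovs), x$manifest$seed))
  invisible(x)
}
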