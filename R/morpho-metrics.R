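# Morphometry of monolayer stacks: cell shape, ciliation, thickness,
# cilium length, 3D marker coverage, and chip-level averaging.

#' Iterative intermeans (IsoData-family) threshold
#'
#' The conventional default global threshold: iterate
#' `t <- (mean(x[x <= t]) + mean(x[x > t])) / 2` from the mid-range until
#' stable. Scale-equivariant: thresholding `k * x` with the threshold of
#' `k * x` selects the same pixels as thresholding `x`.
#'
#' @param x numeric vector/array of intensities.
#' @param method `"isodata"` (default) or `"otsu"`.
#' @return threshold value; pixels strictly above it are foreground. For a
#'   constant input the constant is returned (empty foreground).
#' @export
auto_threshold <- function(x, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  if (method == "otsu") {
    x01 <- (x - rng[1]) / diff(rng)
    t01 <- EBImage::otsu(EBImage::Image(matrix(x01, nrow = 1)), levels = 256)
    return(rng[1] + t01 * diff(rng))
  }
  t <- mean(rng)
  for (i in seq_len(100)) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) break
    t2 <- (mean(lo) + mean(hi)) / 2
    if (abs(t2 - t) <= 1e-10 * diff(rng)) { t <- t2; break }
    t <- t2
  }
  t
}

# count nuclei on a 2D plane: threshold + connected components + size filter
count_nuclei <- function(plane, pixel_size = 1, area_bounds_um2 = c(20, 400),
                         method = "isodata") {
  thr <- auto_threshold(plane, method)
  mask <- plane > thr
  if (!any(mask)) return(0L)
  comp <- EBImage::bwlabel(mask)
  sizes <- tabulate(comp[comp > 0])
  areas <- sizes * pixel_size^2
  sum(areas >= area_bounds_um2[1] & areas <= area_bounds_um2[2])
}

#' Per-cell shape statistics with area exclusion filter
#'
#' Computes apical area and circularity (`4 pi A / P^2`, clamped at 1, the
#' particle-analysis convention) for every segmented cell, then excludes
#' cells outside the area bounds and cells touching the image border, and
#' averages over the retained cells.
#'
#' @param labels a `label_map` from [segment_cells()] or an integer label
#'   matrix.
#' @param pixel_size lateral pixel size in um.
#' @param area_bounds `(min, max)` retained apical area in um^2.
#' @return list with `cells` (data frame: id, area_um2, circularity,
#'   retained), `mean_area_um2`, `mean_circularity`, `n_retained`, and
#'   `empty` (`TRUE` when no cell survives the filter; means are `NA`, never
#'   silently propagated NaN).
#' @export
cell_shape_stats <- function(labels, pixel_size = 1,
                             area_bounds = c(20, 2000)) {
  if (area_bounds[1] >= area_bounds[2]) {
    stop("`area_bounds` must be (min, max) with min < max", call. = FALSE)
  }
  lab <- as_label_matrix(labels)
  n <- max(lab)
  if (n < 1L) {
    return(list(cells = data.frame(), mean_area_um2 = NA_real_,
                mean_circularity = NA_real_, n_retained = 0L, empty = TRUE))
  }
  shp <- footprint_shape(lab, c(pixel_size, pixel_size))
  ny <- nrow(lab); nx <- ncol(lab)
  border_ids <- setdiff(unique(c(lab[1, ], lab[ny, ], lab[, 1], lab[, nx])), 0L)
  ids <- seq_len(n)
  retained <- !(ids %in% border_ids) &
    shp$area_um2 >= area_bounds[1] & shp$area_um2 <= area_bounds[2]
  cells <- data.frame(id = ids, area_um2 = as.numeric(shp$area_um2),
                      circularity = as.numeric(shp$circularity),
                      retained = retained)
  if (!any(retained)) {
    return(list(cells = cells, mean_area_um2 = NA_real_,
                mean_circularity = NA_real_, n_retained = 0L, empty = TRUE))
  }
  # sorted aggregation: means are invariant to cell enumeration order, so
  # axis-flipped inputs give bit-identical results
  list(cells = cells,
       mean_area_um2 = mean(sort(cells$area_um2[retained])),
       mean_circularity = mean(sort(cells$circularity[retained])),
       n_retained = sum(retained), empty = FALSE)
}

#' Percentage of ciliated cells
#'
#' Counts cilia as prominence-filtered maxima of the acetylated-tubulin
#' image (cilia project as bright puncta) and cells as size-filtered
#' connected components of the thresholded nuclei image, and reports
#' `100 * cilia / cells`.
#'
#' @param tubulin_plane,nuclei_plane 2D matrices of identical size.
#' @param pixel_size lateral pixel size in um.
#' @param prominence_frac maxima prominence (noise tolerance) as a fraction
#'   of the tubulin image's dynamic range. Default 0.25: cilia project as
#'   compact near-full-scale puncta well separated from cytoplasmic signal,
#'   so a quarter-range tolerance suppresses shot-noise maxima while keeping
#'   every true punctum.
#' @param smooth_sigma_um presmoothing for the cilia puncta. Default 0
#'   (raw image): cilia are near the pixel scale, so smoothing attenuates
#'   them faster than the noise floor.
#' @param nucleus_area_bounds size filter for nuclei, um^2.
#' @param method threshold method for the nuclei image.
#' @return percentage in `[0, 100]`, or `NA` when no nuclei are found.
#' @export
ciliated_fraction <- function(tubulin_plane, nuclei_plane, pixel_size = 1,
                              prominence_frac = 0.25, smooth_sigma_um = 0,
                              nucleus_area_bounds = c(20, 400),
                              method = "isodata") {
  stopifnot(identical(dim(tubulin_plane), dim(nuclei_plane)))
  n_nuc <- count_nuclei(nuclei_plane, pixel_size, nucleus_area_bounds, method)
  if (n_nuc == 0L) return(NA_real_)
  cilia <- find_nuclei_markers(tubulin_plane, prominence_frac = prominence_frac,
                               pixel_size = pixel_size,
                               smooth_sigma_um = smooth_sigma_um)
  100 * nrow(cilia) / n_nuc
}

# orthogonal (side) view: maximum projection along one lateral axis,
# returning a (z x lateral) matrix
side_view <- function(arr, axis = c("y", "x")) {
  axis <- match.arg(axis)
  keep <- if (axis == "y") 2L else 1L
  t(apply(arr, c(keep, 3L), max))
}

#' Tissue (or basement-membrane) thickness from the orthogonal view
#'
#' Projects the composite of the selected channels along one lateral axis,
#' binarizes the side view with a data-derived threshold, splits it into
#' `n_rois` equal-width vertical strips (excluding a margin at each lateral
#' edge), counts in each strip the number of distinct z-rows containing
#' foreground, converts to um via the z-step, and averages over strips.
#' With `roles = "laminin"` the same procedure measures the basement
#' membrane alone.
#'
#' @param stack an [image_stack()] with more than one z-plane.
#' @param roles channels composited for the measurement (default the
#'   tight-junction + basement-membrane + nuclei composite, capturing cells
#'   plus matrix).
#' @param n_rois number of strips (default 10).
#' @param margin fraction of the lateral extent excluded at each edge.
#' @param axis lateral axis projected over.
#' @param method threshold method.
#' @return mean thickness in um (0 for an empty stack).
#' @export
thickness <- function(stack, roles = c("zo1", "laminin", "nuclei"),
                      n_rois = 10, margin = 0.05, axis = c("y", "x"),
                      method = "isodata") {
  stopifnot(inherits(stack, "image_stack"))
  axis <- match.arg(axis)
  if (dim(stack)[3] < 2L) {
    stop("unsupported input: thickness needs a z-stack (>1 plane)",
         call. = FALSE)
  }
  if (n_rois < 1) stop("`n_rois` must be >= 1", call. = FALSE)
  roles <- intersect(roles, stack$channel_roles)
  if (!length(roles)) stop("none of the requested roles in stack",
                           call. = FALSE)
  comp <- stack$voxels[[roles[1]]]
  for (r in roles[-1]) comp <- pmax(comp, stack$voxels[[r]])
  side <- side_view(comp, axis)
  if (diff(range(side)) == 0) return(0)
  mask <- side > auto_threshold(side, method)
  if (!any(mask)) return(0)
  n_lat <- ncol(mask)
  i0 <- floor(margin * n_lat) + 1L
  i1 <- n_lat - floor(margin * n_lat)
  len <- i1 - i0 + 1L
  bounds <- i0 - 1L + round(seq(0, len, length.out = n_rois + 1L))
  dz <- stack$voxel_size["dz"]
  per_roi <- vapply(seq_len(n_rois), function(k) {
    cols <- (bounds[k] + 1L):bounds[k + 1L]
    sum(rowSums(mask[, cols, drop = FALSE]) > 0) * dz
  }, numeric(1))
  unname(mean(per_roi))
}

#' Maximum cilium length from channel-subtracted orthogonal views
#'
#' Binarizes the side views of the tubulin, pump and nuclei channels
#' separately, removes from the tubulin view everything also marked by
#' nuclei or pump (leaving only "apical" tubulin, i.e. cilia protruding
#' above the cell bodies), and reports the z-extent of the remaining signal:
#' `(max z-row - min z-row) * dz`.
#'
#' @inheritParams thickness
#' @return length in um, or `NA` when no apical tubulin survives the
#'   subtraction (distinct from a true 0).
#' @export
cilia_length <- function(stack, axis = c("y", "x"), method = "isodata") {
  stopifnot(inherits(stack, "image_stack"))
  axis <- match.arg(axis)
  if (dim(stack)[3] < 2L) {
    stop("unsupported input: cilium length needs a z-stack (>1 plane)",
         call. = FALSE)
  }
  need <- c("tubulin", "nakatpase", "nuclei")
  if (!all(need %in% stack$channel_roles)) {
    stop("stack must contain tubulin, nakatpase and nuclei channels",
         call. = FALSE)
  }
  bin_side <- function(role) {
    sv <- side_view(stack$voxels[[role]], axis)
    if (diff(range(sv)) == 0) return(sv > Inf)
    sv > auto_threshold(sv, method)
  }
  apical <- bin_side("tubulin") & !(bin_side("nakatpase") | bin_side("nuclei"))
  if (!any(apical)) return(NA_real_)
  rows <- which(rowSums(apical) > 0)
  unname((max(rows) - min(rows)) * stack$voxel_size["dz"])
}

#' Normalized 3D marker coverage (voxels per nucleus)
#'
#' Derives a global threshold from the slice nearest the stack center,
#' applies that same threshold to every slice, counts suprathreshold voxels
#' and divides by the number of nuclei in the stack (size-filtered connected
#' components of the thresholded nuclei projection). Because the threshold
#' is data-derived, the measure is invariant under uniform rescaling of the
#' channel.
#'
#' @inheritParams thickness
#' @param role the channel whose coverage is measured.
#' @param nucleus_area_bounds size filter for the nuclei count, um^2.
#' @return suprathreshold voxels per nucleus, or `NA` when no nuclei are
#'   found.
#' @export
coverage_3d <- function(stack, role, nucleus_area_bounds = c(20, 400),
                        method = "isodata") {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack)[3]
  if (nz < 3L) stop("coverage needs at least 3 z-planes", call. = FALSE)
  arr <- get_channel(stack, role)
  if (!"nuclei" %in% stack$channel_roles) {
    stop("stack must contain a nuclei channel for normalization",
         call. = FALSE)
  }
  px <- mean(stack$voxel_size[c("dy", "dx")])
  nuc_proj <- apply(get_channel(stack, "nuclei"), c(1, 2), max)
  n_nuc <- count_nuclei(nuc_proj, px, nucleus_area_bounds, method)
  if (n_nuc == 0L) return(NA_real_)
  mid <- arr[, , ceiling(nz / 2)]
  if (diff(range(mid)) == 0) return(sum(arr > mid[1]) / n_nuc)
  thr <- auto_threshold(mid, method)
  sum(arr > thr) / n_nuc
}

#' Morphometry tuning parameters
#'
#' Collects the knobs of the measurement pipeline with their defaults:
#' maxima prominence 10% of dynamic range, 2 um minimum marker separation,
#' 0.5 um segmentation presmoothing, cell area exclusion bounds
#' 20-2000 um^2, nucleus size filter 20-400 um^2, 10 thickness ROIs with a
#' 5% lateral margin, intermeans thresholding.
#'
#' @param prominence_frac maxima prominence as a fraction of dynamic range
#'   (nuclei markers).
#' @param cilia_prominence_frac maxima prominence for cilia puncta (see
#'   [ciliated_fraction()]).
#' @param min_sep_um minimum marker separation, um.
#' @param marker_smooth_um presmoothing before maxima detection, um.
#' @param segment_smooth_um presmoothing of the membrane relief, um.
#' @param lambda regularization of marker-controlled growing.
#' @param area_bounds cell area exclusion filter, um^2.
#' @param nucleus_area_bounds nucleus size filter, um^2.
#' @param n_rois,roi_margin thickness strips and lateral margin.
#' @param threshold_method `"isodata"` or `"otsu"`.
#' @param axis lateral projection axis for orthogonal views.
#' @return list of class `morphometry_params`.
#' @export
morphometry_params <- function(prominence_frac = 0.10,
                               cilia_prominence_frac = 0.25, min_sep_um = 2,
                               marker_smooth_um = 1, segment_smooth_um = 0.5,
                               lambda = 0.05,
                               area_bounds = c(20, 2000),
                               nucleus_area_bounds = c(20, 400),
                               n_rois = 10, roi_margin = 0.05,
                               threshold_method = c("isodata", "otsu"),
                               axis = c("y", "x")) {
  structure(list(prominence_frac = prominence_frac,
                 cilia_prominence_frac = cilia_prominence_frac,
                 min_sep_um = min_sep_um,
                 marker_smooth_um = marker_smooth_um,
                 segment_smooth_um = segment_smooth_um, lambda = lambda,
                 area_bounds = area_bounds,
                 nucleus_area_bounds = nucleus_area_bounds,
                 n_rois = n_rois, roi_margin = roi_margin,
                 threshold_method = match.arg(threshold_method),
                 axis = match.arg(axis)),
            class = "morphometry_params")
}

#' Full morphometry of one field of view
#'
#' Runs the whole measurement battery on one stack: nuclei markers on the
#' DAPI projection, marker-controlled segmentation of the pump stain, shape
#' statistics, ciliated-cell percentage, tissue and laminin thickness,
#' maximum cilium length, and 3D coverage of each membrane/cilium marker.
#' Metrics whose required channels are absent are reported as `NA`.
#'
#' @param stack an [image_stack()].
#' @param params a [morphometry_params()].
#' @return one-row data frame of FOV-level metrics.
#' @export
analyze_fov <- function(stack, params = morphometry_params()) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(params, "morphometry_params"))
  px <- mean(stack$voxel_size[c("dy", "dx")])
  roles <- stack$channel_roles
  has <- function(...) all(c(...) %in% roles)
  nz <- dim(stack)[3]
  out <- data.frame(mean_cell_area = NA_real_, mean_circularity = NA_real_,
                    pct_ciliated = NA_real_, tissue_thickness = NA_real_,
                    laminin_thickness = NA_real_, coverage_zo1 = NA_real_,
                    coverage_nakatpase = NA_real_, coverage_tubulin = NA_real_,
                    nuclei_per_fov = NA_real_, cilia_length = NA_real_)
  proj <- function(role) apply(get_channel(stack, role), c(1, 2), max)

  if (has("nuclei")) {
    nuc <- proj("nuclei")
    out$nuclei_per_fov <- count_nuclei(nuc, px, params$nucleus_area_bounds,
                                       params$threshold_method)
    if (has("nakatpase")) {
      markers <- find_nuclei_markers(
        nuc, prominence_frac = params$prominence_frac,
        pixel_size = px, min_sep_um = params$min_sep_um,
        smooth_sigma_um = params$marker_smooth_um)
      if (nrow(markers) > 0) {
        seg <- segment_cells(proj("nakatpase"), markers, pixel_size = px,
                             smooth_sigma_um = params$segment_smooth_um,
                             lambda = params$lambda)
        shp <- cell_shape_stats(seg, pixel_size = px,
                                area_bounds = params$area_bounds)
        out$mean_cell_area <- shp$mean_area_um2
        out$mean_circularity <- shp$mean_circularity
      }
    }
    if (has("tubulin")) {
      out$pct_ciliated <- ciliated_fraction(
        proj("tubulin"), nuc, pixel_size = px,
        prominence_frac = params$cilia_prominence_frac,
        nucleus_area_bounds = params$nucleus_area_bounds,
        method = params$threshold_method)
    }
  }
  if (nz > 1) {
    comp_roles <- intersect(c("zo1", "laminin", "nuclei"), roles)
    if (length(comp_roles)) {
      out$tissue_thickness <- thickness(stack, comp_roles,
                                        n_rois = params$n_rois,
                                        margin = params$roi_margin,
                                        axis = params$axis,
                                        method = params$threshold_method)
    }
    if (has("laminin")) {
      out$laminin_thickness <- thickness(stack, "laminin",
                                         n_rois = params$n_rois,
                                         margin = params$roi_margin,
                                         axis = params$axis,
                                         method = params$threshold_method)
    }
    if (has("tubulin", "nakatpase", "nuclei")) {
      out$cilia_length <- cilia_length(stack, axis = params$axis,
                                       method = params$threshold_method)
    }
    if (nz >= 3 && has("nuclei")) {
      for (r in intersect(c("zo1", "nakatpase", "tubulin"), roles)) {
        out[[paste0("coverage_", r)]] <- coverage_3d(
          stack, r, nucleus_area_bounds = params$nucleus_area_bounds,
          method = params$threshold_method)
      }
    }
  }
  out
}

#' Average FOV metrics into one chip-level record
#'
#' The chip is the statistical unit: metrics from its fields of view are
#' averaged (missing values excluded per metric) into one record, n = 1 for
#' the downstream group comparison. The number of FOVs contributing to each
#' metric is recorded.
#'
#' @param fov_results data frame of FOV rows (from [analyze_fov()]).
#' @param chip chip identifier.
#' @param group group label.
#' @return one-row data frame: chip, group, per-metric means, per-metric
#'   contributing-FOV counts (`n_fov_<metric>`).
#' @export
chip_summary <- function(fov_results, chip, group) {
  stopifnot(is.data.frame(fov_results), nrow(fov_results) >= 1)
  metric_cols <- names(fov_results)[vapply(fov_results, is.numeric,
                                           logical(1))]
  rec <- data.frame(chip = chip, group = group)
  for (m in metric_cols) {
    v <- fov_results[[m]]
    rec[[m]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    rec[[paste0("n_fov_", m)]] <- sum(!is.na(v))
  }
  rec
}

#' Morphometry of a whole synthetic or on-disk cohort
#'
#' Runs [analyze_fov()] on every field of a cohort and averages fields into
#' chip-level records.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()] (in-memory or
#'   written to disk).
#' @param params a [morphometry_params()].
#' @return data frame with one row per chip (the chip-level
#'   morphometry records).
#' @export
cohort_morphometry <- function(cohort, params = morphometry_params()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  chips <- split(cohort$fovs, vapply(cohort$fovs, `[[`, "", "chip"))
  recs <- lapply(chips, function(recs) {
    fov_df <- do.call(rbind, lapply(recs, function(r) {
      stack <- if (!is.null(r$stack)) r$stack else read_stack(r$path)
      analyze_fov(stack, params)
    }))
    chip_summary(fov_df, recs[[1]]$chip, recs[[1]]$group)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
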