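# Marker detection and marker-controlled segmentation of monolayer images.

# 2D Gaussian smoothing with replicate (edge-extension) boundary; FFT-based
# smoothing would wrap content across image edges and fabricate border maxima
smooth2d <- function(x, sigma_px) {
  size <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma_px)
  as.matrix(EBImage::imageData(EBImage::filter2(x, brush,
                                                boundary = "replicate")))
}

# grayscale morphological reconstruction of `marker` under `mask`
# (4-connectivity), by alternating raster sweeps until stable
grey_reconstruct <- function(marker, mask, max_iter = 1000L) {
  m <- pmin(marker, mask)
  ny <- nrow(m); nx <- ncol(m)
  for (it in seq_len(max_iter)) {
    prev <- m
    for (i in 2:ny) m[i, ] <- pmin(mask[i, ], pmax(m[i, ], m[i - 1L, ]))
    for (i in (ny - 1L):1) m[i, ] <- pmin(mask[i, ], pmax(m[i, ], m[i + 1L, ]))
    for (j in 2:nx) m[, j] <- pmin(mask[, j], pmax(m[, j], m[, j - 1L]))
    for (j in (nx - 1L):1) m[, j] <- pmin(mask[, j], pmax(m[, j], m[, j + 1L]))
    if (identical(m, prev)) break
  }
  m
}

# binary mask of regional maxima of `x` (plateau-safe, via reconstruction)
regional_maxima <- function(x, eps = NULL) {
  if (is.null(eps)) {
    rng <- diff(range(x))
    eps <- if (rng > 0) rng * 1e-6 else 1
  }
  (x - grey_reconstruct(x - eps, x)) > eps / 2
}

#' Detect nuclei markers by prominence-filtered maxima
#'
#' Finds local intensity maxima whose prominence -- the height above the
#' highest saddle connecting them to a stronger maximum -- exceeds a cutoff,
#' the same idea as the ImageJ "find maxima" noise tolerance. Implemented as
#' the h-maxima transform (grayscale reconstruction of the image lowered by
#' the prominence under itself) followed by extraction of the surviving
#' regional maxima. Maxima closer together than `min_sep_um` are merged,
#' keeping the stronger.
#'
#' @param plane 2D numeric matrix (e.g. a z-projection of the DAPI channel).
#' @param prominence required prominence in intensity units of the smoothed
#'   working image; overrides `prominence_frac`.
#' @param prominence_frac default prominence as a fraction of the smoothed
#'   image's dynamic range (default 0.10).
#' @param pixel_size lateral pixel size in um.
#' @param min_sep_um minimum marker separation in um (default 2).
#' @param smooth_sigma_um Gaussian presmoothing sigma in um (default 1,
#'   matched to nucleus scale; use less for punctate signals like cilia).
#' @return integer matrix with columns `y`, `x` (pixel coordinates), one row
#'   per marker; zero rows for an empty or flat image.
#' @export
find_nuclei_markers <- function(plane, prominence = NULL,
                                prominence_frac = 0.10, pixel_size = 1,
                                min_sep_um = 2, smooth_sigma_um = 1) {
  stopifnot(is.matrix(plane))
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("y", "x")))
  rng <- diff(range(plane))
  if (!is.finite(rng) || rng == 0) return(empty)
  sm <- plane
  s_px <- smooth_sigma_um / pixel_size
  if (s_px >= 0.3) sm <- smooth2d(plane, s_px)
  if (is.null(prominence)) prominence <- prominence_frac * diff(range(sm))
  if (prominence < 0) stop("`prominence` must be >= 0", call. = FALSE)
  if (prominence > 0) {
    hmax <- grey_reconstruct(sm - prominence, sm)
  } else {
    hmax <- sm
  }
  peaks <- regional_maxima(hmax)
  if (!any(peaks)) return(empty)
  comp <- EBImage::bwlabel(peaks)
  n <- max(comp)
  ys <- row(comp)[comp > 0]; xs <- col(comp)[comp > 0]
  ids <- comp[comp > 0]
  vals <- sm[comp > 0]
  # marker pixel per plateau component: nearest the (unrounded) centroid,
  # brightest on ties -- a rule that commutes with axis flips, unlike
  # coordinate rounding
  my <- tapply(ys, ids, mean); mx <- tapply(xs, ids, mean)
  cy <- integer(n); cx <- integer(n); strength <- numeric(n)
  for (i in seq_len(n)) {
    sel <- ids == i
    d2 <- (ys[sel] - my[i])^2 + (xs[sel] - mx[i])^2
    cand <- which(d2 == min(d2))
    best <- cand[which.max(vals[sel][cand])]
    cy[i] <- ys[sel][best]; cx[i] <- xs[sel][best]
    strength[i] <- vals[sel][best]
  }
  ord <- order(strength, decreasing = TRUE)
  keep <- logical(n)
  min_sep_px <- min_sep_um / pixel_size
  for (i in ord) {
    if (!any(keep) ||
        min(sqrt((cy[keep] - cy[i])^2 + (cx[keep] - cx[i])^2)) >= min_sep_px) {
      keep[i] <- TRUE
    }
  }
  out <- cbind(y = as.integer(cy[keep]), x = as.integer(cx[keep]))
  out[order(out[, "y"], out[, "x"]), , drop = FALSE]
}

#' Marker-controlled segmentation of the membrane stain
#'
#' Partitions a membrane-stain image (e.g. the basolateral pump channel,
#' whose bright ridges outline cells) into one region per marker, by
#' gradient-weighted region growing from the markers (EBImage's `propagate`,
#' the CellProfiler algorithm): regions expand along paths of least
#' cumulative intensity change, so growth from neighbouring markers meets at
#' the bright inter-cell ridges. Every pixel is assigned to exactly one
#' marker's region; the region count always equals the marker count.
#'
#' @param membrane_plane 2D numeric matrix of the membrane stain.
#' @param markers integer matrix with columns `y`, `x`
#'   (from [find_nuclei_markers()]), one row per cell; at least one.
#' @param pixel_size lateral pixel size in um.
#' @param smooth_sigma_um Gaussian presmoothing sigma in um (default 0.5).
#' @param lambda regularization of the growing metric: larger values weight
#'   spatial distance over intensity (default 0.05).
#' @return An object of class `label_map`: integer `labels` matrix
#'   (background-free; label i belongs to marker row i) and the `markers`
#'   used.
#' @export
segment_cells <- function(membrane_plane, markers, pixel_size = 1,
                          smooth_sigma_um = 0.5, lambda = 0.05) {
  stopifnot(is.matrix(membrane_plane))
  markers <- as.matrix(markers)
  if (nrow(markers) < 1L) stop("at least one marker is required", call. = FALSE)
  ny <- nrow(membrane_plane); nx <- ncol(membrane_plane)
  if (any(markers[, 1] < 1 | markers[, 1] > ny |
          markers[, 2] < 1 | markers[, 2] > nx)) {
    stop("invalid input: markers outside the image", call. = FALSE)
  }
  sm <- membrane_plane
  s_px <- smooth_sigma_um / pixel_size
  if (s_px >= 0.3) sm <- smooth2d(membrane_plane, s_px)
  rng <- diff(range(sm))
  if (rng > 0) sm <- (sm - min(sm)) / rng
  seeds <- matrix(0L, ny, nx)
  seeds[cbind(markers[, 1], markers[, 2])] <- seq_len(nrow(markers))
  labels <- EBImage::imageData(EBImage::propagate(sm, seeds, lambda = lambda))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, markers = markers), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d regions\n",
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  invisible(x)
}

# accept a label_map or a bare integer matrix
as_label_matrix <- function(labels) {
  if (inherits(labels, "label_map")) labels$labels else labels
}

#' Match recovered objects to ground truth
#'
#' Test/validation helpers: `match_markers` greedily pairs detected markers
#' with true centroids within a radius and reports recall and spurious
#' fraction; `label_iou` pairs each true cell footprint with the
#' best-overlapping recovered region and reports per-cell intersection over
#' union (border-touching true cells excluded, as shape analysis excludes
#' them too).
#'
#' @param markers integer matrix (`y`, `x`) of detections.
#' @param truth_px numeric matrix (`y`, `x`) of true centroids in pixels.
#' @param max_dist_px matching radius in pixels.
#' @return `match_markers`: list with `recall`, `spurious_fraction`,
#'   `n_matched`. `label_iou`: numeric vector of per-cell IoU.
#' @export
match_markers <- function(markers, truth_px, max_dist_px = 3) {
  n_true <- nrow(truth_px); n_det <- nrow(markers)
  if (n_det == 0L) {
    return(list(recall = 0, spurious_fraction = 0, n_matched = 0L))
  }
  used <- logical(n_det)
  matched <- 0L
  for (i in seq_len(n_true)) {
    d <- sqrt((markers[, 1] - truth_px[i, 1])^2 +
              (markers[, 2] - truth_px[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= max_dist_px) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(recall = matched / n_true,
       spurious_fraction = (n_det - matched) / n_det,
       n_matched = matched)
}

#' @rdname match_markers
#' @param truth_labels,seg_labels integer label matrices (truth and
#'   recovered), identical dimensions.
#' @export
label_iou <- function(truth_labels, seg_labels) {
  truth_labels <- as_label_matrix(truth_labels)
  seg_labels <- as_label_matrix(seg_labels)
  stopifnot(identical(dim(truth_labels), dim(seg_labels)))
  ny <- nrow(truth_labels); nx <- ncol(truth_labels)
  border_ids <- unique(c(truth_labels[1, ], truth_labels[ny, ],
                         truth_labels[, 1], truth_labels[, nx]))
  interior <- setdiff(sort(unique(as.integer(truth_labels))), c(0L, border_ids))
  tab <- table(truth = as.integer(truth_labels), seg = as.integer(seg_labels))
  t_size <- rowSums(tab)
  s_size <- colSums(tab)
  vapply(interior, function(tid) {
    r <- tab[as.character(tid), ]
    sid <- names(which.max(r))
    inter <- r[[sid]]
    inter / (t_size[[as.character(tid)]] + s_size[[sid]] - inter)
  }, numeric(1))
}
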