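#' Specification of a synthetic confocal acquisition
#'
#' Describes the voxel grid the simulator renders into, emulating a 60x
#' confocal field of view: by default 256 x 256 lateral pixels spanning a
#' 212.13 um square field, z-step 0.4 um (the maximum step used for confocal
#' stacks of these tissues), and all five channel roles.
#'
#' @param shape integer `(z, y, x)` voxel counts.
#' @param voxel_size numeric `(dz, dy, dx)` in um; `dz` must be <= 0.4.
#' @param channels ordered subset of
#'   `c("nuclei", "zo1", "laminin", "nakatpase", "tubulin")`.
#' @param bit_depth 8 or 16.
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(shape = c(32, 256, 256),
                       voxel_size = c(0.4, 212.13 / 256, 212.13 / 256),
                       channels = c("nuclei", "zo1", "laminin", "nakatpase",
                                    "tubulin"),
                       bit_depth = 16) {
  stopifnot(length(shape) == 3, all(shape >= 1), length(voxel_size) == 3,
            all(voxel_size > 0))
  if (voxel_size[1] > 0.4 + 1e-9) {
    stop("invalid spec: z-step must be <= 0.4 um", call. = FALSE)
  }
  allowed <- c("nuclei", "zo1", "laminin", "nakatpase", "tubulin")
  if (!length(channels) || !all(channels %in% allowed) ||
      anyDuplicated(channels)) {
    stop("invalid spec: channels must be a unique subset of {",
         paste(allowed, collapse = ", "), "}", call. = FALSE)
  }
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16", call. = FALSE)
  structure(
    list(shape = stats::setNames(as.integer(shape), c("z", "y", "x")),
         voxel_size = stats::setNames(as.numeric(voxel_size),
                                      c("dz", "dy", "dx")),
         channels = channels, bit_depth = bit_depth),
    class = "stack_spec"
  )
}

#' Tissue parameters of the monolayer forward model
#'
#' Knobs of the simulator: how dense, tall and ciliated the epithelial
#' monolayer is, how bright each stain is, and the optics/noise applied last.
#' The default seeding density matches routine culture of these cells
#' (200,000 cells/cm^2); squamous vs cuboidal phenotypes are encoded purely
#' through `mean_cell_height` and the lattice `jitter` (more jitter gives
#' more irregular, less circular footprints).
#'
#' @param cell_density cells per cm^2.
#' @param mean_cell_height mean apical-basal cell height in um.
#' @param height_cv coefficient of variation of cell heights.
#' @param laminin_thickness basement-membrane sheet thickness in um.
#' @param ciliated_fraction fraction of cells bearing a primary cilium,
#'   in `[0, 1]`.
#' @param mean_cilium_length mean cilium length in um.
#' @param cilium_length_cv coefficient of variation of cilium lengths.
#' @param junction_intensity,pump_intensity,tubulin_body_intensity relative
#'   stain brightness (arbitrary units; 1 = full scale before noise).
#' @param jitter lattice jitter as a fraction of the cell lattice spacing;
#'   controls footprint irregularity.
#' @param noise list with `gaussian_sd` (additive read noise, fraction of
#'   full scale) and `poisson_scale` (expected photon count at full scale).
#' @param psf_sigma Gaussian PSF sigma `(z, y, x)` in um; axial sigma at
#'   least twice lateral, as for a confocal pinhole.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(cell_density = 2e5,
                          mean_cell_height = 8,
                          height_cv = 0.08,
                          laminin_thickness = 1.0,
                          ciliated_fraction = 0.3,
                          mean_cilium_length = 3,
                          cilium_length_cv = 0.1,
                          junction_intensity = 1,
                          pump_intensity = 1,
                          tubulin_body_intensity = 0.2,
                          jitter = 0.15,
                          noise = list(gaussian_sd = 0.02,
                                       poisson_scale = 200),
                          psf_sigma = c(0.6, 0.25, 0.25)) {
  stopifnot(cell_density > 0, mean_cell_height > 0, height_cv >= 0,
            laminin_thickness >= 0,
            ciliated_fraction >= 0, ciliated_fraction <= 1,
            mean_cilium_length > 0, jitter >= 0,
            length(psf_sigma) == 3, all(psf_sigma >= 0))
  stopifnot(is.list(noise), noise$gaussian_sd >= 0, noise$poisson_scale > 0)
  structure(
    list(cell_density = cell_density, mean_cell_height = mean_cell_height,
         height_cv = height_cv, laminin_thickness = laminin_thickness,
         ciliated_fraction = ciliated_fraction,
         mean_cilium_length = mean_cilium_length,
         cilium_length_cv = cilium_length_cv,
         junction_intensity = junction_intensity,
         pump_intensity = pump_intensity,
         tubulin_body_intensity = tubulin_body_intensity,
         jitter = jitter, noise = noise,
         psf_sigma = stats::setNames(as.numeric(psf_sigma),
                                     c("z", "y", "x"))),
    class = "tissue_params"
  )
}
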