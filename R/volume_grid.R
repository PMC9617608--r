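# Core containers: VolumeGrid, LabelMask, AnalysisConfig.
#
# Conventions (used throughout the package):
#  - arrays are dim (nx, ny, nz), 1-based indices;
#  - physical position of voxel (i,j,k) = origin + (c(i,j,k) - 0.5) * pitch,
#    i.e. voxel centres; all lengths in nm, angles in degrees,
#    densities in um^-3 (1 um^3 = 1e9 nm^3).

#' Compartment label codes for mask volumes
#'
#' 0 = extracellular, 1 = cytosol, 2 = membrane, 3 = endoplasmic reticulum,
#' 4 = postsynaptic density, 5 = mitochondria.
#' @export
SPINE_LABELS <- c(extracellular = 0L, cytosol = 1L, membrane = 2L,
                  er = 3L, psd = 4L, mitochondria = 5L)

#' Create a volume grid
#'
#' A 3D scalar field with an isotropic physical voxel pitch. The carrier for
#' raw, smoothed, and distance-transform volumes.
#'
#' @param data 3D numeric array, dim (nx, ny, nz). `NA` marks masked voxels.
#' @param pitch voxel edge length in nm (isotropic, > 0).
#' @param origin physical offset in nm, length 3.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, pitch = 2, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3, all(dim(data) > 0),
            is.numeric(pitch), length(pitch) == 1, pitch > 0,
            length(origin) == 3)
  if (any(is.infinite(data))) stop("volume intensities must be finite")
  structure(list(data = data, pitch = as.numeric(pitch),
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, pitch %.3g nm\n",
              paste(dim(x$data), collapse = "x"), x$pitch))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Create a label mask
#'
#' Per-voxel compartment labels defining the analyzable cytosol and the
#' boundary surfaces (see [SPINE_LABELS]). An optional `domain` array tags
#' each cytosol voxel as belonging to the spine head (1) or neck (2); 0 means
#' untagged.
#'
#' @param labels 3D integer array with values in 0..5.
#' @param pitch voxel pitch in nm.
#' @param origin physical offset in nm.
#' @param domain optional 3D integer array (0 none, 1 head, 2 neck), same dim.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, pitch = 2, origin = c(0, 0, 0), domain = NULL) {
  stopifnot(length(dim(labels)) == 3, pitch > 0)
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L) || any(labels > 5L))
    stop("labels must be integers in 0..5 with no NA")
  if (is.null(domain)) {
    domain <- array(0L, dim(labels))
    domain[labels == SPINE_LABELS["cytosol"]] <- 1L
  }
  stopifnot(identical(dim(domain), dim(labels)))
  storage.mode(domain) <- "integer"
  structure(list(labels = labels, domain = domain,
                 pitch = as.numeric(pitch), origin = as.numeric(origin)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:5,
                      labels = names(SPINE_LABELS)))
  cat(sprintf("<label_mask> %s voxels, pitch %.3g nm\n",
              paste(dim(x$labels), collapse = "x"), x$pitch))
  print(tab)
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$labels)

#' Logical cytosol mask
#' @param mask a `label_mask`.
#' @return logical 3D array, TRUE on cytosol voxels.
#' @export
cytosol_mask <- function(mask) mask$labels == SPINE_LABELS["cytosol"]

#' Cytosol volume in nm^3 (optionally per domain)
#' @param mask a `label_mask`.
#' @param domain `NULL` for all cytosol, or `"head"` / `"neck"`.
#' @export
cytosol_volume <- function(mask, domain = NULL) {
  cy <- cytosol_mask(mask)
  if (!is.null(domain)) {
    dcode <- match(domain, c("head", "neck"))
    cy <- cy & mask$domain == dcode
  }
  sum(cy) * mask$pitch^3
}

#' Physical coordinates of voxel indices
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @param pitch voxel pitch (nm).
#' @param origin physical offset (nm).
#' @return numeric matrix (n x 3) of voxel-centre positions in nm.
#' @export
voxel_centers <- function(idx, pitch, origin = c(0, 0, 0)) {
  sweep((idx - 0.5) * pitch, 2, origin, `+`)
}

#' Voxel indices of physical coordinates (clamped to the grid)
#' @param pos numeric matrix (n x 3) of positions in nm.
#' @param dims grid dimensions.
#' @inheritParams voxel_centers
#' @export
position_to_voxel <- function(pos, pitch, dims, origin = c(0, 0, 0)) {
  idx <- floor(sweep(pos, 2, origin, `-`) / pitch) + 1L
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1L), dims[a])
  storage.mode(idx) <- "integer"
  idx
}

#' Analysis configuration
#'
#' Houses every tunable parameter of the pipeline. Defaults follow the
#' analysis regime of binned spine tomograms at 2 nm voxel pitch: 2 nm
#' smoothing kernel, 20 nm threshold window with offset parameter k = 0.1,
#' 4 nm stub cutoff, 4 nm volume-reconstruction kernel, a 10 nm membrane
#' shell for end-clustering analysis, and 3 nm profile bins.
#'
#' @param sigma_smooth Gaussian smoothing SD, nm.
#' @param window_size local-threshold window edge, nm.
#' @param k unitless threshold offset; positive k lowers the threshold below
#'   the local mean.
#' @param stub_min minimum terminal-branch length kept, nm.
#' @param sigma_vol Gaussian SD of the volume reconstruction kernel, nm.
#' @param filament_diameter assumed filament diameter, nm.
#' @param shell_width membrane shell width for branch-end analysis, nm.
#' @param profile_bin bin width of distance-resolved profiles, nm.
#' @param rng_seed integer seed for all stochastic steps.
#' @param threshold_form `"niblack"` (T = m - k*s) or `"mean-offset"`
#'   (T = m - k, with k in intensity units).
#' @param polarity `"absorption"` (filaments bright) or `"luminance"`
#'   (filaments dark; the volume is negated on entry to the pipeline).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(sigma_smooth = 2, window_size = 20, k = 0.1,
                            stub_min = 4, sigma_vol = 4, filament_diameter = 8,
                            shell_width = 10, profile_bin = 3, rng_seed = 1L,
                            threshold_form = c("niblack", "mean-offset"),
                            polarity = c("absorption", "luminance")) {
  threshold_form <- match.arg(threshold_form)
  polarity <- match.arg(polarity)
  lens <- c(sigma_smooth, window_size, stub_min, sigma_vol,
            filament_diameter, shell_width, profile_bin)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all length parameters must be positive")
  if (window_size <= sigma_smooth) stop("window_size must exceed sigma_smooth")
  if (window_size <= stub_min) stop("window_size must exceed stub_min")
  structure(list(sigma_smooth = sigma_smooth, window_size = window_size,
                 k = k, stub_min = stub_min, sigma_vol = sigma_vol,
                 filament_diameter = filament_diameter,
                 shell_width = shell_width, profile_bin = profile_bin,
                 rng_seed = as.integer(rng_seed),
                 threshold_form = threshold_form, polarity = polarity),
            class = "analysis_config")
}
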