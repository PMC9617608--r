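# Cytosol masking, denoising, local-threshold binarization and the k-sweep.

#' Mask the analyzable intracellular space
#'
#' Voxels outside the cytosol (extracellular space, membrane, ER, PSD,
#' mitochondria) are set to `NA` and excluded from every later statistic;
#' cytosol intensities are unchanged.
#'
#' @param volume a [volume_grid].
#' @param mask a [label_mask] of the same shape.
#' @return a masked [volume_grid].
#' @export
mask_intracellular <- function(volume, mask) {
  stopifnot(identical(dim(volume$data), dim(mask$labels)))
  cy <- cytosol_mask(mask)
  if (!any(cy)) stop("mask contains no cytosol voxels")
  d <- volume$data
  d[!cy] <- NA_real_
  volume_grid(d, pitch = volume$pitch, origin = volume$origin)
}

gaussian_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma_vox))
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

conv3d_separable <- function(a, k1, k2 = k1, k3 = k1) {
  d <- dim(a)
  a <- cpp_conv_axis(as.numeric(a), d, k1, 0L)
  a <- cpp_conv_axis(a, d, k2, 1L)
  a <- cpp_conv_axis(a, d, k3, 2L)
  array(a, d)
}

#' Gaussian smoothing in physical units
#'
#' Isotropic Gaussian convolution with SD `sigma` nm (`sigma/pitch` voxels).
#' Masked (`NA`) voxels are excluded via a renormalized (masked) convolution,
#' so intensities never bleed across the mask; masked voxels stay `NA`.
#'
#' @param volume a [volume_grid] (possibly masked).
#' @param sigma Gaussian SD, nm.
#' @return a smoothed [volume_grid].
#' @export
gaussian_smooth <- function(volume, sigma = 2) {
  stopifnot(sigma > 0)
  if (sigma < volume$pitch / 2)
    warning("smoothing kernel under-resolved: sigma < pitch/2")
  k <- gaussian_kernel_1d(sigma / volume$pitch)
  w <- !is.na(volume$data)
  x <- volume$data
  x[!w] <- 0
  num <- conv3d_separable(x, k)
  den <- conv3d_separable(array(as.numeric(w), dim(x)), k)
  out <- num / den
  out[!w] <- NA_real_
  volume_grid(out, pitch = volume$pitch, origin = volume$origin)
}

#' Local-threshold binarization
#'
#' For each unmasked voxel, the local mean `m` and local SD `s` are computed
#' over a cubic window (masked voxels excluded); the threshold is
#' `T = m - k*s` (Niblack form; `"mean-offset"` uses `T = m - k` with `k` in
#' intensity units). A voxel is foreground iff its intensity is strictly
#' greater than `T`, on absorption polarity (filaments bright). Constant
#' regions therefore yield background. Windows with fewer than 8 valid
#' voxels classify as background.
#'
#' @param volume a masked [volume_grid] in absorption polarity.
#' @param window_size cubic window edge, nm (rounded to the nearest odd voxel
#'   span, minimum 3).
#' @param k unitless offset; positive k lowers the threshold below the local
#'   mean.
#' @param form `"niblack"` or `"mean-offset"`.
#' @return a [binarized_volume]; foreground is always a subset of the
#'   unmasked voxels.
#' @export
local_threshold_binarize <- function(volume, window_size = 20, k = 0.1,
                                     form = c("niblack", "mean-offset")) {
  form <- match.arg(form)
  d <- dim(volume$data)
  wvox <- round(window_size / volume$pitch)
  wvox <- max(3L, as.integer(wvox) + as.integer(wvox %% 2 == 0))
  r <- (wvox - 1L) %/% 2L
  valid <- !is.na(volume$data)
  x <- volume$data
  x[!valid] <- 0

  boxsum <- function(a) {
    a <- cpp_boxsum_axis(as.numeric(a), d, r, 0L)
    a <- cpp_boxsum_axis(a, d, r, 1L)
    array(cpp_boxsum_axis(a, d, r, 2L), d)
  }
  n <- boxsum(array(as.numeric(valid), d))
  s1 <- boxsum(x)
  m <- s1 / pmax(n, 1)
  if (form == "niblack") {
    s2 <- boxsum(x^2)
    svar <- pmax(0, s2 / pmax(n, 1) - m^2)
    thr <- m - k * sqrt(svar)
  } else {
    thr <- m - k
  }
  fg <- valid & n >= 8 & (volume$data > thr)
  fg[is.na(fg)] <- FALSE
  binarized_volume(fg, pitch = volume$pitch, origin = volume$origin,
                   provenance = list(window_size = window_size, k = k,
                                     form = form, window_voxels = wvox))
}

#' Sweep the binarization parameter k
#'
#' For each k the volume is binarized and skeletonized and the four summary
#' statistics are recorded: foreground fraction of the cytosol, Pearson
#' correlation between the absorption intensity and the binary field over
#' the cytosol, cumulative branch length, node density (rank >= 3), and the
#' reconstructed cytoskeleton volume fraction. The point of the sweep is
#' that the topology-derived statistics vary far less with k than the raw
#' foreground volume does.
#'
#' @param volume an (unmasked) [volume_grid] in absorption polarity.
#' @param mask a [label_mask].
#' @param k_values numeric vector of at least 2 values.
#' @param config an [analysis_config].
#' @return data.frame with one row per k.
#' @export
binarization_sweep <- function(volume, mask, k_values,
                               config = analysis_config()) {
  stopifnot(length(k_values) >= 2)
  masked <- mask_intracellular(volume, mask)
  sm <- gaussian_smooth(masked, config$sigma_smooth)
  cy <- cytosol_mask(mask)
  ncy <- sum(cy)
  rows <- lapply(k_values, function(k) {
    b <- local_threshold_binarize(sm, config$window_size, k,
                                  form = config$threshold_form)
    nfg <- sum(b$foreground)
    r <- suppressWarnings(cor(as.numeric(sm$data[cy]),
                              as.numeric(b$foreground[cy])))
    if (nfg == 0) {
      return(data.frame(k = k, foreground_fraction = 0, pearson_r = NA_real_,
                        cumulative_branch_length = 0, node_density = 0,
                        actin_volume_fraction = 0, empty = TRUE))
    }
    sk <- topological_thinning(b)
    sk <- prune_stubs(sk, config$stub_min)
    g <- build_graph(sk, mask)
    ok <- !g$branches$excluded
    cum_len <- sum(g$branches$arc_length[ok])
    nd <- node_density(g, mask)$density_per_um3[1]
    vf <- cytoskeleton_volume_fraction(g, mask, config$sigma_vol)$fraction[1]
    data.frame(k = k, foreground_fraction = nfg / ncy, pearson_r = r,
               cumulative_branch_length = cum_len, node_density = nd,
               actin_volume_fraction = vf, empty = FALSE)
  })
  do.call(rbind, rows)
}
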