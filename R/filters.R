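# Micro-CT preprocessing: histogram normalisation, Perona-Malik diffusion,
# global thresholding and metal-artefact compensation.

#' Reference histogram for intensity normalisation
#'
#' Either supply `bin_edges` + `cumulative_mass` directly, or derive them
#' from a reference image/volume (256 bins over its observed range by
#' default).
#'
#' @param x numeric data (volume/image) to derive the reference from.
#' @param bin_edges monotone vector of bin edges.
#' @param cumulative_mass nondecreasing vector in \[0,1\] (one per edge),
#'   ending at 1.
#' @param n_bins number of bins when deriving from data.
#' @return object of class `reference_histogram`.
#' @export
reference_histogram <- function(x = NULL, bin_edges = NULL,
                                cumulative_mass = NULL, n_bins = 256) {
  if (!is.null(x)) {
    v <- as.numeric(as_plain(x))
    rng <- range(v)
    if (diff(rng) == 0) stop("reference_histogram: constant input")
    bin_edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    cm <- c(0, cumsum(tabulate(pmin(n_bins, pmax(1, findInterval(
      v, bin_edges, rightmost.closed = TRUE))), n_bins)))
    cumulative_mass <- cm / cm[length(cm)]
  }
  if (is.null(bin_edges) || is.null(cumulative_mass))
    stop("reference_histogram: supply data or bin_edges + cumulative_mass")
  if (is.unsorted(bin_edges)) stop("reference_histogram: bin_edges must be monotone")
  if (is.unsorted(cumulative_mass) || abs(cumulative_mass[length(cumulative_mass)] - 1) > 1e-9)
    stop("reference_histogram: cumulative_mass must be nondecreasing and end at 1")
  structure(list(bin_edges = bin_edges, cumulative_mass = cumulative_mass),
            class = "reference_histogram")
}

#' Normalise intensities to a predefined histogram
#'
#' Monotone quantile matching: each voxel is mapped through the composition
#' of the input empirical CDF and the inverse reference CDF, so the output
#' distribution matches the reference within binning error while the voxel
#' rank order is preserved.
#'
#' @param vol a `vol3d` or `section2d` (non-constant).
#' @param ref a [reference_histogram()].
#' @return same container with remapped intensities.
#' @export
normalize_histogram <- function(vol, ref) {
  stopifnot(inherits(ref, "reference_histogram"))
  v <- as.numeric(as_plain(vol))
  if (diff(range(v)) == 0)
    stop("normalize_histogram: constant input has undefined quantiles")
  # binned input CDF (same resolution as the reference), interpolated
  # within bins so the map is monotone and self-normalisation is the
  # identity up to a bin width
  n_bins <- length(ref$bin_edges) - 1L
  rng <- range(v)
  edges_in <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- tabulate(pmin(n_bins, pmax(1, findInterval(
    v, edges_in, rightmost.closed = TRUE))), n_bins)
  cm_in <- c(0, cumsum(cnt)) / length(v)
  r <- approx(edges_in, cm_in, xout = v, rule = 2)$y
  # strictly increasing version of the reference CDF for inversion
  cm <- ref$cumulative_mass
  keep <- c(TRUE, diff(cm) > 0)
  out <- approx(cm[keep], ref$bin_edges[keep], xout = r, rule = 2)$y
  d <- dim(vol)
  res <- array(out, d)
  if (inherits(vol, "section2d")) section2d(res, spacing_um(vol))
  else vol3d(res, spacing_um(vol))
}

#' Perona-Malik anisotropic diffusion
#'
#' Explicit conservative scheme with conductance
#' `g(|grad I|) = exp(-(|grad I|/kappa)^2)` and Neumann (no-flux)
#' boundaries; the intensity mean is conserved exactly and the scheme obeys
#' the discrete maximum principle for steps within the stability bound.
#'
#' @param x matrix, 3D array, `vol3d` or `section2d`.
#' @param params a [diffusion_params()].
#' @return filtered object of the same shape/class.
#' @export
anisotropic_diffusion <- function(x, params = diffusion_params()) {
  stopifnot(inherits(params, "diffusion_params"))
  d <- dim(x)
  is2d <- length(d) == 2L
  dim3 <- if (is2d) c(d, 1L) else d
  bound <- if (is2d) 0.25 else 1 / 6
  step <- if (is.null(params$step)) (if (is2d) 0.125 else 1 / 16) else params$step
  if (step <= 0 || step > bound + 1e-12)
    stop(sprintf("anisotropic_diffusion: step %g outside stability bound (0, %g]",
                 step, bound))
  v <- as_plain(x)
  if (!is.double(v)) v <- v + 0.0
  kappa <- params$kappa
  if (is.null(kappa)) kappa <- max(0.1 * diff(range(v)), 1e-9)
  if (params$iterations == 0L) return(x)
  out <- pm_diffusion_cpp(v, as.integer(dim3), params$iterations, kappa, step)
  out <- array(out, d)
  if (inherits(x, "section2d")) section2d(out, spacing_um(x))
  else if (inherits(x, "vol3d")) vol3d(out, spacing_um(x))
  else out
}

# smoothed 256-bin histogram modes of an image, ordered by intensity.
# Returns intensities of local maxima with at least `min_prom` of the
# largest count.
histogram_modes <- function(v, n_bins = 256, smooth = 5, min_prom = 0.05) {
  if (length(v) > 4e6) v <- v[seq.int(1L, length(v), length.out = 4e6)]
  rng <- range(v)
  if (diff(rng) == 0) return(numeric(0))
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- tabulate(pmin(n_bins, pmax(1, findInterval(v, br, rightmost.closed = TRUE))),
                  n_bins)
  k <- rep(1 / smooth, smooth)
  pad <- (smooth - 1) / 2
  cs <- as.numeric(stats::filter(c(rep(cnt[1], pad), cnt, rep(cnt[n_bins], pad)), k))
  cs <- cs[pad + seq_len(n_bins)]
  mid <- (br[-1] + br[-length(br)]) / 2
  is_max <- vapply(seq_len(n_bins), function(i) {
    lo <- max(1, i - pad - 1); hi <- min(n_bins, i + pad + 1)
    cs[i] >= max(cs[lo:hi])
  }, logical(1))
  idx <- which(is_max)
  if (!length(idx)) return(numeric(0))
  # collapse plateaus / adjacent maxima closer than a few bins
  groups <- cumsum(c(1, diff(idx) > smooth))
  idx <- vapply(split(idx, groups), function(g) g[which.max(cs[g])],
                numeric(1))
  # topographic prominence gate: a mode must rise above the deepest valley
  # separating it from any higher peak, so histogram noise does not count
  ord <- idx[order(-cs[idx])]
  accepted <- ord[1]
  # relative floor plus a Poisson-noise floor for sparse histograms
  thr <- max(min_prom * max(cs), 4 * sqrt(max(cs) / smooth))
  for (i in ord[-1]) {
    valleys <- vapply(accepted, function(a)
      min(cs[seq(min(a, i), max(a, i))]), numeric(1))
    if (cs[i] - max(valleys[cs[accepted] >= cs[i]]) >= thr)
      accepted <- c(accepted, i)
  }
  sort(mid[accepted])
}

#' Otsu threshold
#' @param v numeric vector of intensities.
#' @param n_bins histogram bins.
#' @return threshold value maximising between-class variance.
#' @export
otsu_threshold <- function(v, n_bins = 256) {
  if (length(v) > 4e6) v <- v[seq.int(1L, length(v), length.out = 4e6)]
  rng <- range(v)
  if (diff(rng) == 0) stop("otsu_threshold: constant input")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- tabulate(pmin(n_bins, pmax(1, findInterval(v, br, rightmost.closed = TRUE))),
                  n_bins)
  mid <- (br[-1] + br[-length(br)]) / 2
  w <- cnt / sum(cnt)
  omega <- cumsum(w); mu <- cumsum(w * mid); mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  # centre of the argmax plateau: for well-separated modes the criterion
  # is flat between them and the midpoint is the unbiased cut
  best <- which(sb >= max(sb) - 1e-12 * max(sb))
  mid[round(mean(range(best)))]
}

#' Global thresholding
#'
#' `method = "value"` thresholds at `value`; `"otsu"` uses Otsu's
#' criterion; `"peak_average"` reproduces a calibrated titanium threshold:
#' for each calibration image the highest-intensity histogram mode (the
#' titanium peak) is found, the peaks are averaged across calibration
#' images, and the threshold is placed at the midpoint between that
#' averaged peak and the (averaged) next-lower mode.  With
#' `polarity = "bright"` the mask selects values >= threshold; with
#' `"dark"`, values <= threshold.
#'
#' @param x image or volume.
#' @param value explicit threshold (implies `method = "value"`).
#' @param method one of `"value"`, `"peak_average"`, `"otsu"`.
#' @param calibration list of images/volumes for `"peak_average"`
#'   (defaults to `list(x)`).
#' @param polarity `"bright"` or `"dark"`.
#' @return binary mask of the same class, with attribute `threshold`.
#' @export
global_threshold <- function(x, value = NULL,
                             method = c("value", "peak_average", "otsu"),
                             calibration = NULL,
                             polarity = c("bright", "dark")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  v <- as.numeric(as_plain(x))
  if (!is.null(value)) method <- "value"
  thr <- switch(method,
    value = {
      if (is.null(value)) stop("global_threshold: method 'value' needs `value`")
      value
    },
    otsu = otsu_threshold(v),
    peak_average = {
      if (is.null(calibration)) calibration <- list(x)
      if (!length(calibration))
        stop("global_threshold: peak_average needs at least one calibration image")
      peaks <- lapply(calibration, function(ci)
        histogram_modes(as.numeric(as_plain(ci))))
      if (any(vapply(peaks, length, 1L) < 2))
        stop(paste("global_threshold: peak_average failed: unimodal histogram,",
                   "cannot separate the titanium peak from the next-lower mode"))
      ti <- mean(vapply(peaks, function(p) p[length(p)], 1))
      lo <- mean(vapply(peaks, function(p) p[length(p) - 1], 1))
      (ti + lo) / 2
    })
  m <- if (polarity == "bright") v >= thr else v <= thr
  d <- dim(x)
  out <- array(as.integer(m), d)
  res <- if (inherits(x, "section2d")) section2d(out, spacing_um(x), labels = TRUE)
  else if (inherits(x, "vol3d")) vol3d(out, spacing_um(x), labels = TRUE)
  else out
  attr(res, "threshold") <- thr
  res
}

#' Metal-artefact compensation by banded median inpainting
#'
#' Intensities within `band_um` of titanium are iteratively resampled:
#' each pass replaces every band voxel by the median of the non-titanium
#' values in its `(2*window+1)^3` neighbourhood (band voxels included, so
#' streak oscillations are averaged out in place rather than overwritten
#' from outside).  Iteration stops when the bone-threshold classification
#' of band voxels changes by less than `tol` (fraction), or at `max_iter`.
#' Voxels outside the band are never modified.
#'
#' @param vol intensity `vol3d`.
#' @param titanium_mask binary titanium mask on the same grid.
#' @param band_um width of the corrected band around titanium (um).
#' @param max_iter maximum iterations (0 = identity).
#' @param tol stopping tolerance on the changed classification fraction.
#' @param bone_threshold intensity threshold used by the stopping rule.
#' @param window median window radius (voxels).
#' @return corrected `vol3d`.
#' @export
metal_artifact_correction <- function(vol, titanium_mask, band_um = 45,
                                      max_iter = 3, tol = 0.005,
                                      bone_threshold = NULL, window = 1L) {
  stopifnot(inherits(vol, "vol3d"))
  sp <- spacing_um(vol)
  ti <- as_plain(titanium_mask) > 0
  if (!any(ti)) stop("metal_artifact_correction: titanium mask is empty")
  d <- dim(vol)
  dist <- chamfer_distance_cpp(array(as.integer(ti), d), d, rep(sp, 3))
  band <- array(dist <= band_um, d) & !ti
  if (all(band | ti))
    stop("metal_artifact_correction: band covers the entire non-titanium volume")
  v <- array(as.numeric(as_plain(vol)), d)
  if (max_iter == 0 || !any(band)) return(vol)
  if (is.null(bone_threshold)) bone_threshold <- median(v[!ti & !band])
  allowed <- array(as.integer(!ti), d)
  bandi <- array(as.integer(band), d)
  cls <- v[band] >= bone_threshold
  for (it in seq_len(max_iter)) {
    v <- median_band_cpp(v, d, bandi, allowed, as.integer(window))
    cls_new <- v[band] >= bone_threshold
    changed <- mean(cls != cls_new)
    cls <- cls_new
    if (changed < tol) break
  }
  vol3d(v, sp)
}
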