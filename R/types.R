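#' @useDynLib scafreg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx median optim quantile rnorm runif sd setNames pt qt
#' @importFrom utils head read.csv write.csv
NULL

# ---- containers -----------------------------------------------------------

#' Create a 3D volume
#'
#' A `vol3d` is a numeric 3D array with an isotropic voxel spacing in
#' micrometres.  Voxel `[i, j, k]` has physical coordinates
#' `((i-1)*s, (j-1)*s, (k-1)*s)` micrometres, measured from the centre of
#' the corner voxel; x is the fastest-varying index.
#'
#' @param data numeric 3D array.
#' @param spacing_um isotropic voxel size in micrometres.
#' @param labels logical; if `TRUE` the volume stores integer class labels.
#' @return object of class `vol3d` (and `labelvol` for label data).
#' @export
vol3d <- function(data, spacing_um, labels = FALSE) {
  if (length(dim(data)) != 3L) stop("vol3d: `data` must be a 3D array")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("vol3d: `spacing_um` must be a positive scalar")
  if (labels) storage.mode(data) <- "integer"
  structure(data, spacing_um = as.numeric(spacing_um),
            class = c(if (labels) "labelvol", "vol3d"))
}

#' Create a 2D section image
#'
#' Grayscale sections are matrices; RGB sections are `nx x ny x 3` arrays
#' (values on a 0-255 scale).  `spacing_um` is the pixel size.
#'
#' @param data matrix or `nx x ny x 3` array.
#' @param spacing_um pixel size in micrometres.
#' @param labels logical; integer label image.
#' @return object of class `section2d`.
#' @export
section2d <- function(data, spacing_um, labels = FALSE) {
  nd <- length(dim(data))
  if (!(nd == 2L || (nd == 3L && dim(data)[3] == 3L)))
    stop("section2d: `data` must be a matrix or an nx x ny x 3 RGB array")
  if (labels) storage.mode(data) <- "integer"
  structure(data, spacing_um = as.numeric(spacing_um),
            class = c(if (labels) "labelsec", "section2d"))
}

#' Voxel / pixel spacing in micrometres
#' @param x a `vol3d` or `section2d`.
#' @return numeric scalar.
#' @export
spacing_um <- function(x) {
  s <- attr(x, "spacing_um")
  if (is.null(s)) stop("object carries no spacing_um attribute")
  s
}

is_rgb <- function(x) length(dim(x)) == 3L && dim(x)[3] == 3L

# strip classes/attributes, return plain array (dim only)
as_plain <- function(x) {
  a <- x
  attributes(a) <- list(dim = dim(x))
  a
}

# logical mask from any numeric/integer/logical array, minimal copying
as_mask_fast <- function(x) {
  a <- x > 0
  attributes(a) <- list(dim = dim(x))
  a
}

# one 6-neighbour (face) dilation of a logical array (2D or 3D)
dilate_mask <- function(m, steps = 1L) {
  d <- dim(m)
  dim3 <- if (length(d) == 2L) c(d, 1L) else d
  a <- array(as.integer(m), dim3)
  for (s in seq_len(steps)) a <- dilate6_cpp(a, dim3)
  array(a > 0L, d)
}

# ---- rigid pose -----------------------------------------------------------

#' Rigid pose of a section plane inside a volume
#'
#' Six-parameter rigid transform: intrinsic Z-Y-X Euler angles (degrees)
#' and a translation (micrometres), both relative to the volume's physical
#' centre, plus the slab thickness.  A section point `(u, v, w)` (u, v
#' in-plane about the section centre, w along the plane normal) maps to the
#' volume physical point `centre + translation + R %*% c(u, v, w)`.
#'
#' @param euler_deg rotations about z, y, x (intrinsic, degrees).
#' @param translation_um translation vector, micrometres.
#' @param thickness_um slab thickness, micrometres (>= 0).
#' @return object of class `rigid_pose`.
#' @export
rigid_pose <- function(euler_deg = c(0, 0, 0), translation_um = c(0, 0, 0),
                       thickness_um = 0) {
  stopifnot(length(euler_deg) == 3L, length(translation_um) == 3L,
            length(thickness_um) == 1L, thickness_um >= 0)
  e <- ((as.numeric(euler_deg) + 180) %% 360) - 180
  e[e == -180] <- 180            # normalise to (-180, 180]
  structure(list(euler_deg = e, translation_um = as.numeric(translation_um),
                 thickness_um = as.numeric(thickness_um)),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("rigid_pose: euler ZYX (deg) = [%.3f, %.3f, %.3f], t (um) = [%.2f, %.2f, %.2f], thickness = %.1f um\n",
              x$euler_deg[1], x$euler_deg[2], x$euler_deg[3],
              x$translation_um[1], x$translation_um[2], x$translation_um[3],
              x$thickness_um))
  invisible(x)
}

#' Rotation matrix of a rigid pose
#'
#' Intrinsic Z-Y-X convention: `R = Rz(a) %*% Ry(b) %*% Rx(c)`.
#' @param euler_deg length-3 numeric, degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(euler_deg) {
  a <- euler_deg[1] * pi / 180; b <- euler_deg[2] * pi / 180
  c <- euler_deg[3] * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Euler angles (ZYX intrinsic, degrees) from a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return length-3 numeric.
#' @export
matrix_to_euler <- function(R) {
  b <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(R[2, 1], R[1, 1])
    c <- atan2(R[3, 2], R[3, 3])
  } else {             # gimbal lock: fold everything into a
    a <- atan2(-R[1, 2], R[2, 2])
    c <- 0
  }
  c(a, b, c) * 180 / pi
}

# physical centre of a volume (um)
vol_center <- function(vol) {
  (dim(vol) - 1) / 2 * spacing_um(vol)
}

# compose a pose with an in-plane / full correction expressed in the
# section frame: R' = R %*% Rz(th) %*% Ry(phi) %*% Rx(psi),
# t' = t + R %*% c(du, dv, dw)
compose_pose <- function(pose, th = 0, phi = 0, psi = 0,
                         du = 0, dv = 0, dw = 0) {
  R0 <- euler_to_matrix(pose$euler_deg)
  R1 <- R0 %*% euler_to_matrix(c(th, phi, psi))
  t1 <- pose$translation_um + as.numeric(R0 %*% c(du, dv, dw))
  rigid_pose(matrix_to_euler(R1), t1, pose$thickness_um)
}

#' Difference between two rigid poses
#'
#' @param a,b `rigid_pose` objects.
#' @return list with `rotation_deg` (geodesic angle between the two
#'   rotations) and `translation_um` (displacement of the section centre).
#' @export
pose_difference <- function(a, b) {
  Ra <- euler_to_matrix(a$euler_deg); Rb <- euler_to_matrix(b$euler_deg)
  Rd <- t(Ra) %*% Rb
  ang <- acos(pmin(1, pmax(-1, (sum(diag(Rd)) - 1) / 2))) * 180 / pi
  list(rotation_deg = ang,
       translation_um = sqrt(sum((a$translation_um - b$translation_um)^2)))
}

# ---- parameter records ----------------------------------------------------

#' Scaffold design parameters
#'
#' Cylindrical lattice of three orthogonal families of cylindrical struts.
#' Defaults are the printed design of the implant this package emulates:
#' cylinder diameter 3 mm, height 1.8 mm, strut diameter 180 um; the
#' lattice pitch (not printed) is fixed at 400 um, which the
#' inclusion-exclusion volume formula shows reproduces the printed 65 %
#' porosity.
#'
#' @param diameter_mm,height_mm cylinder dimensions (mm).
#' @param strut_diameter_um strut diameter (um).
#' @param lattice_pitch_um lattice period (um).
#' @param voxel_size_um voxelisation grid spacing (um); struts must span at
#'   least 4 voxels.
#' @param roughness_um SD of the smooth axial strut-radius modulation
#'   emulating the as-built surface roughness of selective laser melting
#'   (0 = ideal CAD lattice).  Applied with a fixed internal seed: the
#'   as-built implant is one reproducible object.  Without it a perfectly
#'   periodic lattice would be ambiguous under whole-pitch translations,
#'   which the real rough implant is not.
#' @return object of class `scaffold_design`.
#' @export
scaffold_design <- function(diameter_mm = 3.0, height_mm = 1.8,
                            strut_diameter_um = 180, lattice_pitch_um = 400,
                            voxel_size_um = 9, roughness_um = 15) {
  d <- list(diameter_mm = diameter_mm, height_mm = height_mm,
            strut_diameter_um = strut_diameter_um,
            lattice_pitch_um = lattice_pitch_um,
            voxel_size_um = voxel_size_um, roughness_um = roughness_um)
  if (roughness_um < 0) stop("scaffold_design: roughness_um must be >= 0")
  if (any(unlist(d)[1:5] <= 0)) stop("scaffold_design: all parameters must be positive")
  if (strut_diameter_um >= lattice_pitch_um)
    stop("scaffold_design: strut_diameter_um must be smaller than lattice_pitch_um")
  if (diameter_mm < 2 * lattice_pitch_um / 1000 ||
      height_mm < 2 * lattice_pitch_um / 1000)
    stop("scaffold_design: cylinder must span at least two lattice pitches")
  if (voxel_size_um > strut_diameter_um / 4)
    stop(sprintf(paste0("scaffold_design: voxel_size_um (%g) must be <= ",
                        "strut_diameter_um/4 (%g): struts must span >= 4 voxels"),
                 voxel_size_um, strut_diameter_um / 4))
  structure(d, class = "scaffold_design")
}

#' Forward micro-CT simulation parameters
#'
#' Class intensities are on an 8-bit-like scale and must be strictly
#' ordered titanium > bone > soft > background.  The point-spread function
#' is an isotropic Gaussian; streaks are in-plane interference patterns
#' anchored at (i.e. windowed by the blurred neighbourhood of) titanium.
#'
#' @param titanium_intensity,bone_intensity,soft_intensity,background_intensity
#'   class mean intensities.
#' @param psf_sigma_um Gaussian PSF sigma (um).
#' @param noise_sd additive Gaussian noise SD.
#' @param streak_amplitude amplitude of metal streaks.
#' @param streak_count number of streak orientations.
#' @param seed integer RNG seed.
#' @return object of class `ct_sim_params`.
#' @export
ct_sim_params <- function(titanium_intensity = 220, bone_intensity = 120,
                          soft_intensity = 60, background_intensity = 20,
                          psf_sigma_um = 9, noise_sd = 5,
                          streak_amplitude = 8, streak_count = 12,
                          seed = 1L) {
  p <- list(titanium_intensity = titanium_intensity,
            bone_intensity = bone_intensity, soft_intensity = soft_intensity,
            background_intensity = background_intensity,
            psf_sigma_um = psf_sigma_um, noise_sd = noise_sd,
            streak_amplitude = streak_amplitude,
            streak_count = as.integer(streak_count), seed = as.integer(seed))
  ints <- c(titanium_intensity, bone_intensity, soft_intensity,
            background_intensity)
  if (any(diff(ints) >= 0))
    stop("ct_sim_params: intensities must satisfy titanium > bone > soft > background")
  if (psf_sigma_um < 0 || noise_sd < 0 || streak_amplitude < 0 || streak_count < 0)
    stop("ct_sim_params: noise parameters must be >= 0")
  structure(p, class = "ct_sim_params")
}

#' Histology simulation parameters
#'
#' Models ground-section brightfield histology of a resin-embedded
#' specimen: a 50-80 um slab, anisotropic in-plane shrinkage of the
#' tissue (the titanium is rigid and exempt), a separation gap opened at
#' the bone-implant interface, an optional smooth elastic warp, and stain
#' colouring with multiplicative noise.
#'
#' @param thickness_um section thickness (um), 50-80 by default.
#' @param stain_color_bone,stain_color_soft,stain_color_titanium,stain_color_background
#'   RGB triples on a 0-255 scale.
#' @param shrink_x,shrink_y in-plane scale factors in (0, 1].
#' @param separation_um gap opened at the bone-implant interface (um).
#' @param elastic_warp_amplitude_um amplitude of the smooth residual warp (um).
#' @param color_noise_sd multiplicative log-normal colour noise SD.
#' @param seed integer RNG seed.
#' @return object of class `histology_sim_params`.
#' @export
histology_sim_params <- function(thickness_um = 60,
                                 stain_color_bone = c(195, 90, 120),
                                 stain_color_soft = c(150, 110, 185),
                                 stain_color_titanium = c(40, 38, 42),
                                 stain_color_background = c(240, 236, 228),
                                 shrink_x = 1, shrink_y = 1,
                                 separation_um = 0,
                                 elastic_warp_amplitude_um = 0,
                                 color_noise_sd = 0.02, seed = 1L) {
  if (thickness_um <= 0) stop("histology_sim_params: thickness_um must be > 0")
  if (shrink_x <= 0 || shrink_x > 1 || shrink_y <= 0 || shrink_y > 1)
    stop("histology_sim_params: shrink factors must lie in (0, 1]")
  if (separation_um < 0 || elastic_warp_amplitude_um < 0)
    stop("histology_sim_params: deformation amplitudes must be >= 0")
  structure(list(thickness_um = thickness_um,
                 stain_color_bone = stain_color_bone,
                 stain_color_soft = stain_color_soft,
                 stain_color_titanium = stain_color_titanium,
                 stain_color_background = stain_color_background,
                 shrink_x = shrink_x, shrink_y = shrink_y,
                 separation_um = separation_um,
                 elastic_warp_amplitude_um = elastic_warp_amplitude_um,
                 color_noise_sd = color_noise_sd, seed = as.integer(seed)),
            class = "histology_sim_params")
}

#' Anisotropic diffusion parameters
#'
#' Explicit Perona-Malik scheme with conductance
#' `g(|grad I|) = exp(-(|grad I|/kappa)^2)`.  The time step must respect
#' the explicit-scheme stability bound: `step <= 0.25` in 2D and
#' `step <= 1/6` in 3D.  `kappa = NULL` defaults to 10 % of the intensity
#' range of the filtered image at call time.
#'
#' @param iterations number of explicit steps.
#' @param kappa edge threshold on gradient magnitude (`NULL` = 10 % of range).
#' @param step time step (`NULL` = 0.125 in 2D, 1/16 in 3D).
#' @return object of class `diffusion_params`.
#' @export
diffusion_params <- function(iterations = 10, kappa = NULL, step = NULL) {
  if (iterations < 0 || iterations != round(iterations))
    stop("diffusion_params: iterations must be a nonnegative integer")
  if (!is.null(kappa) && kappa <= 0) stop("diffusion_params: kappa must be > 0")
  structure(list(iterations = as.integer(iterations), kappa = kappa,
                 step = step), class = "diffusion_params")
}

# labels used throughout the phantom
LAB <- c(background = 0L, cortical = 1L, soft = 2L, titanium = 3L, bone = 4L)

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Dice overlap coefficient between two binary masks
#' @param a,b logical/integer arrays of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  a <- as.logical(as_plain(a)); b <- as.logical(as_plain(b))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
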