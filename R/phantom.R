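# Synthetic phantom world: lattice scaffold, implanted tibia, forward
# micro-CT simulator and histology simulator, all ground-truthed.

# distance (um) from coordinate x to the nearest lattice plane of period a
# passing through phase
lattice_dist <- function(x, phase, a) {
  abs(((x - phase + a / 2) %% a) - a / 2)
}

# Lattice phases relative to the cylinder axis, as fractions of the pitch,
# shared per axis so that the three strut families meet at common nodes
# (the inclusion-exclusion porosity oracle assumes intersecting axes, as
# does the real design).  The phase offset from the cylinder axis breaks
# the exact 90-degree rotation symmetry of the clipped cylinder; the
# remaining mirror and whole-pitch translation symmetries of any ideal
# node lattice are broken by the as-built strut roughness instead.
LATTICE_PHASE <- list(
  famZ = c(x = 0.30, y = 0.15),   # struts along z: x/y positions
  famX = c(y = 0.15, z = 0.20),   # struts along x: y/z positions
  famY = c(x = 0.30, z = 0.20))   # struts along y: x/z positions

#' Voxelise a cylindrical orthogonal-strut lattice scaffold
#'
#' Builds a binary titanium mask: three orthogonal families of cylindrical
#' struts (axes aligned to the grid axes, period `lattice_pitch_um`, strut
#' radius `strut_diameter_um/2`), clipped to the design cylinder.  The void
#' fraction (porosity) inside the cylinder is reported alongside.
#'
#' @param design a [scaffold_design()].
#' @return list with `mask` (binary `labelvol`), `cylinder` (design-cylinder
#'   mask), `porosity` (void fraction in \[0,1\]) and `design`.
#' @export
make_scaffold <- function(design) {
  stopifnot(inherits(design, "scaffold_design"))
  sp <- design$voxel_size_um
  D <- design$diameter_mm * 1000; H <- design$height_mm * 1000
  a <- design$lattice_pitch_um; r <- design$strut_diameter_um / 2
  sig <- if (is.null(design$roughness_um)) 0 else design$roughness_um
  nx <- max(2L, round(D / sp)); nz <- max(2L, round(H / sp))
  x <- (seq_len(nx) - 1) * sp
  z <- (seq_len(nz) - 1) * sp
  cx <- (nx - 1) / 2 * sp; cz <- (nz - 1) / 2 * sp
  R <- D / 2

  # strut axis positions per lattice family (node-sharing phases)
  ph <- LATTICE_PHASE
  lat <- function(center, phase, lim, margin) {
    p0 <- center + phase * a
    k <- seq(floor((-margin - p0) / a), ceiling((lim + margin - p0) / a))
    p0 + k * a
  }
  pxz <- lat(cx, ph$famZ[["x"]], max(x), r + 3 * sig)
  pyz <- lat(cx, ph$famZ[["y"]], max(x), r + 3 * sig)
  pyx <- lat(cx, ph$famX[["y"]], max(x), r + 3 * sig)
  pzx <- lat(cz, ph$famX[["z"]], max(z), r + 3 * sig)
  pxy <- lat(cx, ph$famY[["x"]], max(x), r + 3 * sig)
  pzy <- lat(cz, ph$famY[["z"]], max(z), r + 3 * sig)

  # per-strut as-built variation: axis jitter and a smooth radius profile
  # along the strut, both of scale roughness_um.  The radius modulation is
  # centred so E[r_eff^2] = r^2 (the design porosity is preserved).  A
  # fixed internal seed makes the as-built implant one reproducible
  # object; without the roughness the ideal node lattice is ambiguous
  # under mirror reflections and whole-pitch translations, which the real
  # as-built implant is not.
  base <- if (sig > 0) r - sig^2 / (2 * r) else r
  jit <- function() {
    if (sig == 0) return(0)
    max(-2 * sig, min(2 * sig, rnorm(1, 0, sig)))
  }
  profile <- function(t) {
    if (sig == 0) return(rep(r, length(t)))
    n_w <- 6L
    lam <- runif(n_w, 120, 400)
    phw <- runif(n_w, 0, 2 * pi)
    dr <- rowSums(vapply(seq_len(n_w), function(m)
      cos(2 * pi * t / lam[m] + phw[m]), numeric(length(t))))
    pmax(base + sig * dr / sqrt(n_w / 2), 2 * sp)
  }
  rmax <- r + 3 * sig + sp
  solid <- array(FALSE, c(nx, nx, nz))
  # paint one strut: axis along `along`, centre (c1, c2) in the two
  # transverse coordinates, radius profile evaluated along the axis
  paint <- function(along, c1, c2) {
    co1 <- if (along == 1L) x else x       # transverse coord 1 (y or x)
    co2 <- if (along == 3L) x else z       # transverse coord 2
    ax <- switch(along, x, x, z)           # axial coordinate vector
    i1 <- which(abs(co1 - c1) <= rmax)
    i2 <- which(abs(co2 - c2) <= rmax)
    if (!length(i1) || !length(i2)) return()
    rs2 <- profile(ax)^2
    d2 <- outer((co1[i1] - c1)^2, (co2[i2] - c2)^2, "+")
    n1 <- length(i1); n2 <- length(i2); na <- length(ax)
    cond <- outer(as.vector(d2), rs2, "<=")
    if (along == 3L) {                     # strut along z: (x, y) box
      dim(cond) <- c(n1, n2, na)
      solid[i1, i2, ] <<- solid[i1, i2, , drop = FALSE] | cond
    } else if (along == 1L) {              # strut along x: (y, z) box
      cond <- aperm(array(cond, c(n1, n2, na)), c(3, 1, 2))
      solid[, i1, i2] <<- solid[, i1, i2, drop = FALSE] | cond
    } else {                               # strut along y: (x, z) box
      cond <- aperm(array(cond, c(n1, n2, na)), c(1, 3, 2))
      solid[i1, , i2] <<- solid[i1, , i2, drop = FALSE] | cond
    }
  }
  with_seed(9713L, {
    for (sx in pxz) for (sy in pyz) paint(3L, sx + jit(), sy + jit())
    for (sy in pyx) for (sz in pzx) paint(1L, sy + jit(), sz + jit())
    for (sx in pxy) for (sz in pzy) paint(2L, sx + jit(), sz + jit())
  })
  cyl2 <- outer((x - cx)^2, (x - cx)^2, "+") <= R^2
  cyl <- array(cyl2, c(nx, nx, nz))
  mask <- solid & cyl
  porosity <- 1 - sum(mask) / sum(cyl)
  out <- list(mask = vol3d(mask + 0L, sp, labels = TRUE),
              cylinder = vol3d(cyl + 0L, sp, labels = TRUE),
              porosity = porosity, design = design)
  class(out) <- "scaffold_phantom"
  out
}

#' Analytic scaffold porosity by inclusion-exclusion
#'
#' Infinite-lattice solid fraction per unit cell: three cylinders of volume
#' `pi r^2 a`, minus the three pairwise perpendicular-cylinder (Steinmetz)
#' intersections `16 r^3 / 3`, plus the triple intersection
#' `8 (2 - sqrt(2)) r^3`.  Porosity is one minus the solid fraction.
#'
#' @param design a [scaffold_design()].
#' @return porosity in \[0, 1\].
#' @export
analytic_scaffold_porosity <- function(design) {
  a <- design$lattice_pitch_um; r <- design$strut_diameter_um / 2
  v_union <- 3 * pi * r^2 * a - 3 * (16 * r^3 / 3) + 8 * (2 - sqrt(2)) * r^3
  1 - v_union / a^3
}

#' Cylinder mask on an arbitrary grid
#'
#' Axis-aligned (z-axis) solid cylinder; used for the defect-equivalent
#' volume of interest.
#'
#' @param dim length-3 grid dimensions.
#' @param spacing_um voxel size.
#' @param diameter_mm,height_mm cylinder dimensions.
#' @param center_um cylinder centre (defaults to the grid centre).
#' @return binary `labelvol`.
#' @export
make_cylinder_mask <- function(dim, spacing_um, diameter_mm, height_mm,
                               center_um = NULL) {
  if (is.null(center_um)) center_um <- (dim - 1) / 2 * spacing_um
  x <- (seq_len(dim[1]) - 1) * spacing_um - center_um[1]
  y <- (seq_len(dim[2]) - 1) * spacing_um - center_um[2]
  z <- (seq_len(dim[3]) - 1) * spacing_um - center_um[3]
  in_xy <- outer(x^2, y^2, "+") <= (diameter_mm * 500)^2
  in_z <- abs(z) <= height_mm * 500
  m <- array(in_xy, dim) & array(rep(in_z, each = dim[1] * dim[2]), dim)
  vol3d(m + 0L, spacing_um, labels = TRUE)
}

# smooth seeded scalar field evaluated at voxel coords (0-based vectors),
# as a sum of random plane-wave cosines; sd approx 1.  Wave parameters are
# drawn from the caller's RNG stream; evaluation runs in compiled code.
smooth_field <- function(ix, iy, iz, n_waves = 8, wavelength_vox = c(25, 60)) {
  dir <- matrix(rnorm(3 * n_waves), 3)
  dir <- sweep(dir, 2, sqrt(colSums(dir^2)), "/")
  lam <- runif(n_waves, wavelength_vox[1], wavelength_vox[2])
  ph <- runif(n_waves, 0, 2 * pi)
  plane_waves_cpp(as.numeric(ix), as.numeric(iy), as.numeric(iz),
                  dir, lam, ph)
}

#' Build an implanted-tibia phantom around a scaffold
#'
#' Embeds the scaffold in a larger field with a cortical-bone annulus and
#' marrow, then fills a controllable fraction of the scaffold void with new
#' bone.  The fill pattern is a smooth random field plus a radial gradient
#' (`edge_bias` > 0 biases bone toward the implant periphery, emulating
#' preferential peripheral ingrowth).  `contact_fraction`, when given,
#' adjusts the interface band so that approximately that fraction of the
#' scaffold surface touches bone.  The achieved bone ingrowth (BI) and
#' bone contact (BC) are recomputed exactly from the masks with
#' [bone_ingrowth()] / [bone_contact()] and stored in the returned truth.
#'
#' Labels: 0 background, 1 cortical bone, 2 marrow/soft, 3 titanium,
#' 4 new bone.
#'
#' @param scaffold result of [make_scaffold()].
#' @param fill_fraction target fraction of the scaffold void filled, \[0,1\].
#' @param contact_fraction optional target fraction of scaffold surface in
#'   contact with bone, \[0,1\].
#' @param edge_bias nonnegative weight of the radial gradient.
#' @param seed integer RNG seed.
#' @param field_mm in-plane field of view (default 3.5 mm).
#' @param z_margin_mm axial margin above/below the scaffold.
#' @return list with `labels` (a `labelvol`) and `truth` (masks, VOI,
#'   achieved `true_BI_percent` / `true_BC_percent`, seed).
#' @export
make_tibia_phantom <- function(scaffold, fill_fraction = 0.5,
                               contact_fraction = NULL, edge_bias = 0,
                               seed = 1L, field_mm = 3.5, z_margin_mm = 0.2) {
  stopifnot(inherits(scaffold, "scaffold_phantom"))
  if (fill_fraction < 0 || fill_fraction > 1)
    stop("make_tibia_phantom: fill_fraction must lie in [0, 1]")
  if (!is.null(contact_fraction)) {
    if (contact_fraction < 0 || contact_fraction > 1)
      stop("make_tibia_phantom: contact_fraction must lie in [0, 1]")
    if (fill_fraction == 0 && contact_fraction > 0)
      stop("make_tibia_phantom: contact_fraction > 0 is incompatible with fill_fraction = 0")
  }
  design <- scaffold$design
  sp <- design$voxel_size_um
  scaf_small <- as_plain(scaffold$mask)
  d0 <- dim(scaf_small)
  nf <- max(round(field_mm * 1000 / sp), d0[1] + 4L)
  mz <- round(z_margin_mm * 1000 / sp)
  nfz <- d0[3] + 2L * mz
  ox <- floor((nf - d0[1]) / 2); oz <- mz
  dimf <- c(nf, nf, nfz)

  x <- (seq_len(nf) - 1) * sp; cx <- (nf - 1) / 2 * sp
  r2d <- sqrt(outer((x - cx)^2, (x - cx)^2, "+"))
  R <- design$diameter_mm * 500
  # cortical annulus: the inner radius leaves a soft-tissue gap wide
  # enough that an in-plane tissue shrink of ~0.92 about the section
  # centre does not drag the cortex under the implant rim
  r_in <- 1.09 * R
  r_out <- min((nf - 1) / 2 * sp - 2 * sp, r_in + 200)
  zs <- (oz + 1):(oz + d0[3])                     # scaffold z-extent
  nzs <- length(zs)

  # assemble labels from 2D integer templates replicated along z
  # (memory-lean: no full-size logical temporaries)
  tpl_out <- matrix(ifelse(r2d <= r_out, LAB[["soft"]], LAB[["background"]]),
                    nf, nf)                        # above/below the scaffold
  cort2d <- r2d >= r_in & r2d <= r_out
  tpl_mid <- tpl_out
  tpl_mid[cort2d] <- LAB[["cortical"]]
  labels <- c(rep(as.integer(tpl_out), mz), rep(as.integer(tpl_mid), nzs),
              rep(as.integer(tpl_out), mz))
  dim(labels) <- dimf

  # linear field indices of the embedded scaffold voxels
  si <- which(scaf_small > 0L)
  i0 <- (si - 1L) %% d0[1]; j0 <- ((si - 1L) %/% d0[1]) %% d0[2]
  k0 <- (si - 1L) %/% (d0[1] * d0[2])
  scaf_idx <- (i0 + ox) + nf * (j0 + ox) + (nf * nf) * (k0 + oz) + 1
  labels[scaf_idx] <- LAB[["titanium"]]

  # defect-equivalent VOI = leg template (filled tibia cross-section over
  # the scaffold z-extent) intersected with the design cylinder
  leg2d <- r2d <= r_out
  cyl2d <- r2d <= R
  rep_mid <- function(tpl2d) {
    v <- integer(nf * nf * nfz)
    v[(mz * nf * nf) + seq_len(nzs * nf * nf)] <- rep(as.integer(tpl2d), nzs)
    dim(v) <- dimf
    v
  }
  leg <- rep_mid(leg2d)
  cyl <- rep_mid(cyl2d)
  voi <- cyl                      # cyl subset of leg, so leg & cyl = cyl

  void_idx <- masked_which_cpp(voi, labels, LAB[["titanium"]])
  bone_idx <- integer(0)
  if (fill_fraction > 0) {
    n_void <- length(void_idx)
    k <- round(fill_fraction * n_void)
    ii <- ((void_idx - 1) %% nf)
    jj <- ((void_idx - 1) %/% nf) %% nf
    kk <- (void_idx - 1) %/% (nf * nf)
    rnorm_r <- r2d[ii + 1 + nf * jj] / R
    score <- with_seed(seed, smooth_field(ii, jj, kk)) + edge_bias * rnorm_r
    if (k >= n_void) sel <- rep(TRUE, n_void)
    else if (k <= 0) sel <- rep(FALSE, n_void)
    else {
      thr <- -sort(-score, partial = k)[k]
      sel <- score > thr
      short <- k - sum(sel)
      if (short > 0) sel[which(score == thr)[seq_len(short)]] <- TRUE
    }
    bone_idx <- void_idx[sel]

    if (!is.null(contact_fraction)) {
      scafm <- labels == LAB[["titanium"]]
      iface <- dilate_mask(scafm)
      iface_idx <- void_idx[iface[void_idx]]
      if (length(iface_idx)) {
        i2 <- ((iface_idx - 1) %% nf); j2 <- ((iface_idx - 1) %/% nf) %% nf
        k2 <- (iface_idx - 1) %/% (nf * nf)
        patch <- with_seed(seed + 7L, smooth_field(i2, j2, k2, n_waves = 6,
                                                   wavelength_vox = c(40, 90)))
        if (contact_fraction >= 1) keep <- rep(TRUE, length(iface_idx))
        else if (contact_fraction <= 0) keep <- rep(FALSE, length(iface_idx))
        else keep <- patch >= quantile(patch, 1 - contact_fraction)
        bone_idx <- union(setdiff(bone_idx, iface_idx), iface_idx[keep])
      }
    }
  }
  labels[bone_idx] <- LAB[["bone"]]

  labels <- vol3d(labels, sp, labels = TRUE)
  from_idx <- function(idx) {
    v <- integer(prod(dimf)); v[idx] <- 1L; dim(v) <- dimf
    vol3d(v, sp, labels = TRUE)
  }
  lab_arr <- as_plain(labels)
  truth <- list(scaffold_mask = from_idx(scaf_idx),
                bone_mask = from_idx(bone_idx),
                cortical_mask = from_idx(which(lab_arr == LAB[["cortical"]])),
                voi_mask = vol3d(voi, sp, labels = TRUE),
                leg_mask = vol3d(leg, sp, labels = TRUE),
                cylinder_mask = vol3d(cyl, sp, labels = TRUE),
                design = design, seed = as.integer(seed),
                scaffold_z_range = range(zs))
  # exact achieved metrics, counted directly from the label indices; the
  # test suite asserts these equal bone_ingrowth()/bone_contact() on the
  # stored masks (the definitions coincide by construction)
  truth$true_BI_percent <- 100 * length(bone_idx) / length(void_idx)
  cc <- contact_counts_cpp(lab_arr, voi, dimf, LAB[["titanium"]],
                           LAB[["bone"]])
  truth$true_BC_percent <- if (cc[1] > 0) 100 * cc[2] / cc[1] else 0
  list(labels = labels, truth = truth)
}

#' Forward micro-CT simulation
#'
#' Maps labels to class intensities, convolves with a Gaussian PSF, adds
#' in-plane streak patterns anchored at titanium (windowed by the blurred
#' titanium neighbourhood, emulating metal artefacts) and adds Gaussian
#' noise.  Deterministic for a fixed seed.
#'
#' @param labels a `labelvol` with labels 0..4 (see [make_tibia_phantom()]).
#' @param params a [ct_sim_params()].
#' @return intensity `vol3d`.
#' @export
simulate_ct <- function(labels, params = ct_sim_params()) {
  stopifnot(inherits(labels, "vol3d"), inherits(params, "ct_sim_params"))
  sp <- spacing_um(labels)
  lab <- as_plain(labels)
  d <- dim(lab)
  lut <- c(params$background_intensity, params$bone_intensity,
           params$soft_intensity, params$titanium_intensity,
           params$bone_intensity)           # bg, cortical, soft, Ti, new bone
  vol <- lut[lab + 1L]
  dim(vol) <- d
  if (params$psf_sigma_um > 0) {
    s <- params$psf_sigma_um / sp
    vol <- gauss_blur_cpp(vol, d, rep(s, 3))
  }
  with_seed(params$seed, {
    if (params$streak_amplitude > 0 && params$streak_count > 0) {
      ti <- (lab == LAB[["titanium"]]) + 0.0
      dim(ti) <- d
      W <- gauss_blur_cpp(ti, d, rep(2, 3))
      W <- W / max(W, 1e-12)
      xs <- seq_len(d[1]) - 1; ys <- seq_len(d[2]) - 1
      P <- matrix(0, d[1], d[2])
      for (m in seq_len(params$streak_count)) {
        th <- runif(1, 0, pi); lam <- runif(1, 3, 8); ph <- runif(1, 0, 2 * pi)
        P <- P + cos(outer(xs * cos(th), ys * sin(th), "+") * (2 * pi / lam) + ph)
      }
      P <- P / sqrt(params$streak_count / 2)
      vol <- vol + params$streak_amplitude * W * as.vector(P)
    }
    if (params$noise_sd > 0)
      vol <- vol + rnorm(length(vol), 0, params$noise_sd)
  })
  dim(vol) <- d
  vol3d(vol, sp)
}

# number of slab planes and their offsets (um) along the plane normal
slab_offsets <- function(thickness_um, step_um) {
  n <- max(1L, round(thickness_um / step_um))
  (seq_len(n) - (n + 1) / 2) * step_um
}

#' Extract an oblique finite-thickness section from a volume
#'
#' The section is the mean of parallel resampled planes spanning the slab
#' thickness, centred on the pose plane.  Output pixel `(i, j)` lies at
#' section coordinates `((i-(nu-1)/2) su, (j-(nv-1)/2) sv)`; the pose maps
#' these into the volume (see [rigid_pose()]).  Samples outside the volume
#' take the value `outside`.
#'
#' @param vol a `vol3d` (intensities) or `labelvol` (labels).
#' @param pose a [rigid_pose()].
#' @param thickness_um slab thickness; defaults to the pose thickness.
#' @param out_spacing output pixel size (default: voxel size).
#' @param out_size output dimensions (default: volume x/y dimensions).
#' @param interp `"linear"` or `"nearest"` (default linear for intensities,
#'   nearest for labels).
#' @param reduce `"mean"` (average the slab planes), `"max"` (maximum over
#'   planes; the natural slab model for binary masks of an opaque phase) or
#'   `"stack"` (return an `nu x nv x nplanes` array).
#' @param outside fill value for samples outside the volume.
#' @return a `section2d` (or plain array for `reduce = "stack"`).
#' @export
extract_section <- function(vol, pose, thickness_um = NULL, out_spacing = NULL,
                            out_size = NULL, interp = NULL,
                            reduce = c("mean", "stack", "max"), outside = 0) {
  stopifnot(inherits(vol, "vol3d"), inherits(pose, "rigid_pose"))
  reduce <- match.arg(reduce)
  sp <- spacing_um(vol)
  d <- dim(vol)
  if (is.null(thickness_um)) thickness_um <- pose$thickness_um
  if (thickness_um > 0 && thickness_um < sp)
    thickness_um <- sp
  if (is.null(out_spacing)) out_spacing <- sp
  if (is.null(out_size)) out_size <- c(d[1], d[2])
  if (is.null(interp)) interp <- if (inherits(vol, "labelvol")) "nearest" else "linear"
  origin <- vol_center(vol) + pose$translation_um
  ext <- (d - 1) * sp
  if (any(origin < -0.5 * sp) || any(origin > ext + 0.5 * sp))
    stop("extract_section: pose plane lies outside the volume")
  R <- euler_to_matrix(pose$euler_deg)
  woff <- slab_offsets(max(thickness_um, sp), sp)
  mode <- switch(reduce, mean = 0L, stack = 1L, max = 2L)
  arr <- slab_resample_cpp(as.numeric(as_plain(vol)), d, rep(sp, 3), R, origin,
                           as.integer(out_size[1]), as.integer(out_size[2]),
                           out_spacing, out_spacing, woff,
                           if (interp == "nearest") 1L else 0L,
                           outside, mode)
  if (reduce == "stack") return(structure(arr, spacing_um = out_spacing))
  section2d(arr, out_spacing, labels = inherits(vol, "labelvol") &&
              interp == "nearest")
}

# majority tissue label (bone > cortical > soft > background priority on
# ties) across slab planes, excluding titanium
composite_tissue <- function(stack) {
  d <- dim(stack)
  cnt <- sapply(c(LAB[["bone"]], LAB[["cortical"]], LAB[["soft"]],
                  LAB[["background"]]),
                function(l) rowSums(array(stack == l, d), dims = 2))
  pick <- max.col(cnt, ties.method = "first")
  lab_order <- c(LAB[["bone"]], LAB[["cortical"]], LAB[["soft"]],
                 LAB[["background"]])
  out <- matrix(lab_order[pick], d[1], d[2])
  out[matrix(rowSums(cnt) == 0, d[1], d[2])] <- LAB[["soft"]]  # fully under titanium
  out
}

# smooth standardized 2D field (for the elastic warp), seeded by caller
smooth_field2d <- function(nu, nv, sigma_px = 15) {
  f <- array(rnorm(nu * nv), c(nu, nv, 1L))
  f <- gauss_blur_cpp(f, c(nu, nv, 1L), c(sigma_px, sigma_px, 0))
  f <- matrix(f, nu, nv)
  (f - mean(f)) / max(sd(f), 1e-12)
}

#' Simulate a stained histology section
#'
#' Extracts the label slab at `pose`, then applies (in order): anisotropic
#' in-plane shrinkage of the tissue about the section centre (`shrink_x`,
#' `shrink_y`; the titanium is rigid and exempt, mirroring its role as the
#' registration fiducial), a separation gap of `separation_um` opened where
#' bone meets the titanium, and an optional smooth elastic warp of the
#' tissue.  Classes are then coloured with the stain colours plus
#' multiplicative noise.
#'
#' @param labels a `labelvol` (see [make_tibia_phantom()]).
#' @param pose section [rigid_pose()]; its thickness is used unless the
#'   parameter record says otherwise.
#' @param params a [histology_sim_params()].
#' @param truth optional truth list to update (pose and shrink recorded).
#' @param out_size,out_spacing output geometry (defaults: volume grid).
#' @return list with `image` (RGB `section2d`), `labels2d` (deformed label
#'   `section2d`), and `truth` (adds `section_pose`, `shrink_x`, `shrink_y`,
#'   `slab_titanium` = undeformed titanium mask, `slab_labels`).
#' @export
simulate_histology <- function(labels, pose, params = histology_sim_params(),
                               truth = list(), out_size = NULL,
                               out_spacing = NULL) {
  stopifnot(inherits(labels, "labelvol"), inherits(pose, "rigid_pose"))
  sp <- spacing_um(labels)
  if (is.null(out_spacing)) out_spacing <- sp
  if (is.null(out_size)) out_size <- dim(labels)[1:2]
  thick <- params$thickness_um
  stack <- extract_section(labels, pose, thickness_um = thick,
                           out_spacing = out_spacing, out_size = out_size,
                           interp = "nearest", reduce = "stack")
  stack <- array(stack, dim = dim(stack))
  nu <- dim(stack)[1]; nv <- dim(stack)[2]
  titanium <- matrix(rowSums(array(stack == LAB[["titanium"]], dim(stack)),
                             dims = 2) > 0, nu, nv)
  tissue <- composite_tissue(stack)

  cxp <- (nu - 1) / 2; cyp <- (nv - 1) / 2
  xg <- matrix(seq_len(nu) - 1, nu, nv)
  yg <- matrix(seq_len(nv) - 1, nu, nv, byrow = TRUE)

  # 1. anisotropic shrink about the section centre (tissue only)
  if (params$shrink_x < 1 || params$shrink_y < 1) {
    mapx <- cxp + (xg - cxp) / params$shrink_x
    mapy <- cyp + (yg - cyp) / params$shrink_y
    tissue <- warp2d_cpp(tissue + 0, mapx, mapy, 1L, LAB[["background"]])
  }
  # 2. separation gap at the bone-implant interface
  if (params$separation_um > 0) {
    dti <- chamfer_distance_cpp(array(as.integer(titanium), c(nu, nv, 1L)),
                                c(nu, nv, 1L), rep(out_spacing, 3))
    gap <- matrix(dti <= params$separation_um, nu, nv) & !titanium &
      tissue == LAB[["bone"]]
    tissue[gap] <- LAB[["background"]]
  }
  # 3. smooth elastic warp (tissue only)
  if (params$elastic_warp_amplitude_um > 0) {
    amp_px <- params$elastic_warp_amplitude_um / out_spacing
    wfx <- with_seed(params$seed + 11L, smooth_field2d(nu, nv))
    wfy <- with_seed(params$seed + 12L, smooth_field2d(nu, nv))
    tissue <- warp2d_cpp(tissue + 0, xg + amp_px * wfx, yg + amp_px * wfy,
                         1L, LAB[["background"]])
  }
  final <- tissue
  final[titanium] <- LAB[["titanium"]]
  storage.mode(final) <- "integer"

  cols <- rbind(params$stain_color_background,   # 0
                params$stain_color_bone,         # 1 cortical
                params$stain_color_soft,         # 2
                params$stain_color_titanium,     # 3
                params$stain_color_bone)         # 4 new bone
  rgb <- array(0, c(nu, nv, 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(cols[final + 1L, ch], nu, nv)
  if (params$color_noise_sd > 0)
    rgb <- with_seed(params$seed + 13L,
                     rgb * exp(rnorm(length(rgb), 0, params$color_noise_sd)))
  rgb <- array(pmin(pmax(rgb, 0), 255), c(nu, nv, 3))

  pose$thickness_um <- thick
  truth$section_pose <- pose
  truth$shrink_x <- params$shrink_x
  truth$shrink_y <- params$shrink_y
  truth$slab_titanium <- section2d(titanium + 0L, out_spacing, labels = TRUE)
  truth$slab_labels <- section2d(composite_tissue(stack), out_spacing,
                                 labels = TRUE)
  list(image = section2d(rgb, out_spacing), labels2d =
         section2d(final, out_spacing, labels = TRUE), truth = truth)
}
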