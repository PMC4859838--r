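# Coarse-to-fine rigid slice-to-volume registration driven by the
# correlation coefficient, plus 2D affine registration for shrinkage.

#' Correlation coefficient between two images
#'
#' `C = sum((T-Tm)(R-Rm)) / (sqrt(sum((T-Tm)^2)) * sqrt(sum((R-Rm)^2)))`
#' over all pixels, where `Tm`, `Rm` are the image means.  `C = 1` for an
#' identical pair; `C` always lies in \[-1, 1\].
#'
#' @param target,reference equal-shape numeric images (masks are cast to
#'   reals); each must be non-constant.
#' @return scalar correlation coefficient.
#' @export
correlation_coefficient <- function(target, reference) {
  t <- as.numeric(as_plain(target)); r <- as.numeric(as_plain(reference))
  if (length(t) != length(r))
    stop("correlation_coefficient: images must have equal shapes")
  td <- t - mean(t); rd <- r - mean(r)
  den <- sqrt(sum(td^2)) * sqrt(sum(rd^2))
  if (den == 0)
    stop("correlation_coefficient: constant image (zero denominator)")
  max(-1, min(1, sum(td * rd) / den))
}

# correlation that tolerates constant slabs (returns NA instead of error);
# used inside searches where off-target poses can produce empty slabs
cc_or_na <- function(target_dev, target_ss, slab) {
  sd <- slab - mean(slab)
  den <- sqrt(target_ss) * sqrt(sum(sd * sd))
  if (den == 0) return(NA_real_)
  sum(target_dev * sd) / den
}

# slab resample of a (mask) volume at a pose, matched to a section grid.
# `sharpen` pushes antialiased boundary fractions towards 0/1 through a
# smooth logistic: a differentiable stand-in for the nearest-neighbour
# resampling that binary masks ultimately use, so that a perfectly
# registered binary pair scores C ~ 1 while the objective stays smooth
# for the simplex optimiser.
resample_for_section <- function(vol_arr, dimv, sp, pose, nu, nv, su,
                                 thickness_um, interp = 0L,
                                 reduce_mode = 0L, sharpen = FALSE) {
  R <- euler_to_matrix(pose$euler_deg)
  origin <- (dimv - 1) / 2 * sp + pose$translation_um
  woff <- slab_offsets(max(thickness_um, sp), sp)
  out <- slab_resample_cpp(vol_arr, dimv, rep(sp, 3), R, origin,
                           as.integer(nu), as.integer(nv), su, su, woff,
                           interp, 0, reduce_mode)
  if (sharpen) out <- stats::plogis(30 * (out - 0.5))
  out
}

#' Coarse-search grid specification
#'
#' The default grid scans plane offsets in 1-voxel steps along the axis
#' nearest the section normal, in-plane rotations every 5 degrees, and
#' out-of-plane tilts -10..10 degrees in 5-degree steps.  To keep the
#' search tractable the scan is staged: offsets x in-plane rotations are
#' evaluated first (at `downsample`-reduced resolution, zero tilt), then
#' the tilt grid is applied around the `top_k` best candidates at full
#' resolution.
#'
#' @param offsets_vox plane offsets along the normal axis, voxels
#'   (`NULL` = span the occupied part of the volume).
#' @param offset_stride offset step of the scans (voxels); the refinement
#'   stage recovers sub-stride offsets.
#' @param inplane_deg in-plane rotation angles (degrees).
#' @param tilt_deg out-of-plane tilt angles (degrees), applied on both tilt
#'   axes.
#' @param top_k candidates promoted to the final full-resolution stage.
#' @param n_angles distinct in-plane angles promoted to the joint
#'   offset-tilt stage.
#' @param downsample length-2 integer resolution reduction for stages 1
#'   and 2.
#' @return object of class `search_grid`.
#' @export
search_grid <- function(offsets_vox = NULL, offset_stride = 2,
                        inplane_deg = seq(0, 355, by = 5),
                        tilt_deg = seq(-10, 10, by = 5), top_k = 8,
                        n_angles = 3, downsample = c(4, 4)) {
  downsample <- rep(as.integer(downsample), length.out = 2)
  structure(list(offsets_vox = offsets_vox,
                 offset_stride = as.integer(offset_stride),
                 inplane_deg = inplane_deg,
                 tilt_deg = tilt_deg, top_k = as.integer(top_k),
                 n_angles = as.integer(n_angles),
                 downsample = downsample),
            class = "search_grid")
}

#' Coarse correlation search of a section inside a volume
#'
#' Exhaustively evaluates the correlation coefficient between the section
#' mask and slabs resampled from the volume mask over a grid of plane
#' offsets (along z), in-plane rotations and out-of-plane tilts, and
#' returns candidate poses ranked by descending C.  Ranking is
#' deterministic: ties are broken by offset, then angles, so the result
#' does not depend on grid order.
#'
#' @param section_mask binary `section2d` (the segmented titanium).
#' @param volume_mask binary `labelvol` / `vol3d` (segmented titanium).
#' @param grid a [search_grid()].
#' @param thickness_um slab thickness used during the search.
#' @return `data.frame` with columns `C`, `offset_vox`, `inplane_deg`,
#'   `tilt_y_deg`, `tilt_x_deg` and an attribute `poses` (list of
#'   [rigid_pose()], same order).
#' @export
coarse_search <- function(section_mask, volume_mask, grid = search_grid(),
                          thickness_um = NULL) {
  stopifnot(inherits(grid, "search_grid"))
  sec <- as_plain(section_mask) + 0
  if (!any(sec > 0)) stop("coarse_search: empty section mask")
  varr <- as.numeric(as_plain(volume_mask))
  if (!any(varr > 0)) stop("coarse_search: empty volume mask")
  dimv <- dim(volume_mask)
  sp <- spacing_um(volume_mask)
  su <- spacing_um(section_mask)
  if (is.null(thickness_um)) thickness_um <- sp
  offs <- grid$offsets_vox
  stride <- max(1L, grid$offset_stride)
  if (is.null(offs)) {
    # scan only z levels where the volume mask is occupied
    zany <- colSums(matrix(varr, prod(dimv[1:2]), dimv[3])) > 0
    zr <- range(which(zany))
    zc <- (dimv[3] + 1) / 2
    offs <- seq(zr[1] - 2 - zc, zr[2] + 2 - zc)
  }
  offs1 <- offs[seq(1, length(offs), by = stride)]
  ds <- max(1L, grid$downsample[1])
  nu <- dim(sec)[1]; nv <- dim(sec)[2]
  sec_ds <- sec[seq(1, nu, by = ds), seq(1, nv, by = ds)]
  nud <- nrow(sec_ds); nvd <- ncol(sec_ds)
  center <- (dimv - 1) / 2 * sp

  # stage 1: offsets x in-plane rotations, downsampled, zero tilt, single
  # central plane; the offset scan runs in compiled code per rotation
  s1 <- expand.grid(offset = offs1, inplane = grid$inplane_deg,
                    KEEP.OUT.ATTRS = FALSE)
  c1 <- unlist(lapply(grid$inplane_deg, function(ang)
    offset_scan_cpp(varr, dimv, rep(sp, 3), euler_to_matrix(c(ang, 0, 0)),
                    center, offs1 * sp, matrix(sec_ds, nud, nvd), su * ds)))
  ord1 <- order(-c1, s1$offset, s1$inplane, na.last = TRUE)
  ord1 <- ord1[!is.na(c1[ord1])]
  if (!length(ord1)) stop("coarse_search: no finite correlation on the grid")
  # best distinct in-plane angles (in-plane rotation is identified robustly
  # by the flat scan; the offset is re-searched jointly with tilt below,
  # because an out-of-plane tilt moves the best-matching flat offset)
  top_angles <- unique(s1$inplane[ord1])[seq_len(min(grid$n_angles,
                                                     length(unique(s1$inplane[ord1]))))]

  # stage 2: joint offset x tilt scan for each retained angle
  ds2 <- max(1L, grid$downsample[2])
  sec_d2 <- sec[seq(1, nu, by = ds2), seq(1, nv, by = ds2)]
  sec_d2 <- matrix(sec_d2, nrow(sec_d2))
  tilts <- expand.grid(ty = grid$tilt_deg, tx = grid$tilt_deg,
                       KEEP.OUT.ATTRS = FALSE)
  res <- do.call(rbind, lapply(top_angles, function(ang)
    do.call(rbind, lapply(seq_len(nrow(tilts)), function(q) {
      cs <- offset_scan_cpp(varr, dimv, rep(sp, 3),
                            euler_to_matrix(c(ang, tilts$ty[q], tilts$tx[q])),
                            center, offs1 * sp, sec_d2, su * ds2)
      data.frame(C2 = cs, offset = offs1, inplane = ang,
                 ty = tilts$ty[q], tx = tilts$tx[q])
    }))))
  ord2 <- order(-res$C2, res$offset, res$inplane, res$ty, res$tx,
                na.last = TRUE)
  ord2 <- head(ord2[!is.na(res$C2[ord2])], grid$top_k)

  # stage 3: full resolution, full slab thickness, final ranking
  sdev_f <- sec - mean(sec); sss_f <- sum(sdev_f * sdev_f)
  res3 <- res[ord2, , drop = FALSE]
  poses <- lapply(seq_len(nrow(res3)), function(i)
    rigid_pose(c(res3$inplane[i], res3$ty[i], res3$tx[i]),
               c(0, 0, res3$offset[i] * sp), thickness_um))
  c3 <- vapply(seq_along(poses), function(i) {
    slab <- resample_for_section(varr, dimv, sp, poses[[i]], nu, nv, su,
                                 thickness_um, interp = 1L,
                                 reduce_mode = 2L)
    cc_or_na(sdev_f, sss_f, slab)
  }, numeric(1))
  ord <- order(-c3, res3$offset, res3$inplane, res3$ty, res3$tx,
               na.last = TRUE)
  out <- data.frame(C = c3[ord], offset_vox = res3$offset[ord],
                    inplane_deg = res3$inplane[ord],
                    tilt_y_deg = res3$ty[ord], tilt_x_deg = res3$tx[ord])
  attr(out, "poses") <- poses[ord]
  out
}

#' Refine a rigid pose by derivative-free maximisation of C
#'
#' Nelder-Mead simplex over an in-plane (3 degrees of freedom: in-plane
#' translation + rotation) or full rigid (6 DOF) correction composed with
#' the initial pose.  The DOF count follows the section-thickness rule:
#' 3 DOF when the slab is a single voxel thick, 6 DOF above 5 voxels, and
#' a conservative 3 DOF in between (configurable via `dof`).  The moving
#' slab is resampled from the volume at every evaluation; the best C seen
#' so far is recorded in the trace, which is therefore nondecreasing.
#'
#' @param section_mask binary `section2d`.
#' @param volume_mask binary volume mask.
#' @param init initial [rigid_pose()] (from [coarse_search()] or a user).
#' @param thickness_um slab thickness (defaults to the init pose).
#' @param max_iter maximum objective evaluations.
#' @param tol relative convergence tolerance on C.
#' @param dof `NULL` (thickness rule) or 3 or 6.
#' @return object of class `registration_result`: `pose`, `final_C`,
#'   `iterations`, `trace` (accepted-step C values), `dof_used`.
#' @export
refine_rigid <- function(section_mask, volume_mask, init,
                         thickness_um = NULL, max_iter = 300, tol = 1e-4,
                         dof = NULL) {
  stopifnot(inherits(init, "rigid_pose"))
  sec <- as_plain(section_mask) + 0
  varr <- as.numeric(as_plain(volume_mask))
  dimv <- dim(volume_mask)
  sp <- spacing_um(volume_mask)
  su <- spacing_um(section_mask)
  if (is.null(thickness_um)) thickness_um <- init$thickness_um
  if (thickness_um <= 0) thickness_um <- sp
  tv <- thickness_um / sp
  if (is.null(dof)) dof <- if (tv > 5) 6L else 3L
  dof <- as.integer(dof)
  if (!dof %in% c(3L, 6L)) stop("refine_rigid: dof must be 3 or 6")
  nu <- dim(sec)[1]; nv <- dim(sec)[2]

  env <- new.env()
  env$trace <- numeric(0)
  env$best <- -Inf
  env$evals <- 0L
  par_to_pose <- function(p) {
    if (dof == 3L)
      compose_pose(init, th = p[1], du = p[2], dv = p[3])
    else
      compose_pose(init, th = p[1], phi = p[2], psi = p[3],
                   du = p[4], dv = p[5], dw = p[6])
  }
  make_objective <- function(secM, su_eff, record, interp = 0L) {
    sdev <- secM - mean(secM); sss <- sum(sdev * sdev)
    nuM <- nrow(secM); nvM <- ncol(secM)
    function(p) {
      pose <- par_to_pose(p)
      slab <- resample_for_section(varr, dimv, sp, pose, nuM, nvM, su_eff,
                                   thickness_um, interp = interp,
                                   reduce_mode = 2L)
      cc <- cc_or_na(sdev, sss, slab)
      if (is.na(cc) || !is.finite(cc))
        stop(sprintf(paste0("refine_rigid: non-finite correlation at pose ",
                            "euler=[%.2f, %.2f, %.2f] t=[%.1f, %.1f, %.1f]"),
                     pose$euler_deg[1], pose$euler_deg[2], pose$euler_deg[3],
                     pose$translation_um[1], pose$translation_um[2],
                     pose$translation_um[3]))
      env$evals <- env$evals + 1L
      if (record && cc > env$best) {
        env$best <- cc
        env$trace <- c(env$trace, cc)
      }
      -cc
    }
  }
  p0 <- rep(0, dof)
  scale <- if (dof == 3L) c(1, sp, sp) else c(1, 1, 1, sp, sp, sp)
  # two-level pyramid: a half-resolution pass positions the simplex
  # cheaply, a full-resolution pass polishes; C of record is full-res only
  if (min(nu, nv) > 160) {
    sec_half <- sec[seq(1, nu, by = 2), seq(1, nv, by = 2)]
    obj_half <- make_objective(sec_half, su * 2, record = FALSE)
    fit0 <- optim(p0, obj_half, method = "Nelder-Mead",
                  control = list(maxit = max_iter, reltol = tol,
                                 parscale = scale))
    p0 <- fit0$par
  }
  # main pass on the smooth (antialiased, trilinear) objective, whose
  # basin is well behaved; then a short polish pass on the metric of
  # record: C against the nearest-neighbour-resampled mask slab, exactly
  # what apply_pose() produces for the registered 2D correspondence
  objective <- make_objective(matrix(sec, nu, nv), su, record = FALSE)
  fit_main <- optim(p0, objective, method = "Nelder-Mead",
                    control = list(maxit = max_iter, reltol = tol,
                                   parscale = scale))
  polish <- make_objective(matrix(sec, nu, nv), su, record = TRUE,
                           interp = 1L)
  fit <- optim(fit_main$par, polish, method = "Nelder-Mead",
               control = list(maxit = max(60, ceiling(max_iter / 4)),
                              reltol = tol, parscale = scale))
  fit$counts[1] <- fit$counts[1] + fit_main$counts[1]
  pose <- par_to_pose(fit$par)
  pose$thickness_um <- thickness_um
  structure(list(pose = pose, final_C = env$best,
                 iterations = as.integer(fit$counts[1]),
                 trace = env$trace, dof_used = dof,
                 convergence = fit$convergence, evaluations = env$evals),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: final C = %.4f after %d evaluations (%d DOF)\n",
              x$final_C, x$iterations, x$dof_used))
  print(x$pose)
  invisible(x)
}

#' Extract the registered 2D correspondence from a volume
#'
#' Resamples the slab at a registered pose: trilinear interpolation for
#' intensity volumes, nearest-neighbour for label masks.
#'
#' @param vol `vol3d` or `labelvol`.
#' @param pose a [rigid_pose()].
#' @param ... passed to [extract_section()] (`out_size`, `out_spacing`, ...).
#' @return `section2d`.
#' @export
apply_pose <- function(vol, pose, ...) {
  extract_section(vol, pose, ...)
}

#' 2D affine mask registration (scale, rotation, shear, translation)
#'
#' Maximises the (soft) Dice overlap between the fixed mask and the
#' affinely transformed moving mask.  Initialised from mask centroids and
#' principal-axis second moments; refined by Nelder-Mead on
#' `(log sx, log sy, rotation, shear, tx, ty)`.  The linear part is
#' `R(rotation) %*% [sx, shear; 0, sy]`, so the determinant is
#' `sx * sy > 0`.
#'
#' @param fixed_mask,moving_mask binary `section2d` masks with equal pixel
#'   size and a single dominant component.
#' @param max_iter Nelder-Mead evaluation budget.
#' @return object of class `affine2d`: `scale_x`, `scale_y`,
#'   `rotation_deg`, `shear`, `translation_um`, `dice`.
#' @export
register_affine2d <- function(fixed_mask, moving_mask, max_iter = 600) {
  f <- as_plain(fixed_mask) > 0
  m <- as_plain(moving_mask) > 0
  if (!any(f) || !any(m)) stop("register_affine2d: empty mask")
  if (sum(f) < 10 || sum(m) < 10)
    stop("register_affine2d: degenerate mask (area < 10 pixels)")
  spf <- spacing_um(fixed_mask); spm <- spacing_um(moving_mask)
  if (abs(spf - spm) > 1e-9)
    stop("register_affine2d: masks must share a pixel size")
  fi <- which(f, arr.ind = TRUE) - 1
  mi <- which(m, arr.ind = TRUE) - 1
  cf <- colMeans(fi); cm <- colMeans(mi)
  mdbl <- m + 0
  fdbl <- f + 0
  sumf <- sum(fdbl)
  xg <- matrix(seq_len(nrow(f)) - 1, nrow(f), ncol(f))
  yg <- matrix(seq_len(ncol(f)) - 1, nrow(f), ncol(f), byrow = TRUE)

  soft_dice <- function(p) {
    sx <- exp(p[1]); sy <- exp(p[2]); th <- p[3] * pi / 180; sh <- p[4]
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    L <- Rm %*% matrix(c(sx, 0, sh, sy), 2, 2)
    Li <- solve(L)
    # fixed pixel -> moving source coordinate
    dx <- xg - cf[1] - p[5]; dy <- yg - cf[2] - p[6]
    mapx <- Li[1, 1] * dx + Li[1, 2] * dy + cm[1]
    mapy <- Li[2, 1] * dx + Li[2, 2] * dy + cm[2]
    warped <- warp2d_cpp(mdbl, mapx, mapy, 0L, 0)
    2 * sum(warped * fdbl) / (sum(warped) + sumf)
  }
  # moment-based initialisation: scales from second-moment magnitudes,
  # rotation from the principal-axis angle difference (folded to +-90 deg)
  covf <- stats::cov(fi); covm <- stats::cov(mi)
  ef <- eigen(covf, symmetric = TRUE); em <- eigen(covm, symmetric = TRUE)
  s0 <- sqrt(pmax(ef$values, 1e-9) / pmax(em$values, 1e-9))
  ang <- function(e) atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  th0 <- (ang(ef) - ang(em)) %% 180
  if (th0 > 90) th0 <- th0 - 180
  run <- function(theta) {
    optim(c(log(mean(s0)), log(mean(s0)), theta, 0, 0, 0),
          function(p) -soft_dice(p), method = "Nelder-Mead",
          control = list(maxit = max_iter, reltol = 1e-9,
                         parscale = c(0.05, 0.05, 2, 0.05, 2, 2)))
  }
  fits <- lapply(unique(c(th0, 0)), run)
  fit <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  p <- fit$par
  structure(list(scale_x = exp(p[1]), scale_y = exp(p[2]),
                 rotation_deg = p[3], shear = p[4],
                 translation_um = (cf - cm + p[5:6]) * spf,
                 dice = -fit$value),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("affine2d: scale = (%.4f, %.4f), rotation = %.2f deg, shear = %.4f, Dice = %.4f\n",
              x$scale_x, x$scale_y, x$rotation_deg, x$shear, x$dice))
  invisible(x)
}
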