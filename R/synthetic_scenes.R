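# Synthetic scene generation. Scenes are built as ideal (noise-free) label
# and intensity fields from planted geometry, then corrupted by Gaussian PSF
# blur and Poisson-Gaussian noise. Ground truth records every planted object
# so downstream stages can be scored by parameter recovery.
#
# Rasterization detail: each condensate is a prolate spheroid; its voxel mask
# is the set of the `round(V / voxel_volume)` voxels with the smallest
# ellipsoid quadratic form, so the voxel-count volume matches the planted
# volume to within half a voxel regardless of how the surface cuts the grid.

scene_dims <- function(spec) {
  d <- pmax(1L, as.integer(round(spec$field_size_um / spec$voxel_size_um)))
  d
}

# ---- organelle rendering ---------------------------------------------------

ball_offsets <- function(radius_um, h) {
  r <- ceiling(radius_um / h)
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  keep <- (g$dz * h[1])^2 + (g$dy * h[2])^2 + (g$dx * h[3])^2 <=
    radius_um^2 + 1e-12
  as.matrix(g[keep, , drop = FALSE])
}

stamp_balls <- function(mask, centers_um, radius_um, h) {
  d <- dim(mask)
  off <- ball_offsets(radius_um, h)
  for (i in seq_len(nrow(centers_um))) {
    c_vox <- round(centers_um[i, ] / h + 0.5)
    z <- off[, 1] + c_vox[1]; y <- off[, 2] + c_vox[2]
    x <- off[, 3] + c_vox[3]
    keep <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    mask[cbind(z[keep], y[keep], x[keep])] <- TRUE
  }
  mask
}

render_organelle <- function(spec, dims) {
  h <- spec$voxel_size_um
  L <- spec$field_size_um
  mask <- array(FALSE, dims)
  geom <- spec$organelle$geometry
  if (geom == "none") return(mask)
  if (geom == "puncta") {
    n <- spec$organelle$n_puncta
    r <- spec$organelle$radius_um
    centers <- cbind(runif(n, r, L[1] - r), runif(n, r, L[2] - r),
                     runif(n, r, L[3] - r))
    mask <- stamp_balls(mask, centers, r, h)
  } else { # tubular_network: random-walk tubes of fixed radius
    r <- spec$organelle$tube_radius_um
    step <- spec$organelle$tube_step_um
    pts <- NULL
    for (tube in seq_len(spec$organelle$n_tubes)) {
      p <- c(runif(1, r, L[1] - r), runif(1, r, L[2] - r),
             runif(1, r, L[3] - r))
      u <- rnorm(3); u[1] <- u[1] * 0.3  # mostly in-plane, like sheets of ER
      u <- u / sqrt(sum(u^2))
      for (s in seq_len(spec$organelle$n_steps)) {
        u <- u + c(0.15, 0.5, 0.5) * rnorm(3)
        u <- u / sqrt(sum(u^2))
        q <- p + u * step
        q <- pmin(pmax(q, r), L - r)
        # densify the segment so the tube has no gaps
        nsub <- max(2L, ceiling(step / (min(h) / 2)))
        tt <- seq(0, 1, length.out = nsub)
        pts <- rbind(pts, cbind(p[1] + tt * (q[1] - p[1]),
                                p[2] + tt * (q[2] - p[2]),
                                p[3] + tt * (q[3] - p[3])))
        p <- q
      }
    }
    mask <- stamp_balls(mask, pts, r, h)
  }
  mask
}

# ---- condensate placement --------------------------------------------------

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

draw_truncated_lognormal <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmin(pmax(rlnorm(n, meanlog, sdlog), lo), hi)
}

# quadratic form of a prolate spheroid (long semi-axis `a` along unit `u`,
# short semi-axes `b`) evaluated at rows of `d` (displacements, um)
spheroid_q <- function(d, u, a, b) {
  proj <- as.vector(d %*% u)
  r2 <- rowSums(d^2)
  (proj / a)^2 + (r2 - proj^2) / b^2
}

# voxels (index matrix) of the spheroid at `center_um`, exact-count selection
rasterize_spheroid <- function(center_um, u, a, b, volume_um3, dims, h) {
  voxvol <- prod(h)
  m_target <- round(volume_um3 / voxvol)
  if (m_target < 1)
    stop("planted volume ", signif(volume_um3, 3),
         " um^3 is below one voxel (", signif(voxvol, 3), " um^3)")
  rad <- ceiling(a / h) + 1L
  c_vox <- round(center_um / h + 0.5)
  zr <- max(1, c_vox[1] - rad[1]):min(dims[1], c_vox[1] + rad[1])
  yr <- max(1, c_vox[2] - rad[2]):min(dims[2], c_vox[2] + rad[2])
  xr <- max(1, c_vox[3] - rad[3]):min(dims[3], c_vox[3] + rad[3])
  g <- as.matrix(expand.grid(z = zr, y = yr, x = xr))
  cen <- voxel_centers_um(g, h)
  d <- sweep(cen, 2, center_um)
  q <- spheroid_q(d, u, a, b)
  ord <- order(q)
  take <- ord[seq_len(min(m_target, sum(q <= 1.8)))]
  g[take, , drop = FALSE]
}

adjacent_or_overlapping <- function(vox, mask) {
  d <- dim(mask)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    z <- vox[, 1] + dz; y <- vox[, 2] + dy; x <- vox[, 3] + dx
    keep <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    if (any(mask[cbind(z[keep], y[keep], x[keep])])) return(TRUE)
  }
  FALSE
}

place_condensates <- function(spec, dims, org_mask) {
  n <- spec$n_condensates
  h <- spec$voxel_size_um
  L <- spec$field_size_um
  labels <- array(0L, dims)
  empty <- data.frame(id = integer(0), z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), volume_um3 = numeric(0),
                      voxel_count = integer(0), aspect_ratio = numeric(0),
                      texture_roughness = numeric(0),
                      associated = logical(0))
  if (n == 0) return(list(objects = empty, labels = labels, masks = list()))

  vol <- draw_truncated_lognormal(n, spec$volume_dist$mean_um3,
                                  spec$volume_dist$sd_um3,
                                  spec$volume_dist$min_um3,
                                  spec$volume_dist$max_um3)
  ar <- pmax(1, draw_truncated_lognormal(n, spec$aspect_ratio_dist$mean,
                                         spec$aspect_ratio_dist$sd))
  n_assoc <- round(spec$association_fraction * n)
  assoc <- c(rep(TRUE, n_assoc), rep(FALSE, n - n_assoc))
  has_org <- any(org_mask)
  if (n_assoc > 0 && !has_org)
    stop("association_fraction > 0 requires an organelle channel")

  org_edt <- if (has_org)
    cpp_edt3d(as.vector(org_mask), dim(org_mask), h)$dist else NULL
  org_idx_um <- if (has_org)
    voxel_centers_um(which(org_mask, arr.ind = TRUE), h) else NULL

  objs <- vector("list", n)
  masks <- vector("list", n)
  placed <- matrix(numeric(0), ncol = 4)  # z, y, x, long semi-axis
  clearance <- spec$placement_clearance_um

  for (k in seq_len(n)) {
    b <- (3 * vol[k] / (4 * pi * ar[k]))^(1 / 3)
    a <- ar[k] * b
    if (any(a + h >= L - a - h))
      stop("cannot place condensate ", k, " (volume ", signif(vol[k], 3),
           " um^3): object larger than the field allows")
    u <- random_unit_vector()
    done <- FALSE
    for (try in seq_len(200)) {
      if (assoc[k]) {
        anchor <- org_idx_um[sample.int(nrow(org_idx_um), 1), ]
        center <- anchor + random_unit_vector() * runif(1, 0, 0.5 * b)
        center <- pmin(pmax(center, a + h), L - a - h)
      } else {
        center <- c(runif(1, a + h[1], L[1] - a - h[1]),
                    runif(1, a + h[2], L[2] - a - h[2]),
                    runif(1, a + h[3], L[3] - a - h[3]))
        if (has_org) {
          cv <- pmin(pmax(round(center / h + 0.5), 1), dims)
          if (org_edt[cv[1], cv[2], cv[3]] < a + clearance) next
        }
      }
      if (nrow(placed) > 0) {
        dd <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - center)^2))
        if (any(dd < placed[, 4] + a + clearance)) next
      }
      vox <- rasterize_spheroid(center, u, a, b, vol[k], dims, h)
      if (any(labels[vox] != 0)) next
      touches <- has_org && adjacent_or_overlapping(vox, org_mask)
      if (assoc[k] != touches) next
      labels[vox] <- k
      masks[[k]] <- vox
      placed <- rbind(placed, c(center, a))
      objs[[k]] <- data.frame(id = k, z_um = center[1], y_um = center[2],
                              x_um = center[3], volume_um3 = vol[k],
                              voxel_count = nrow(vox), aspect_ratio = ar[k],
                              texture_roughness = spec$texture_roughness,
                              associated = assoc[k])
      done <- TRUE
      break
    }
    if (!done)
      stop("cannot place condensate ", k, " (volume ", signif(vol[k], 3),
           " um^3, ", if (assoc[k]) "associated" else "cytoplasmic",
           "): field too crowded")
  }
  list(objects = do.call(rbind, objs), labels = labels, masks = masks)
}

# ---- intensity rendering and corruption ------------------------------------

# multiplicative band-limited speckle: blurred white noise, unit SD, mean 1
texture_field <- function(dims, roughness, corr_vox = 1.5) {
  if (roughness <= 0) return(array(1, dims))
  w <- array(rnorm(prod(dims)), dims)
  w <- cpp_gauss_blur3d(w, dims, rep(corr_vox, 3))
  w <- (w - mean(w)) / max(sd(w), 1e-12)
  pmax(1 + roughness * w, 0.1)
}

render_condensate_intensity <- function(placement, spec, dims) {
  ideal <- array(spec$intensity$background, dims)
  for (k in seq_along(placement$masks)) {
    vox <- placement$masks[[k]]
    if (is.null(vox) || nrow(vox) == 0) next
    rough <- placement$objects$texture_roughness[
      placement$objects$id == k]
    bb <- apply(vox, 2, range)
    bd <- bb[2, ] - bb[1, ] + 1L
    tx <- texture_field(bd, rough)
    rel <- sweep(vox, 2, bb[1, ] - 1L)
    ideal[vox] <- spec$intensity$condensate * tx[rel]
  }
  ideal
}

corrupt_channel <- function(ideal, spec) {
  dims <- dim(ideal)
  sig_vox <- spec$psf_sigma_um / spec$voxel_size_um
  blurred <- cpp_gauss_blur3d(ideal, dims, sig_vox)
  ps <- spec$noise$poisson_scale
  v <- as.vector(blurred)
  if (ps > 0) v <- rpois(length(v), pmax(ps * v, 0)) / ps
  v <- v + rnorm(length(v), 0, spec$noise$gaussian_sd)
  v <- round(pmin(pmax(v, 0), 65535))
  array(v, dims)
}

# ---- public generators -----------------------------------------------------

#' Generate a single-timepoint synthetic scene with ground truth
#'
#' Plants ellipsoidal condensates (optionally touching a rendered organelle
#' mask for an exact `round(association_fraction * n)` of them), renders the
#' ideal intensity fields, applies Gaussian PSF blur and Poisson-Gaussian
#' noise, and returns the corrupted stack together with the complete ground
#' truth (per-object table, ideal label map, organelle mask).
#'
#' @param spec a [scene_spec].
#' @return list with `stack` (an [image_stack]) and `truth` (class
#'   `ground_truth`: `objects` data frame, `label_map` integer array,
#'   `organelle_mask` logical array, `spec`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    dims <- scene_dims(spec)
    org_mask <- render_organelle(spec, dims)
    placement <- place_condensates(spec, dims, org_mask)
    cond_ideal <- render_condensate_intensity(placement, spec, dims)

    chans <- list(condensate = corrupt_channel(cond_ideal, spec))
    roles <- "condensate"
    if (spec$organelle$geometry != "none") {
      org_ideal <- array(spec$intensity$background, dims)
      org_ideal[org_mask] <- spec$intensity$organelle
      chans$organelle <- corrupt_channel(org_ideal, spec)
      roles <- c(roles, "organelle")
    }
    arr <- array(0, dim = c(1, length(chans), dims))
    for (i in seq_along(chans)) arr[1, i, , , ] <- chans[[i]]
    stack <- image_stack(arr, spec$voxel_size_um,
                         channel_roles = roles)
    truth <- structure(list(objects = placement$objects,
                            label_map = placement$labels,
                            organelle_mask = org_mask, spec = spec),
                       class = "ground_truth")
    list(stack = stack, truth = truth)
  })
}

#' Generate a time series with planted directed/diffusive motion and fission
#'
#' Objects are placed as in [generate_scene()]; a `round(fraction_directed *
#' n)` subset moves ballistically along a fixed random unit vector at
#' `speed_directed_um_s`, the rest take isotropic Gaussian steps with
#' per-axis variance `2 * D * dt` (confined/diffusive motion). Objects whose
#' extent would leave the field have their trajectory truncated and flagged
#' (never an error). With `fission_rate > 0` an active object may split into
#' two half-volume children that straddle the parent position. An optional
#' bleach event multiplies the condensate-channel intensity of objects
#' inside the ROI at the bleach frame by `residual` for all later frames;
#' unbleached mobile objects re-entering the ROI model the recovery.
#'
#' @param spec a [scene_spec] (the `motion` block must be present).
#' @param render render and corrupt intensity frames (default). With
#'   `render = FALSE` only ground-truth trajectories, label maps and events
#'   are produced (`stack` is `NULL`): a fast dry run for closed-form
#'   motion statistics.
#' @return list with `stack` (frames in T; `NULL` when `render = FALSE`)
#'   and `truth` (adds `trajectories`, `events`, per-frame `label_maps`).
#' @export
generate_timeseries <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    dims <- scene_dims(spec)
    h <- spec$voxel_size_um
    L <- spec$field_size_um
    mo <- spec$motion
    nf <- mo$n_frames
    dt <- mo$frame_interval_s
    org_mask <- render_organelle(spec, dims)
    placement <- place_condensates(spec, dims, org_mask)
    obj <- placement$objects
    n <- nrow(obj)
    if (n == 0) stop("timeseries needs n_condensates > 0")

    n_dir <- round(mo$fraction_directed * n)
    directed <- seq_len(n) <= n_dir  # placement order is already random
    # directed (microtubule-like) transport runs in-plane: the emulated
    # stacks are thin in Z, and ballistic motion along Z would leave the
    # field within a frame or two
    theta <- runif(n, 0, 2 * pi)
    dirs <- cbind(0, sin(theta), cos(theta))

    state <- data.frame(id = obj$id, z = obj$z_um, y = obj$y_um,
                        x = obj$x_um, vol = obj$volume_um3,
                        ar = obj$aspect_ratio, active = TRUE,
                        bleached = FALSE,
                        motion = ifelse(directed, "directed", "confined"))
    state$uz <- dirs[, 1]; state$uy <- dirs[, 2]; state$ux <- dirs[, 3]
    next_id <- n
    traj <- list()
    events <- list()
    frames <- vector("list", nf)
    label_maps <- vector("list", nf)

    bleach <- spec$bleach
    in_roi <- function(p) {
      if (is.null(bleach)) return(FALSE)
      r <- bleach$roi
      p[1] >= r$z_um[1] && p[1] <= r$z_um[2] &&
        p[2] >= r$y_um[1] && p[2] <= r$y_um[2] &&
        p[3] >= r$x_um[1] && p[3] <= r$x_um[2]
    }

    org_ideal <- NULL
    if (spec$organelle$geometry != "none") {
      org_ideal <- array(spec$intensity$background, dims)
      org_ideal[org_mask] <- spec$intensity$organelle
    }

    for (f in seq_len(nf)) {
      if (f > 1) {
        for (i in which(state$active)) {
          p <- c(state$z[i], state$y[i], state$x[i])
          step <- if (state$motion[i] == "directed") {
            mo$speed_directed_um_s * dt *
              c(state$uz[i], state$uy[i], state$ux[i])
          } else {
            rnorm(3, 0, sqrt(2 * mo$diffusion_coeff_um2_s * dt))
          }
          p <- p + step
          b <- (3 * state$vol[i] / (4 * pi * state$ar[i]))^(1 / 3)
          a <- state$ar[i] * b
          if (any(p < a + h) || any(p > L - a - h)) {
            state$active[i] <- FALSE  # left the field: truncate, flag
          } else {
            # volume exclusion in fission worlds: these condensates never
            # coalesce (no fusion is ever planted), so a step that would
            # bring two surfaces within blur-merge range is rejected. In
            # pure-motion worlds objects may pass each other (crossing
            # paths at different depths), so planted speeds stay exact.
            others <- if (spec$fission_rate > 0) which(state$active)
                      else integer(0)
            others <- others[others != i]
            ok <- TRUE
            if (length(others)) {
              bo <- (3 * state$vol[others] /
                       (4 * pi * state$ar[others]))^(1 / 3)
              ao <- state$ar[others] * bo
              dd <- sqrt((state$z[others] - p[1])^2 +
                         (state$y[others] - p[2])^2 +
                         (state$x[others] - p[3])^2)
              ok <- all(dd >= ao + a + 0.35)
            }
            if (ok) {
              state$z[i] <- p[1]; state$y[i] <- p[2]; state$x[i] <- p[3]
            }
          }
        }
        if (spec$fission_rate > 0) {
          for (i in which(state$active)) {
            if (runif(1) >= spec$fission_rate) next
            # only objects whose daughters stay comfortably above the
            # 0.05 um^3 gate split; smaller ones are not fission-competent
            # in this world (keeps planted events recoverable)
            if (state$vol[i] < 0.3) next
            vol_c <- state$vol[i] / 2
            r_c <- (3 * vol_c / (4 * pi))^(1 / 3)
            # split along the parent's long axis (projected in-plane):
            # condensates pinch along their elongation, and this keeps both
            # daughters overlapping the parent footprint
            up <- c(0, state$uy[i], state$ux[i])
            if (sqrt(sum(up^2)) < 0.3) {
              phi <- runif(1, 0, 2 * pi)
              w <- c(0, sin(phi), cos(phi))
            } else w <- up / sqrt(sum(up^2))
            p <- c(state$z[i], state$y[i], state$x[i])
            # children start just resolvable (gap ~0.45 um survives the
            # PSF) yet each still overlapping the parent footprint; one
            # child then departs ballistically, emulating motor-driven
            # removal, so daughters never blur back into a fake fusion
            off <- (r_c + 0.225) * w
            p1 <- pmin(pmax(p + off, r_c + h), L - r_c - h)
            p2 <- pmin(pmax(p - off, r_c + h), L - r_c - h)
            kids <- data.frame(
              id = next_id + 1:2, z = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
              x = c(p1[3], p2[3]), vol = vol_c, ar = 1, active = TRUE,
              bleached = state$bleached[i],
              motion = c("directed", state$motion[i]),
              uz = c(w[1], state$uz[i]), uy = c(w[2], state$uy[i]),
              ux = c(w[3], state$ux[i]))
            events[[length(events) + 1]] <- data.frame(
              type = "fission", frame = f, parent_id = state$id[i],
              child1 = kids$id[1], child2 = kids$id[2])
            state$active[i] <- FALSE
            state <- rbind(state, kids)
            next_id <- next_id + 2
          }
        }
      }
      if (!is.null(bleach) && f == bleach$frame) {
        for (i in which(state$active))
          if (in_roi(c(state$z[i], state$y[i], state$x[i])))
            state$bleached[i] <- TRUE
      }

      # rasterize active objects for this frame
      labels <- array(0L, dims)
      ideal <- array(spec$intensity$background, dims)
      for (i in which(state$active)) {
        b <- (3 * state$vol[i] / (4 * pi * state$ar[i]))^(1 / 3)
        a <- state$ar[i] * b
        vox <- rasterize_spheroid(c(state$z[i], state$y[i], state$x[i]),
                                  c(state$uz[i], state$uy[i], state$ux[i]),
                                  a, b, state$vol[i], dims, h)
        free <- labels[vox] == 0
        vox <- vox[free, , drop = FALSE]
        labels[vox] <- state$id[i]
        amp <- spec$intensity$condensate *
          (if (state$bleached[i]) bleach$residual else 1)
        ideal[vox] <- amp
      }
      traj[[f]] <- data.frame(id = state$id[state$active], frame = f,
                              z_um = state$z[state$active],
                              y_um = state$y[state$active],
                              x_um = state$x[state$active],
                              motion = state$motion[state$active],
                              bleached = state$bleached[state$active])
      label_maps[[f]] <- labels
      frames[[f]] <- if (render) corrupt_channel(ideal, spec) else NULL
    }

    stack <- NULL
    if (render) {
      nc <- if (is.null(org_ideal)) 1L else 2L
      arr <- array(0, dim = c(nf, nc, dims))
      for (f in seq_len(nf)) {
        arr[f, 1, , , ] <- frames[[f]]
        if (!is.null(org_ideal)) arr[f, 2, , , ] <- corrupt_channel(
          org_ideal, spec)
      }
      roles <- if (nc == 2) c("condensate", "organelle") else "condensate"
      stack <- image_stack(arr, h, frame_interval_s = dt,
                           channel_roles = roles)
    }
    truth <- structure(list(
      objects = obj,
      trajectories = do.call(rbind, traj),
      events = if (length(events)) do.call(rbind, events) else
        data.frame(type = character(0), frame = integer(0),
                   parent_id = integer(0), child1 = integer(0),
                   child2 = integer(0)),
      label_maps = label_maps, organelle_mask = org_mask, spec = spec),
      class = "ground_truth")
    list(stack = stack, truth = truth)
  })
}

#' Generate a paired 5'/3' probe scene
#'
#' Transcript statuses are a recorded multinomial draw over
#' (intact, orphan 5', orphan 3'). An intact transcript places one 5' and
#' one 3' spot independently within 0.1 um of a shared center (so the pair
#' is always closer than the 0.2 um spot-spot threshold); orphans place a
#' single spot in their channel. Spots are rendered as 3D Gaussians and the
#' channels corrupted like any other.
#'
#' @param spec a [scene_spec] (the `probe_spec` block must be present).
#' @return list with `stack` (channels: optional condensate, `spot_5utr`,
#'   `spot_3utr`) and `truth` (adds a `transcripts` data frame).
#' @export
generate_probe_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  ps <- spec$probe_spec
  with_seed(spec$seed, {
    dims <- scene_dims(spec)
    h <- spec$voxel_size_um
    L <- spec$field_size_um
    n <- ps$n_transcripts
    counts <- as.vector(rmultinom(1, n, c(ps$intact_fraction,
                                          ps$orphan5_fraction,
                                          ps$orphan3_fraction)))
    status <- sample(rep(c("intact", "orphan5", "orphan3"), counts))
    margin <- 0.4
    centers <- cbind(runif(n, margin, L[1] - margin),
                     runif(n, margin, L[2] - margin),
                     runif(n, margin, L[3] - margin))
    off <- function() random_unit_vector() * runif(1, 0, 0.05)
    tr <- data.frame(id = seq_len(n), status = status,
                     z5_um = NA_real_, y5_um = NA_real_, x5_um = NA_real_,
                     z3_um = NA_real_, y3_um = NA_real_, x3_um = NA_real_)
    for (i in seq_len(n)) {
      if (status[i] != "orphan3") {
        p <- centers[i, ] + off()
        tr[i, c("z5_um", "y5_um", "x5_um")] <- p
      }
      if (status[i] != "orphan5") {
        p <- centers[i, ] + off()
        tr[i, c("z3_um", "y3_um", "x3_um")] <- p
      }
    }

    render_spots <- function(pos) {
      ideal <- array(spec$intensity$background, dims)
      if (nrow(pos) == 0) return(ideal)
      s <- ps$spot_sigma_um
      rad <- ceiling(3 * s / h)
      for (i in seq_len(nrow(pos))) {
        p <- as.numeric(pos[i, ])
        cv <- round(p / h + 0.5)
        zr <- max(1, cv[1] - rad[1]):min(dims[1], cv[1] + rad[1])
        yr <- max(1, cv[2] - rad[2]):min(dims[2], cv[2] + rad[2])
        xr <- max(1, cv[3] - rad[3]):min(dims[3], cv[3] + rad[3])
        g <- as.matrix(expand.grid(z = zr, y = yr, x = xr))
        cen <- voxel_centers_um(g, h)
        d2 <- rowSums(sweep(cen, 2, p)^2)
        ideal[g] <- ideal[g] + spec$intensity$spot * exp(-d2 / (2 * s^2))
      }
      ideal
    }

    p5 <- tr[!is.na(tr$z5_um), c("z5_um", "y5_um", "x5_um")]
    p3 <- tr[!is.na(tr$z3_um), c("z3_um", "y3_um", "x3_um")]
    chans <- list()
    roles <- character(0)
    truth_extra <- list()
    if (spec$n_condensates > 0) {
      org_mask <- render_organelle(spec, dims)
      placement <- place_condensates(spec, dims, org_mask)
      chans$condensate <- corrupt_channel(
        render_condensate_intensity(placement, spec, dims), spec)
      roles <- "condensate"
      truth_extra <- list(objects = placement$objects,
                          label_map = placement$labels,
                          organelle_mask = org_mask)
    }
    chans$spot5 <- corrupt_channel(render_spots(p5), spec)
    chans$spot3 <- corrupt_channel(render_spots(p3), spec)
    roles <- c(roles, "spot_5utr", "spot_3utr")

    arr <- array(0, dim = c(1, length(chans), dims))
    for (i in seq_along(chans)) arr[1, i, , , ] <- chans[[i]]
    stack <- image_stack(arr, h, channel_roles = roles)
    truth <- structure(c(list(transcripts = tr,
                              status_counts = setNames(
                                counts, c("intact", "orphan5", "orphan3")),
                              spec = spec), truth_extra),
                       class = "ground_truth")
    list(stack = stack, truth = truth)
  })
}

#' Write ground truth to JSON
#'
#' Serializes the tabular parts of a `ground_truth` (objects, trajectories,
#' events, transcripts); voxel arrays are regenerable from the spec and are
#' not written.
#'
#' @param truth a `ground_truth`.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  keep <- intersect(names(truth),
                    c("objects", "trajectories", "events", "transcripts",
                      "status_counts"))
  out <- truth[keep]
  out$spec <- unclass(truth$spec)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
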