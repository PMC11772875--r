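# Shared fixtures: everything is generated in code at test time.

# small association scene: condensates + punctate organelle
small_scene_spec <- function(seed = 1, n = 25, assoc = 0.3) {
  scene_spec(n_condensates = n, association_fraction = assoc, seed = seed,
             field_size_um = c(3, 18, 18))
}

# match detected objects to ground truth by nearest centroid; returns the
# per-truth-object index of the nearest detection and its distance (um)
match_to_truth <- function(truth_objects, detected_objects) {
  Tm <- as.matrix(truth_objects[, c("z_um", "y_um", "x_um")])
  Dm <- as.matrix(detected_objects[, c("z_um", "y_um", "x_um")])
  if (nrow(Dm) == 0)
    return(data.frame(j = integer(nrow(Tm)), dist = rep(Inf, nrow(Tm))))
  dd <- outer(rowSums(Tm^2), rowSums(Dm^2), `+`) - 2 * Tm %*% t(Dm)
  dd[dd < 0] <- 0
  data.frame(j = apply(dd, 1, which.min), dist = sqrt(apply(dd, 1, min)))
}

# digital ball mask on an isotropic or anisotropic grid
ball_mask <- function(r_um, h, pad = 3) {
  n <- as.integer(ceiling(2 * r_um / h) + 2 * pad)
  g <- expand.grid(z = seq_len(n[1]), y = seq_len(n[2]), x = seq_len(n[3]))
  c0 <- n * h / 2
  array(((g$z - 0.5) * h[1] - c0[1])^2 + ((g$y - 0.5) * h[2] - c0[2])^2 +
          ((g$x - 0.5) * h[3] - c0[3])^2 <= r_um^2, n)
}

# axis-aligned digital ellipsoid mask (semi-axes um, order z,y,x)
ellipsoid_mask <- function(axes_um, h, pad = 3) {
  n <- as.integer(ceiling(2 * axes_um / h) + 2 * pad)
  g <- expand.grid(z = seq_len(n[1]), y = seq_len(n[2]), x = seq_len(n[3]))
  c0 <- n * h / 2
  q <- (((g$z - 0.5) * h[1] - c0[1]) / axes_um[1])^2 +
       (((g$y - 0.5) * h[2] - c0[2]) / axes_um[2])^2 +
       (((g$x - 0.5) * h[3] - c0[3]) / axes_um[3])^2
  array(q <= 1, n)
}

# build a noise-free stack with balls stamped at given centers/radii
stamp_scene <- function(centers_um, radii_um, dims, h, amp = 3000,
                        background = 100, blur_um = c(0.25, 0.08, 0.08)) {
  ideal <- array(background, dims)
  g <- expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                   x = seq_len(dims[3]))
  cen <- cbind((g$z - 0.5) * h[1], (g$y - 0.5) * h[2], (g$x - 0.5) * h[3])
  for (i in seq_len(nrow(centers_um))) {
    d2 <- (cen[, 1] - centers_um[i, 1])^2 + (cen[, 2] - centers_um[i, 2])^2 +
      (cen[, 3] - centers_um[i, 3])^2
    ideal[d2 <= radii_um[i]^2] <- amp
  }
  blurred <- condensatr:::cpp_gauss_blur3d(ideal, dims, blur_um / h)
  image_stack(array(round(blurred), c(1, 1, dims)), h,
              channel_roles = "condensate")
}
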