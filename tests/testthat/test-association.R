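make_cset <- function(labels, h = c(0.3, 0.1, 0.1)) {
  ids <- sort(unique(labels[labels > 0]))
  obj <- do.call(rbind, lapply(ids, function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    cen <- colMeans(condensatr:::voxel_centers_um(idx, h))
    data.frame(frame = 1L, id = k, voxel_count = nrow(idx),
               volume_um3 = nrow(idx) * prod(h), z_um = cen[1],
               y_um = cen[2], x_um = cen[3], mean_intensity = 1)
  }))
  structure(list(objects = obj, labels = labels, voxel_size_um = h,
                 frame = 1L), class = "condensate_set")
}

test_that("touch-or-overlap rule classifies hand-built geometries", {
  dims <- c(5L, 40L, 40L)
  h <- c(0.3, 0.1, 0.1)
  org <- array(FALSE, dims); org[2:4, 5:10, 5:10] <- TRUE
  labs <- array(0L, dims)
  labs[2:3, 8:12, 8:12] <- 1L     # overlaps the organelle
  labs[2:3, 5:8, 11:13] <- 2L     # face-adjacent in x (columns 10 | 11)
  labs[2:3, 25:28, 25:28] <- 3L   # far away
  labs[2:3, 5:8, 20:22] <- 4L     # ~1 um away in x
  of <- organelle_field(org, h)
  rec <- classify_by_distance(make_cset(labs, h), of)
  expect_equal(rec$assoc_class[rec$id == 1], "associated")
  expect_lte(rec$shortest_distance_um[rec$id == 1], 0)
  expect_equal(rec$assoc_class[rec$id == 2], "associated")  # touch
  expect_equal(rec$shortest_distance_um[rec$id == 2], 0)
  expect_equal(rec$assoc_class[rec$id == 3], "cytoplasmic")
  expect_equal(rec$assoc_class[rec$id == 4], "cytoplasmic")
  # object 4: nearest faces are x-columns 10 (organelle) and 20 (object):
  # gap of 9 voxel pitches = 0.9 um edge-to-edge
  expect_equal(rec$shortest_distance_um[rec$id == 4], 0.9,
               tolerance = 1e-6)
})

test_that("degenerate organelle masks classify correctly", {
  dims <- c(3L, 10L, 10L)
  h <- c(0.3, 0.1, 0.1)
  labs <- array(0L, dims); labs[2, 3:5, 3:5] <- 1L
  full <- organelle_field(array(TRUE, dims), h)
  rec <- classify_by_distance(make_cset(labs, h), full)
  expect_equal(rec$assoc_class, "associated")
  expect_warning(
    rec0 <- classify_by_distance(make_cset(labs, h),
                                 organelle_field(array(FALSE, dims), h)),
    "empty organelle")
  expect_equal(rec0$assoc_class, "cytoplasmic")
})

test_that("classification accuracy >= 95% on a planted scene", {
  spec <- scene_spec(n_condensates = 60, association_fraction = 0.3,
                     field_size_um = c(3, 25, 25), seed = 61)
  sc <- generate_scene(spec)
  cs <- assign_association(segment_condensates(sc$stack),
                           segment_organelle(sc$stack))
  m <- match_to_truth(sc$truth$objects, cs$objects)
  pred <- cs$objects$assoc_class[m$j] == "associated"
  acc <- mean(pred == sc$truth$objects$associated, na.rm = TRUE)
  expect_gte(acc, 0.95)
})

test_that("spot-spot colocalization applies the strict 0.2 um rule", {
  A <- rbind(c(1, 1, 1))
  B15 <- rbind(c(1, 1, 1.15))
  B25 <- rbind(c(1, 1, 1.25))
  expect_equal(colocalize_spots(A, B15)$n_A_coloc, 1)
  expect_equal(colocalize_spots(A, B25)$n_A_coloc, 0)
  # identical sets are fully colocalized both ways
  set.seed(7)
  P <- matrix(runif(60, 0, 5), ncol = 3)
  r <- colocalize_spots(P, P)
  expect_equal(r$frac_A_coloc, 1)
  expect_equal(r$frac_B_coloc, 1)
  # empty sets: zero counts, fractions defined as 0
  r0 <- colocalize_spots(P[0, , drop = FALSE], P)
  expect_equal(r0$n_A_coloc, 0)
  expect_equal(r0$frac_A_coloc, 0)
})

test_that("spot-spot matches a brute-force all-pairs check exactly", {
  set.seed(11)
  A <- matrix(runif(3 * 150, 0, 4), ncol = 3)
  B <- matrix(runif(3 * 180, 0, 4), ncol = 3)
  for (thr in c(0.1, 0.2, 0.5)) {
    r <- colocalize_spots(A, B, thr)
    bf_A <- sum(vapply(seq_len(nrow(A)), function(i)
      min(sqrt(colSums((t(B) - A[i, ])^2))) < thr, logical(1)))
    bf_B <- sum(vapply(seq_len(nrow(B)), function(i)
      min(sqrt(colSums((t(A) - B[i, ])^2))) < thr, logical(1)))
    expect_identical(as.integer(r$n_A_coloc), as.integer(bf_A))
    expect_identical(as.integer(r$n_B_coloc), as.integer(bf_B))
  }
})

test_that("colocalized fraction is monotone in the threshold", {
  set.seed(13)
  A <- matrix(runif(90, 0, 3), ncol = 3)
  B <- matrix(runif(90, 0, 3), ncol = 3)
  fr <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
               function(t) colocalize_spots(A, B, t)$frac_A_coloc,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("spot-surface distances honour the 0.1 um rule sub-voxel", {
  dims <- c(7L, 40L, 40L)
  h <- c(0.3, 0.1, 0.1)
  labs <- array(0L, dims)
  labs[2:6, 10:20, 10:20] <- 1L   # box surface at x = 2.0 um (voxel 20)
  cset <- make_cset(labs, h)
  inside <- data.frame(frame = 1, channel = "spot_5utr", z_um = 1.0,
                       y_um = 1.5, x_um = 1.5, radius_um = 0.1)
  near <- transform(inside, x_um = 2.05)   # 0.05 um outside the face
  far <- transform(inside, x_um = 2.40)    # 0.40 um outside
  r_in <- colocalize_spot_surface(inside, cset)
  r_near <- colocalize_spot_surface(near, cset)
  r_far <- colocalize_spot_surface(far, cset)
  expect_equal(r_in$n_A_coloc, 1)
  expect_lt(attr(r_in, "spot_distance_um"), 0)
  expect_equal(r_near$n_A_coloc, 1)
  expect_equal(attr(r_near, "spot_distance_um"), 0.05, tolerance = 1e-6)
  expect_equal(r_far$n_A_coloc, 0)
  expect_equal(attr(r_far, "spot_distance_um"), 0.40, tolerance = 1e-6)
})

test_that("decay directionality recovers planted fractions and ordering", {
  # degenerate: perfectly paired channels
  P <- matrix(runif(90, 0.5, 4), ncol = 3)
  d <- degradation_directionality(colocalize_spots(P, P))
  expect_equal(d$frac_intact, 1)
  expect_equal(d$frac_orphan5, 0)
  expect_equal(d$frac_orphan3, 0)

  # orphan5-dominant world calls the 3'->5' pathway
  spec <- scene_spec(n_condensates = 0, seed = 62,
                     field_size_um = c(3, 22, 22),
                     probe_spec = list(n_transcripts = 400,
                                       intact_fraction = 0.6,
                                       orphan5_fraction = 0.3,
                                       orphan3_fraction = 0.1))
  ps <- generate_probe_scene(spec)
  s5 <- detect_spots(ps$stack, "spot_5utr")
  s3 <- detect_spots(ps$stack, "spot_3utr")
  d2 <- degradation_directionality(colocalize_spots(s5, s3))
  expect_equal(d2$dominant_pathway, "3to5")
  cnt <- ps$truth$status_counts
  expect_lt(abs(d2$frac_intact - cnt["intact"] / sum(cnt)), 0.05)
  # empty channel flags undefined fractions
  expect_warning(
    d0 <- degradation_directionality(
      colocalize_spots(P[0, , drop = FALSE], P)),
    "zero spots")
  expect_true(is.na(d0$frac_intact))
})

test_that("FRAP counting reports per-class counts and percent difference", {
  spec <- scene_spec(n_condensates = 40, association_fraction = 0.4,
                     field_size_um = c(3, 25, 25), seed = 63,
                     motion = list(fraction_directed = 0.6,
                                   speed_directed_um_s = 0.05,
                                   n_frames = 12),
                     bleach = list(roi = list(z_um = c(0, 3),
                                              y_um = c(5, 20),
                                              x_um = c(5, 20)),
                                   frame = 2, residual = 0.05))
  ts <- generate_timeseries(spec)
  pre <- image_stack(ts$stack$data[1, , , , , drop = FALSE],
                     ts$stack$voxel_size_um,
                     channel_roles = ts$stack$channel_roles)
  post <- image_stack(ts$stack$data[12, , , , , drop = FALSE],
                      ts$stack$voxel_size_um,
                      channel_roles = ts$stack$channel_roles)
  ofield <- segment_organelle(pre)
  res <- frap_recovery_counts(pre, post, spec$bleach$roi, ofield)
  expect_named(res$pre, c("associated", "cytoplasmic"))
  expect_true(sum(res$post) < sum(res$pre))  # bleach removed objects
  # identical stacks give identical counts
  same <- frap_recovery_counts(pre, pre, spec$bleach$roi, ofield)
  expect_identical(same$pre, same$post)
  # recovery is dominated by mobile (cytoplasmic) objects re-entering
  expect_gte(res$post[["cytoplasmic"]], res$post[["associated"]])
})
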