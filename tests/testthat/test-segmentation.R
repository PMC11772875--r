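test_that("the 0.05 um^3 volume gate is strict and effective", {
  h <- c(0.3, 0.1, 0.1)
  dims <- c(12L, 80L, 80L)
  # radii for 0.04 and 0.5 um^3
  r_small <- (3 * 0.04 / (4 * pi))^(1 / 3)
  r_big <- (3 * 0.5 / (4 * pi))^(1 / 3)
  # deconvolved-like mild PSF so the 0.04 um^3 object survives blurring
  stack <- stamp_scene(rbind(c(1.8, 2, 2), c(1.8, 5.5, 5.5)),
                       c(r_small, r_big), dims, h,
                       blur_um = c(0.1, 0.04, 0.04))
  cs <- segment_condensates(stack, min_volume_um3 = 0.05)
  expect_equal(nrow(cs$objects), 1)
  expect_gt(cs$objects$volume_um3, 0.05)
  # without the gate, both are found
  cs0 <- segment_condensates(stack, min_volume_um3 = 0)
  expect_equal(nrow(cs0$objects), 2)
})

test_that("flat channels yield an empty set with a warning", {
  stack <- image_stack(array(0, c(1, 1, 4, 10, 10)), c(0.3, 0.1, 0.1),
                       channel_roles = "condensate")
  expect_warning(cs <- segment_condensates(stack), "flat")
  expect_equal(nrow(cs$objects), 0)
})

test_that("unknown threshold methods are a config error", {
  sc <- generate_scene(small_scene_spec(seed = 2, n = 3))
  expect_error(segment_condensates(sc$stack, threshold_method = "magic"),
               "unknown threshold method")
})

test_that("planted objects >= 0.1 um^3 are recovered with sub-0.3 um error", {
  spec <- scene_spec(n_condensates = 50, field_size_um = c(3, 28, 28),
                     volume_dist = list(mean_um3 = 0.35, sd_um3 = 0.25,
                                        min_um3 = 0.1, max_um3 = 1),
                     seed = 13)
  sc <- generate_scene(spec)
  cs <- segment_condensates(sc$stack)
  m <- match_to_truth(sc$truth$objects, cs$objects)
  expect_gte(sum(m$dist < 0.3), 48)
})

test_that("segmentation is invariant to uniform intensity rescaling", {
  sc <- generate_scene(small_scene_spec(seed = 14, n = 12))
  cs1 <- segment_condensates(sc$stack)
  scaled <- sc$stack
  scaled$data <- scaled$data * 3.7
  cs2 <- segment_condensates(scaled)
  expect_identical(cs1$labels, cs2$labels)
})

test_that("volume conservation and gate monotonicity hold", {
  sc <- generate_scene(small_scene_spec(seed = 15, n = 20))
  cs <- segment_condensates(sc$stack)
  expect_equal(sum(cs$objects$voxel_count), sum(cs$labels > 0))
  n_prev <- Inf
  for (gate in c(0, 0.05, 0.1, 0.3, 0.6)) {
    n <- nrow(segment_condensates(sc$stack, min_volume_um3 = gate)$objects)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("signed distance field follows the center-to-center metric", {
  mask <- array(FALSE, c(5, 11, 11))
  mask[3, 6, 6] <- TRUE
  of <- organelle_field(mask, c(0.3, 0.1, 0.1))
  expect_equal(of$dist[3, 6, 7], 0.1)   # XY neighbour: one XY pitch
  expect_equal(of$dist[4, 6, 6], 0.3)   # Z neighbour: one Z pitch
  expect_lt(of$dist[3, 6, 6], 0)        # inside is negative
})

test_that("empty organelle channel classifies everything cytoplasmic", {
  sc <- generate_scene(small_scene_spec(seed = 16, n = 6))
  flat <- sc$stack
  flat$data[1, 2, , , ] <- 50
  expect_warning(of <- segment_organelle(flat), "flat")
  expect_true(all(is.infinite(of$dist)))
  cs <- segment_condensates(sc$stack)
  expect_warning(rec <- classify_by_distance(cs, of), "empty organelle")
  expect_true(all(rec$assoc_class == "cytoplasmic"))
  expect_true(all(is.infinite(rec$shortest_distance_um)))
})

test_that("distance field agrees with brute force on a tubular network", {
  spec <- scene_spec(n_condensates = 0, association_fraction = 0,
                     organelle = list(geometry = "tubular_network",
                                      n_tubes = 3, n_steps = 25),
                     field_size_um = c(3, 12, 12), seed = 17)
  sc <- generate_scene(spec)
  om <- sc$truth$organelle_mask
  h <- spec$voxel_size_um
  of <- organelle_field(om, h)
  expect_true(all(of$dist[!om] >= 0))
  idx <- which(om, arr.ind = TRUE)
  cen <- condensatr:::voxel_centers_um(idx, h)
  set.seed(1)
  probes <- cbind(sample(dim(om)[1], 100, TRUE),
                  sample(dim(om)[2], 100, TRUE),
                  sample(dim(om)[3], 100, TRUE))
  pc <- condensatr:::voxel_centers_um(probes, h)
  half_diag <- sqrt(sum((h / 2)^2))
  for (i in 1:100) {
    bf <- min(sqrt(colSums((t(cen) - pc[i, ])^2)))
    got <- of$dist[probes[i, 1], probes[i, 2], probes[i, 3]]
    if (om[probes[i, 1], probes[i, 2], probes[i, 3]]) {
      expect_lte(got, 0)
    } else {
      expect_lt(abs(got - bf), half_diag)
    }
  }
})

test_that("a single rendered spot is localized within 0.05 um", {
  spec <- scene_spec(n_condensates = 0, seed = 18,
                     field_size_um = c(3, 6, 6),
                     noise = list(poisson_scale = 1, gaussian_sd = 2),
                     probe_spec = list(n_transcripts = 1, intact_fraction = 0,
                                       orphan5_fraction = 1,
                                       orphan3_fraction = 0))
  ps <- generate_probe_scene(spec)
  s5 <- detect_spots(ps$stack, "spot_5utr")
  expect_equal(nrow(s5), 1)
  tr <- ps$truth$transcripts
  err <- sqrt((s5$z_um - tr$z5_um)^2 + (s5$y_um - tr$y5_um)^2 +
                (s5$x_um - tr$x5_um)^2)
  expect_lt(err, 0.05)
  expect_equal(s5$radius_um, 0.1)
})

test_that("spot detection on an empty channel returns an empty set", {
  stack <- image_stack(array(3, c(1, 1, 4, 12, 12)), c(0.3, 0.1, 0.1),
                       channel_roles = "spot_5utr")
  expect_equal(nrow(detect_spots(stack, "spot_5utr")), 0)
  expect_error(detect_spots(stack, "spot_5utr", diameter_um = 0.05),
               "smaller than one XY pixel")
})

test_that("spot recall and precision reach 0.95 on a dense probe scene", {
  spec <- scene_spec(n_condensates = 0, seed = 19,
                     field_size_um = c(3, 26, 26),
                     probe_spec = list(n_transcripts = 500,
                                       intact_fraction = 0.5,
                                       orphan5_fraction = 0.5,
                                       orphan3_fraction = 0))
  ps <- generate_probe_scene(spec)
  tr <- ps$truth$transcripts
  truth5 <- tr[!is.na(tr$z5_um), c("z5_um", "y5_um", "x5_um")]
  names(truth5) <- c("z_um", "y_um", "x_um")
  s5 <- detect_spots(ps$stack, "spot_5utr")
  m <- match_to_truth(truth5, s5)
  recall <- mean(m$dist < 0.15)
  m_rev <- match_to_truth(s5, truth5)
  precision <- mean(m_rev$dist < 0.15)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("transcription sites are segmented inside the nuclear mask only", {
  h <- c(0.3, 0.1, 0.1)
  dims <- c(12L, 60L, 60L)
  r <- (3 * 0.3 / (4 * pi))^(1 / 3)  # 0.3 um^3 foci
  stack <- stamp_scene(rbind(c(1.8, 2, 2), c(1.8, 4, 4), c(1.8, 5.5, 1)),
                       rep(r, 3), dims, h, blur_um = c(0.15, 0.05, 0.05))
  stack$channel_roles <- "spot_5utr"
  nuc <- array(FALSE, dims)
  nuc[, 1:50, 1:50] <- TRUE  # first two foci inside, third outside (y>5)
  sites <- detect_transcription_sites(stack, "spot_5utr", nuc)
  expect_equal(nrow(sites$objects), 2)
  expect_true(all(abs(sites$objects$volume_um3 - 0.3) / 0.3 < 0.15))
  # empty mask -> empty set; missing mask -> error
  empty <- detect_transcription_sites(stack, "spot_5utr",
                                      array(FALSE, dims))
  expect_equal(nrow(empty$objects), 0)
  expect_error(detect_transcription_sites(stack, "spot_5utr", NULL),
               "nuclear mask")
})
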