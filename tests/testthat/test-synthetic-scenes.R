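test_that("empty scene gives pure noise and empty ground truth", {
  spec <- scene_spec(n_condensates = 0, organelle = list(geometry = "none"),
                     association_fraction = 0, field_size_um = c(1.5, 5, 5),
                     seed = 3)
  sc <- generate_scene(spec)
  expect_equal(nrow(sc$truth$objects), 0)
  expect_false(any(sc$truth$label_map > 0))
  expect_gt(sd(sc$stack$data), 0)  # noise, not a constant field
})

test_that("generation is bit-identical for identical (spec, seed)", {
  spec <- small_scene_spec(seed = 5, n = 10)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$objects, b$truth$objects)
  # and the global RNG stream of the caller is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_scene(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("planted association count is exact", {
  spec <- scene_spec(n_condensates = 100, association_fraction = 0.5,
                     field_size_um = c(3, 30, 30), seed = 8)
  sc <- generate_scene(spec)
  expect_equal(sum(sc$truth$objects$associated), 50)
  expect_equal(nrow(sc$truth$objects), 100)  # conservation: no silent drops
})

test_that("rasterized volumes track planted volumes within 10%", {
  sc <- generate_scene(small_scene_spec(seed = 2, n = 30))
  o <- sc$truth$objects
  voxvol <- prod(sc$truth$spec$voxel_size_um)
  rel <- abs(o$voxel_count * voxvol - o$volume_um3) / o$volume_um3
  expect_true(all(rel[o$volume_um3 >= 0.05] < 0.10))
})

test_that("association labels match planted mask geometry (brute force)", {
  sc <- generate_scene(small_scene_spec(seed = 4, n = 20))
  lm <- sc$truth$label_map
  om <- sc$truth$organelle_mask
  for (k in sc$truth$objects$id) {
    vox <- which(lm == k, arr.ind = TRUE)
    touches <- condensatr:::adjacent_or_overlapping(vox, om)
    expect_identical(touches, sc$truth$objects$associated[
      sc$truth$objects$id == k])
  }
})

test_that("impossible placements fail loudly, naming the object", {
  crowded <- scene_spec(n_condensates = 60, field_size_um = c(1.2, 3, 3),
                        organelle = list(geometry = "none"),
                        association_fraction = 0, seed = 1)
  expect_error(generate_scene(crowded), "cannot place condensate")
  tiny <- scene_spec(n_condensates = 2, seed = 1,
                     organelle = list(geometry = "none"),
                     association_fraction = 0,
                     volume_dist = list(mean_um3 = 0.001, sd_um3 = 1e-6,
                                        min_um3 = 0.0005, max_um3 = 0.002))
  expect_error(generate_scene(tiny), "below one voxel")
})

test_that("scene spec invariants are enforced", {
  expect_error(scene_spec(probe_spec = list(intact_fraction = 0.5,
                                            orphan5_fraction = 0.2,
                                            orphan3_fraction = 0.2)),
               "sum to 1")
  expect_error(scene_spec(association_fraction = 1.2), "fractions")
  expect_error(scene_spec(voxel_size_um = c(0.3, 0, 0.1)), "positive")
  expect_error(scene_spec(motion = list(frame_interval_s = 0)),
               "frame_interval_s")
})

test_that("directed ground-truth steps have exact length v*dt", {
  spec <- scene_spec(n_condensates = 8, organelle = list(geometry = "none"),
                     association_fraction = 0, field_size_um = c(3, 25, 25),
                     motion = list(fraction_directed = 1,
                                   speed_directed_um_s = 0.05, n_frames = 6),
                     seed = 10)
  ts <- generate_timeseries(spec, render = FALSE)
  tr <- ts$truth$trajectories
  for (id in unique(tr$id)) {
    p <- as.matrix(tr[tr$id == id, c("z_um", "y_um", "x_um")])
    if (nrow(p) < 2) next
    steps <- unname(sqrt(rowSums(diff(p)^2)))
    expect_equal(steps, rep(0.05 * 15, length(steps)), tolerance = 1e-10)
  }
})

test_that("zero-motion spec gives stationary trajectories", {
  spec <- scene_spec(n_condensates = 6, organelle = list(geometry = "none"),
                     association_fraction = 0, field_size_um = c(3, 15, 15),
                     motion = list(fraction_directed = 0,
                                   diffusion_coeff_um2_s = 0, n_frames = 5),
                     seed = 12)
  ts <- generate_timeseries(spec, render = FALSE)
  tr <- ts$truth$trajectories
  sp <- tapply(seq_len(nrow(tr)), tr$id, function(i) {
    p <- as.matrix(tr[i, c("z_um", "y_um", "x_um")])
    if (nrow(p) < 2) 0 else max(abs(diff(p)))
  })
  expect_true(all(unlist(sp) == 0))
})

test_that("planted diffusion matches the 6*D*dt closed form (Monte Carlo)", {
  D <- 0.001
  spec <- scene_spec(n_condensates = 200,
                     organelle = list(geometry = "none"),
                     association_fraction = 0, field_size_um = c(8, 45, 45),
                     placement_clearance_um = 0.3,
                     motion = list(fraction_directed = 0,
                                   diffusion_coeff_um2_s = D,
                                   n_frames = 20),
                     seed = 77)
  ts <- generate_timeseries(spec, render = FALSE)
  tr <- ts$truth$trajectories
  d2 <- unlist(lapply(split(tr, tr$id), function(t) {
    t <- t[order(t$frame), ]
    if (nrow(t) < 2) return(NULL)
    rowSums(diff(as.matrix(t[, c("z_um", "y_um", "x_um")]))^2)
  }))
  expect_gt(length(d2), 1000)
  expect_equal(mean(d2), 6 * D * 15, tolerance = 0.10)
})

test_that("probe scenes honour planted transcript statuses", {
  # all intact: every 3' position has its 5' partner within 0.2 um
  spec <- scene_spec(n_condensates = 0, seed = 31,
                     field_size_um = c(3, 10, 10),
                     probe_spec = list(n_transcripts = 60,
                                       intact_fraction = 1,
                                       orphan5_fraction = 0,
                                       orphan3_fraction = 0))
  ps <- generate_probe_scene(spec)
  tr <- ps$truth$transcripts
  sep <- sqrt((tr$z5_um - tr$z3_um)^2 + (tr$y5_um - tr$y3_um)^2 +
                (tr$x5_um - tr$x3_um)^2)
  expect_true(all(sep < 0.2))

  # all orphan5: no 3' spots exist at all
  spec5 <- scene_spec(n_condensates = 0, seed = 32,
                      field_size_um = c(3, 10, 10),
                      probe_spec = list(n_transcripts = 40,
                                        intact_fraction = 0,
                                        orphan5_fraction = 1,
                                        orphan3_fraction = 0))
  ps5 <- generate_probe_scene(spec5)
  expect_true(all(is.na(ps5$truth$transcripts$z3_um)))

  # recorded multinomial counts agree with the per-transcript statuses
  spec_m <- scene_spec(n_condensates = 0, seed = 33,
                       field_size_um = c(3, 20, 20),
                       probe_spec = list(n_transcripts = 400,
                                         intact_fraction = 0.6,
                                         orphan5_fraction = 0.25,
                                         orphan3_fraction = 0.15))
  psm <- generate_probe_scene(spec_m)
  tab <- table(psm$truth$transcripts$status)
  expect_equal(unname(psm$truth$status_counts["intact"]),
               unname(tab[["intact"]]))
  expect_equal(unname(psm$truth$status_counts["orphan5"]),
               unname(tab[["orphan5"]]))
  expect_equal(sum(psm$truth$status_counts), 400)
})

test_that("scene specs round-trip through YAML", {
  spec <- small_scene_spec(seed = 44, n = 7)
  f <- tempfile(fileext = ".yaml")
  write_scene_spec(spec, f)
  spec2 <- read_scene_spec(f)
  expect_equal(unclass(spec), unclass(spec2), tolerance = 1e-12)
})
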