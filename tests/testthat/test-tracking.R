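fake_frames <- function(pos_list) {
  # pos_list: list of matrices (one per frame) of (z, y, x) positions
  lapply(pos_list, function(p) {
    if (is.null(p) || nrow(p) == 0)
      return(data.frame(id = integer(0), z_um = numeric(0),
                        y_um = numeric(0), x_um = numeric(0)))
    data.frame(id = seq_len(nrow(p)), z_um = p[, 1], y_um = p[, 2],
               x_um = p[, 3])
  })
}

test_that("stationary objects give one track each, full length", {
  P <- rbind(c(1, 2, 2), c(1, 8, 8))
  tk <- link_tracks(fake_frames(rep(list(P), 10)), gate_um = 2)
  expect_equal(length(unique(tk$track_id)), 2)
  expect_true(all(table(tk$track_id) == 10))
})

test_that("a jump beyond the gate terminates the track", {
  frames <- fake_frames(list(rbind(c(1, 2, 2)), rbind(c(1, 2, 2.5)),
                             rbind(c(1, 2, 9))))
  tk <- link_tracks(frames, gate_um = 2, max_gap = 0)
  expect_equal(length(unique(tk$track_id)), 2)
})

test_that("optimal linking recovers planted directed identities", {
  spec <- scene_spec(n_condensates = 50, organelle = list(geometry = "none"),
                     association_fraction = 0, field_size_um = c(4, 35, 35),
                     motion = list(fraction_directed = 1,
                                   speed_directed_um_s = 0.05,
                                   n_frames = 10),
                     seed = 71)
  ts <- generate_timeseries(spec, render = FALSE)
  tr <- ts$truth$trajectories
  frames <- lapply(sort(unique(tr$frame)), function(f) {
    d <- tr[tr$frame == f, ]
    data.frame(id = d$id, z_um = d$z_um, y_um = d$y_um, x_um = d$x_um)
  })
  tk <- link_tracks(frames, gate_um = 2)
  # a link is correct when consecutive rows of a track carry one truth id
  links <- do.call(rbind, lapply(split(tk, tk$track_id), function(t) {
    t <- t[order(t$frame), ]
    if (nrow(t) < 2) return(NULL)
    data.frame(a = t$object_id[-nrow(t)], b = t$object_id[-1])
  }))
  expect_gte(mean(links$a == links$b), 0.95)
})

test_that("track linearity has its closed forms and range", {
  straight <- data.frame(frame = 1:3, z_um = c(0, 0, 0), y_um = c(0, 0, 0),
                         x_um = c(0, 1, 2))
  expect_equal(track_linearity(straight), 1.0)
  back <- data.frame(frame = 1:3, z_um = 0, y_um = 0, x_um = c(0, 1, 0))
  expect_equal(as.numeric(track_linearity(back)), 0.0)
  still <- data.frame(frame = 1:3, z_um = 0, y_um = 0, x_um = 0)
  expect_equal(as.numeric(track_linearity(still)), 0)
  expect_equal(attr(track_linearity(still), "flag"), "stationary")
  single <- data.frame(frame = 1, z_um = 0, y_um = 0, x_um = 0)
  expect_true(is.na(track_linearity(single)))

  # property: always in [0, 1]; 1 only for monotone collinear tracks
  set.seed(5)
  for (i in 1:50) {
    t <- data.frame(frame = 1:6,
                    z_um = cumsum(rnorm(6)), y_um = cumsum(rnorm(6)),
                    x_um = cumsum(rnorm(6)))
    l <- as.numeric(track_linearity(t))
    expect_gte(l, 0); expect_lte(l, 1 + 1e-12)
    P <- as.matrix(t[, c("z_um", "y_um", "x_um")])
    st <- diff(P)
    collinear_monotone <-
      sqrt(sum((P[6, ] - P[1, ])^2)) == sum(sqrt(rowSums(st^2)))
    expect_identical(abs(l - 1) < 1e-12, collinear_monotone)
  }
})

test_that("instantaneous speed is plain step arithmetic", {
  t <- data.frame(frame = 1:2, z_um = c(0, 0), y_um = c(0, 0),
                  x_um = c(0, 0.3))
  expect_equal(instantaneous_speed(t, 15)$speed_um_s, 0.02)
  still <- data.frame(frame = 1:4, z_um = 0, y_um = 0, x_um = 0)
  expect_true(all(instantaneous_speed(still, 15)$speed_um_s == 0))
})

test_that("MSD closed forms: ballistic v^2 tau^2, stationary zero", {
  v <- 0.04; dt <- 15
  tr <- data.frame(track_id = 1, frame = 1:10, z_um = 0, y_um = 0,
                   x_um = v * dt * (0:9))
  m <- msd(tr, dt, 45)
  expect_equal(m$msd_um2, (v * m$lag_s)^2, tolerance = 1e-12)
  expect_equal(as.numeric(msd_fit(m, "directed", intercept = FALSE)), v)
  still <- data.frame(track_id = 1, frame = 1:10, z_um = 1, y_um = 1,
                      x_um = 1)
  expect_true(all(msd(still, dt, 45)$msd_um2 == 0))
  # lag with no support is reported missing
  short <- data.frame(track_id = 1, frame = 1:2, z_um = 0, y_um = 0,
                      x_um = c(0, 1))
  m2 <- msd(short, dt, 45)
  expect_true(is.nan(m2$msd_um2[3]) || is.na(m2$msd_um2[3]))
})

test_that("directed tracks are more linear than diffusive ones", {
  mk <- function(fd, D, seed) {
    spec <- scene_spec(n_condensates = 100,
                       organelle = list(geometry = "none"),
                       association_fraction = 0,
                       field_size_um = c(6, 40, 40),
                       placement_clearance_um = 0.3,
                       motion = list(fraction_directed = fd,
                                     speed_directed_um_s = 0.05,
                                     diffusion_coeff_um2_s = D,
                                     n_frames = 8),
                       seed = seed)
    ts <- generate_timeseries(spec, render = FALSE)
    tr <- ts$truth$trajectories
    vapply(split(tr, tr$id), function(t)
      if (nrow(t) >= 4) as.numeric(track_linearity(t)) else NA_real_,
      numeric(1))
  }
  lin_dir <- mk(1, 0.002, 72)
  lin_dif <- mk(0, 0.002, 73)
  expect_gt(mean(lin_dir, na.rm = TRUE), mean(lin_dif, na.rm = TRUE))
  mw <- mann_whitney(lin_dir[!is.na(lin_dir)], lin_dif[!is.na(lin_dif)])
  expect_lt(mw$p, 0.01)
})

test_that("track class is a majority vote with ties to associated", {
  expect_equal(track_class(c("associated", "cytoplasmic", "associated")),
               "associated")
  expect_equal(track_class(c("cytoplasmic", "cytoplasmic", "associated")),
               "cytoplasmic")
  expect_equal(track_class(c("associated", "cytoplasmic")), "associated")
})

test_that("fission and fusion detection works on ideal label maps", {
  dims <- c(3L, 30L, 30L)
  one <- array(0L, dims); one[2, 10:16, 10:16] <- 1L
  split2 <- array(0L, dims)
  split2[2, 10:12, 10:16] <- 1L
  split2[2, 15:17, 10:16] <- 2L
  static <- list(one, one, one)
  expect_equal(nrow(detect_fission_fusion(static)), 0)
  fission <- detect_fission_fusion(list(one, split2))
  expect_equal(fission$type, "fission")
  expect_equal(fission$frame, 2)
  fusion <- detect_fission_fusion(list(split2, one))
  expect_equal(fusion$type, "fusion")
  expect_equal(nrow(fusion[fusion$type == "fission", ]), 0)
})

test_that("track duration follows the frame interval", {
  t <- data.frame(frame = c(2, 3, 5), z_um = 0, y_um = 0, x_um = 0)
  expect_equal(track_duration(t, 15), 45)
})

test_that("gap closing bridges a single missing frame", {
  frames <- fake_frames(list(rbind(c(1, 5, 5)), NULL, rbind(c(1, 5, 5.4))))
  tk <- link_tracks(frames, gate_um = 2, max_gap = 1)
  expect_equal(length(unique(tk$track_id)), 1)
  tk0 <- link_tracks(frames, gate_um = 2, max_gap = 0)
  expect_equal(length(unique(tk0$track_id)), 2)
})
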