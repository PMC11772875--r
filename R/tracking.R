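# Frame-to-frame linking by optimal assignment (Hungarian algorithm via
# clue::solve_LSAP) in full 3D physical coordinates, with a hard distance
# gate, birth/death handling, and gap closing up to `max_gap` skipped
# frames. Deterministic and order-independent; ties are broken by the
# solver's canonical order.

normalize_detections <- function(per_frame) {
  out <- lapply(seq_along(per_frame), function(f) {
    x <- per_frame[[f]]
    if (inherits(x, "condensate_set")) x <- x$objects
    if (nrow(x) == 0)
      return(data.frame(frame = integer(0), object_id = integer(0),
                        z_um = numeric(0), y_um = numeric(0),
                        x_um = numeric(0)))
    data.frame(frame = f, object_id = x$id, z_um = x$z_um, y_um = x$y_um,
               x_um = x$x_um)
  })
  out
}

lap_link <- function(P, Q, gate) {
  # returns integer vector: for each row of P the matched row of Q, NA if none
  n1 <- nrow(P); n2 <- nrow(Q)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  BIG <- 1e6
  D <- sqrt(outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q))
  D[!is.finite(D)] <- 0
  C <- matrix(BIG, n1 + n2, n1 + n2)
  C[1:n1, 1:n2] <- ifelse(D <= gate, D, BIG)
  for (i in 1:n1) C[i, n2 + i] <- gate          # death
  for (j in 1:n2) C[n1 + j, j] <- gate          # birth
  C[(n1 + 1):(n1 + n2), (n2 + 1):(n2 + n1)] <- 0
  sol <- clue::solve_LSAP(C)
  m <- rep(NA_integer_, n1)
  for (i in 1:n1) {
    j <- sol[i]
    if (j <= n2 && C[i, j] < BIG) m[i] <- j
  }
  m
}

#' Link per-frame detections into tracks
#'
#' @param per_frame list (one element per frame, in time order) of
#'   `condensate_set`s or data frames with `id`, `z_um`, `y_um`, `x_um`.
#' @param gate_um hard per-frame linking gate (default 2 um per frame; for
#'   gap closing the gate scales with the number of skipped frames).
#' @param max_gap maximum number of missing frames bridged inside a track.
#' @return a data frame of class `track_set`: `track_id`, `frame`,
#'   `object_id`, `z_um`, `y_um`, `x_um`, ordered by track then frame.
#' @export
link_tracks <- function(per_frame, gate_um = 2, max_gap = 1L) {
  if (length(per_frame) < 2) stop("need at least 2 frames to link")
  if (gate_um <= 0) stop("gate_um must be > 0")
  det <- normalize_detections(per_frame)
  nf <- length(det)
  # assign every detection a track id; propagate via frame-to-frame LAP
  for (f in seq_len(nf))
    det[[f]]$track_id <- rep(NA_integer_, nrow(det[[f]]))
  next_track <- 0L
  if (nrow(det[[1]])) {
    det[[1]]$track_id <- seq_len(nrow(det[[1]]))
    next_track <- nrow(det[[1]])
  }
  for (f in seq_len(nf - 1)) {
    P <- as.matrix(det[[f]][, c("z_um", "y_um", "x_um")])
    Q <- as.matrix(det[[f + 1]][, c("z_um", "y_um", "x_um")])
    m <- lap_link(P, Q, gate_um)
    if (nrow(det[[f + 1]])) {
      for (i in seq_along(m)) {
        if (!is.na(m[i]))
          det[[f + 1]]$track_id[m[i]] <- det[[f]]$track_id[i]
      }
      new <- which(is.na(det[[f + 1]]$track_id))
      if (length(new)) {
        det[[f + 1]]$track_id[new] <- next_track + seq_along(new)
        next_track <- next_track + length(new)
      }
    }
  }
  tracks <- do.call(rbind, det)

  # gap closing: join a track ending at fe to one starting at fs when
  # 2 <= fs - fe <= max_gap + 1 and the jump fits the scaled gate
  if (max_gap >= 1 && nrow(tracks)) {
    repeat {
      info <- do.call(rbind, lapply(split(tracks, tracks$track_id),
        function(tr) {
          tr <- tr[order(tr$frame), ]
          data.frame(track_id = tr$track_id[1],
                     f0 = tr$frame[1], f1 = tr$frame[nrow(tr)],
                     z0 = tr$z_um[1], y0 = tr$y_um[1], x0 = tr$x_um[1],
                     z1 = tr$z_um[nrow(tr)], y1 = tr$y_um[nrow(tr)],
                     x1 = tr$x_um[nrow(tr)])
        }))
      ends <- info
      starts <- info
      cand <- NULL
      for (i in seq_len(nrow(ends))) for (j in seq_len(nrow(starts))) {
        gap <- starts$f0[j] - ends$f1[i]
        if (gap < 2 || gap > max_gap + 1) next
        d <- sqrt((starts$z0[j] - ends$z1[i])^2 +
                  (starts$y0[j] - ends$y1[i])^2 +
                  (starts$x0[j] - ends$x1[i])^2)
        if (d <= gate_um * gap)
          cand <- rbind(cand, data.frame(
            from = ends$track_id[i], to = starts$track_id[j], d = d))
      }
      if (is.null(cand)) break
      # greedy on shortest jump; one join per iteration keeps it simple
      cand <- cand[order(cand$d), ]
      tracks$track_id[tracks$track_id == cand$to[1]] <- cand$from[1]
      if (nrow(cand) == 1) break
    }
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  class(tracks) <- c("track_set", "data.frame")
  tracks
}

#' Track linearity (net displacement over path length)
#'
#' 1 for straight monotone motion, 0 for closed out-and-back paths.
#' A track with no motion at all (0/0) is defined as 0 and flagged; a
#' single-point track returns `NA` (undefined, flagged).
#'
#' @param track data frame with `frame`, `z_um`, `y_um`, `x_um` (one track).
#' @return scalar in `[0, 1]` (or `NA`), with attribute `flag` when
#'   degenerate.
#' @export
track_linearity <- function(track) {
  track <- track[order(track$frame), ]
  P <- as.matrix(track[, c("z_um", "y_um", "x_um")])
  if (nrow(P) < 2)
    return(structure(NA_real_, flag = "single_point"))
  steps <- diff(P)
  total <- sum(sqrt(rowSums(steps^2)))
  net <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
  if (total == 0) return(structure(0, flag = "stationary"))
  net / total
}

#' Per-step instantaneous speeds of a track
#'
#' @param track one track (frame-ordered rows).
#' @param frame_interval_s seconds per frame.
#' @return data frame `frame` (of the step's end), `speed_um_s`.
#' @export
instantaneous_speed <- function(track, frame_interval_s) {
  track <- track[order(track$frame), ]
  P <- as.matrix(track[, c("z_um", "y_um", "x_um")])
  if (nrow(P) < 2)
    return(data.frame(frame = integer(0), speed_um_s = numeric(0)))
  steps <- sqrt(rowSums(diff(P)^2))
  dtf <- diff(track$frame)
  data.frame(frame = track$frame[-1],
             speed_um_s = steps / (dtf * frame_interval_s))
}

#' Ensemble mean squared displacement
#'
#' Time-averaged squared displacement per track at each lag, then averaged
#' over tracks (each track weighted equally). Lags run over multiples of
#' the frame interval up to `max_lag_s` (the published readout uses lags of
#' 15, 30 and 45 s). Lags no track can support are reported `NA`.
#'
#' @param tracks a `track_set` (or any data frame with `track_id`, `frame`
#'   and position columns).
#' @param frame_interval_s seconds per frame.
#' @param max_lag_s largest lag (default 45 s).
#' @return data frame `lag_s`, `msd_um2`, `n_tracks`.
#' @export
msd <- function(tracks, frame_interval_s, max_lag_s = 45) {
  max_k <- floor(max_lag_s / frame_interval_s)
  if (max_k < 1) stop("max_lag_s is below one frame interval")
  per_track <- split(tracks, tracks$track_id)
  acc <- matrix(NA_real_, length(per_track), max_k)
  for (t in seq_along(per_track)) {
    tr <- per_track[[t]][order(per_track[[t]]$frame), ]
    P <- as.matrix(tr[, c("z_um", "y_um", "x_um")])
    fr <- tr$frame
    for (k in seq_len(max_k)) {
      j <- match(fr + k, fr)
      ok <- !is.na(j)
      if (!any(ok)) next
      d2 <- rowSums((P[j[ok], , drop = FALSE] - P[ok, , drop = FALSE])^2)
      acc[t, k] <- mean(d2)
    }
  }
  data.frame(lag_s = seq_len(max_k) * frame_interval_s,
             msd_um2 = colMeans(acc, na.rm = TRUE),
             n_tracks = colSums(!is.na(acc)))
}

#' Fit an MSD curve to a diffusive or directed motion model
#'
#' Diffusive: `MSD = 6 D tau + c` (3D), returning `D`; directed:
#' `MSD = v^2 tau^2 + c`, returning `v`. By default the fit carries an
#' intercept `c` that absorbs the static localization-error offset
#' (`2 d sigma_loc^2`), which otherwise biases `D` upward; set
#' `intercept = FALSE` to force the fit through the origin.
#'
#' @param msd_df output of [msd()].
#' @param model `"diffusive"` or `"directed"`.
#' @param intercept fit a localization-noise offset (default `TRUE`).
#' @return named scalar (`D_um2_s` or `v_um_s`).
#' @export
msd_fit <- function(msd_df, model = c("diffusive", "directed"),
                    intercept = TRUE) {
  model <- match.arg(model)
  ok <- is.finite(msd_df$msd_um2)
  tau <- msd_df$lag_s[ok]
  y <- msd_df$msd_um2[ok]
  if (length(tau) < 1) stop("no finite MSD values to fit")
  x <- if (model == "diffusive") tau else tau^2
  slope <- if (intercept && length(tau) >= 2)
    coef(lm(y ~ x))[["x"]]
  else
    sum(x * y) / sum(x^2)
  if (model == "diffusive") c(D_um2_s = slope / 6)
  else c(v_um_s = sqrt(max(slope, 0)))
}

#' Track duration in seconds
#'
#' @param track one track.
#' @param frame_interval_s seconds per frame.
#' @return `(last - first frame) * frame_interval_s`.
#' @export
track_duration <- function(track, frame_interval_s) {
  (max(track$frame) - min(track$frame)) * frame_interval_s
}

#' Majority-vote class label of a track
#'
#' The track inherits the majority of its per-frame association classes;
#' ties go to `"associated"` (the conservative choice).
#'
#' @param classes character vector of per-frame classes.
#' @return `"associated"` or `"cytoplasmic"`.
#' @export
track_class <- function(classes) {
  n_a <- sum(classes == "associated")
  n_c <- sum(classes == "cytoplasmic")
  if (n_a >= n_c) "associated" else "cytoplasmic"
}

#' Detect fission and fusion events from label-map overlap
#'
#' Fission: one object at frame `t` whose mask overlaps two or more
#' disjoint objects at `t + 1`, each overlap of at least `min_overlap_vox`
#' voxels; fusion is the symmetric case. Works on the per-frame label
#' arrays (from segmentation or ground truth).
#'
#' @param label_maps list of integer label arrays, one per frame.
#' @param min_overlap_vox minimum shared-voxel count for a parent-child
#'   relation (default 3; guards against threshold jitter).
#' @return data frame `type` (`"fission"`/`"fusion"`), `frame` (the later
#'   frame), `parent_ids`, `child_ids` (comma-separated label lists).
#' @export
detect_fission_fusion <- function(label_maps, min_overlap_vox = 3L) {
  events <- list()
  for (f in seq_len(length(label_maps) - 1)) {
    a <- label_maps[[f]]
    b <- label_maps[[f + 1]]
    both <- a > 0 & b > 0
    if (!any(both)) next
    ov <- table(parent = a[both], child = b[both])
    ov <- as.data.frame(ov, stringsAsFactors = FALSE)
    ov <- ov[ov$Freq >= min_overlap_vox, , drop = FALSE]
    if (nrow(ov) == 0) next
    # fission: a parent with >= 2 children that claim it as main parent
    for (p in unique(ov$parent)) {
      kids <- ov$child[ov$parent == p]
      main <- vapply(kids, function(k) {
        sub <- ov[ov$child == k, ]
        sub$parent[which.max(sub$Freq)] == p
      }, logical(1))
      kids <- kids[main]
      if (length(kids) >= 2)
        events[[length(events) + 1]] <- data.frame(
          type = "fission", frame = f + 1, parent_ids = p,
          child_ids = paste(kids, collapse = ","))
    }
    for (k in unique(ov$child)) {
      pars <- ov$parent[ov$child == k]
      main <- vapply(pars, function(p) {
        sub <- ov[ov$parent == p, ]
        sub$child[which.max(sub$Freq)] == k
      }, logical(1))
      pars <- pars[main]
      if (length(pars) >= 2)
        events[[length(events) + 1]] <- data.frame(
          type = "fusion", frame = f + 1, parent_ids = paste(pars,
                                                             collapse = ","),
          child_ids = k)
    }
  }
  if (length(events) == 0)
    return(data.frame(type = character(0), frame = integer(0),
                      parent_ids = character(0), child_ids = character(0)))
  do.call(rbind, events)
}
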