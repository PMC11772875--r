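# Organelle-association classification and distance-threshold
# colocalization. Conventions follow the published analysis: a condensate
# is organelle-associated iff its shortest surface distance is <= 0 um
# (touch or overlap); spot-spot colocalization is center distance < 0.2 um;
# spot-surface is surface-to-center distance < 0.1 um (strict "<" for the
# spot rules, "<= 0" for surface-surface). "Touch" is operationalized as
# voxel-box contact: overlapping or 26-adjacent voxels (boxes meeting at a
# face, edge or corner) give distance <= 0. Positive distances are exact
# point/box-to-box distances to the nearest organelle voxel found via the
# EDT feature transform.

box_gap_distance <- function(delta_um, h) {
  # gap between two voxel boxes with centers `delta_um` apart
  g <- pmax(abs(delta_um) - matrix(h, nrow(delta_um), 3, byrow = TRUE), 0)
  sqrt(rowSums(g^2))
}

#' Classify condensates as organelle-associated or cytoplasmic
#'
#' The shortest signed distance of each condensate to the organelle surface
#' is computed (negative for overlap, exactly 0 for voxel contact, the
#' box-to-box gap otherwise) and the `<= threshold_um` rule applied
#' (default 0: touch or overlap).
#'
#' @param cset a `condensate_set`.
#' @param ofield an `organelle_field` on the same grid.
#' @param threshold_um association rule threshold (default 0 um).
#' @return data frame: `id`, `shortest_distance_um`, `assoc_class`.
#' @export
classify_by_distance <- function(cset, ofield, threshold_um = 0) {
  stopifnot(inherits(cset, "condensate_set"),
            inherits(ofield, "organelle_field"))
  if (!identical(dim(cset$labels), dim(ofield$mask)))
    stop("condensate set and organelle field are on different grids")
  obj <- cset$objects
  res <- data.frame(id = obj$id, shortest_distance_um = numeric(nrow(obj)),
                    assoc_class = character(nrow(obj)))
  if (nrow(obj) == 0) return(res)
  if (!any(ofield$mask)) {
    warning("empty organelle mask: all condensates classified cytoplasmic")
    res$shortest_distance_um <- Inf
    res$assoc_class <- "cytoplasmic"
    return(res)
  }
  h <- cset$voxel_size_um
  dims <- dim(cset$labels)
  for (i in seq_len(nrow(obj))) {
    idx <- which(cset$labels == obj$id[i], arr.ind = TRUE)
    dmin <- min(ofield$dist[idx])
    if (dmin <= 0) {           # voxel overlap
      res$shortest_distance_um[i] <- dmin
    } else if (adjacent_or_overlapping(idx, ofield$mask)) {
      res$shortest_distance_um[i] <- 0   # touch: boxes in contact
    } else {
      feat <- ofield$feature[idx] + 1L   # 1-based linear index
      fidx <- arrayInd(feat, dims)
      delta <- voxel_centers_um(idx, h) - voxel_centers_um(fidx, h)
      res$shortest_distance_um[i] <- min(box_gap_distance(delta, h))
    }
  }
  res$assoc_class <- ifelse(res$shortest_distance_um <= threshold_um,
                            "associated", "cytoplasmic")
  res
}

#' Attach association classes to a condensate set
#'
#' Convenience wrapper around [classify_by_distance()] that merges
#' `shortest_distance_um` and `assoc_class` into the object table.
#'
#' @inheritParams classify_by_distance
#' @return the `condensate_set` with association columns filled.
#' @export
assign_association <- function(cset, ofield, threshold_um = 0) {
  rec <- classify_by_distance(cset, ofield, threshold_um)
  cset$objects$shortest_distance_um <-
    rec$shortest_distance_um[match(cset$objects$id, rec$id)]
  cset$objects$assoc_class <- rec$assoc_class[match(cset$objects$id, rec$id)]
  cset
}

new_coloc_result <- function(n_A, n_B, n_A_coloc, n_B_coloc, threshold_um,
                             mode) {
  structure(list(
    n_A = n_A, n_B = n_B, n_A_coloc = n_A_coloc, n_B_coloc = n_B_coloc,
    frac_A_coloc = if (n_A > 0) n_A_coloc / n_A else 0,
    frac_B_coloc = if (n_B > 0) n_B_coloc / n_B else 0,
    threshold_um = threshold_um, mode = mode),
    class = "colocalization_result")
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat(sprintf("<colocalization %s, threshold %g um>\n", x$mode,
              x$threshold_um))
  cat(sprintf("  A: %d/%d colocalized (%.1f%%)\n", x$n_A_coloc, x$n_A,
              100 * x$frac_A_coloc))
  cat(sprintf("  B: %d/%d colocalized (%.1f%%)\n", x$n_B_coloc, x$n_B,
              100 * x$frac_B_coloc))
  invisible(x)
}

spot_positions <- function(s) {
  if (is.matrix(s)) return(s)
  as.matrix(s[, c("z_um", "y_um", "x_um")])
}

#' Spot-spot colocalization by center distance
#'
#' A spot in A is colocalized iff its nearest B-spot center is strictly
#' closer than `threshold_um`; computed symmetrically for B. Each spot is
#' counted once.
#'
#' @param set_A,set_B `spot_set` data frames (or plain matrices of
#'   `(z, y, x)` positions in um).
#' @param threshold_um center-to-center threshold (default 0.2 um).
#' @return a `colocalization_result`.
#' @export
colocalize_spots <- function(set_A, set_B, threshold_um = 0.2) {
  A <- spot_positions(set_A)
  B <- spot_positions(set_B)
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0 || nB == 0)
    return(new_coloc_result(nA, nB, 0L, 0L, threshold_um, "spot_spot"))
  # block the pairwise computation to keep memory bounded
  nnA <- rep(Inf, nA)
  nnB <- rep(Inf, nB)
  bs <- 2000L
  for (i0 in seq(1, nA, bs)) {
    i1 <- min(i0 + bs - 1, nA)
    d2 <- outer(rowSums(A[i0:i1, , drop = FALSE]^2), rowSums(B^2), `+`) -
      2 * A[i0:i1, , drop = FALSE] %*% t(B)
    d2[d2 < 0] <- 0
    nnA[i0:i1] <- sqrt(apply(d2, 1, min))
    nnB <- pmin(nnB, sqrt(apply(d2, 2, min)))
  }
  new_coloc_result(nA, nB, sum(nnA < threshold_um), sum(nnB < threshold_um),
                   threshold_um, "spot_spot")
}

#' Spot-surface colocalization by surface-to-center distance
#'
#' A spot is colocalized iff the signed distance from the nearest
#' condensate surface to its center is strictly less than `threshold_um`
#' (a spot inside a surface has negative distance and always counts).
#' On the B side, a condensate is colocalized iff at least one spot lies
#' within the threshold of its surface.
#'
#' @param spots a `spot_set`.
#' @param cset a `condensate_set`.
#' @param threshold_um surface-to-center threshold (default 0.1 um).
#' @return a `colocalization_result` with per-spot distances attached as
#'   attribute `"spot_distance_um"`.
#' @export
colocalize_spot_surface <- function(spots, cset, threshold_um = 0.1) {
  P <- spot_positions(spots)
  nS <- nrow(P)
  nC <- nrow(cset$objects)
  if (nS == 0 || nC == 0)
    return(new_coloc_result(nS, nC, 0L, 0L, threshold_um, "spot_surface"))
  h <- cset$voxel_size_um
  dims <- dim(cset$labels)
  mask <- cset$labels > 0
  ed <- cpp_edt3d(as.vector(mask), dims, h)
  vox <- pmin(pmax(round(sweep(P, 2, h, `/`) + 0.5), 1),
              matrix(rep(dims, each = nS), ncol = 3))
  dist_um <- numeric(nS)
  near_id <- integer(nS)
  for (i in seq_len(nS)) {
    vz <- vox[i, 1]; vy <- vox[i, 2]; vx <- vox[i, 3]
    if (mask[vz, vy, vx]) {
      # inside a surface: negative distance (depth to the boundary)
      inn <- nearest_boundary_depth(mask, vox[i, ], P[i, ], h)
      dist_um[i] <- -inn
      near_id[i] <- cset$labels[vz, vy, vx]
    } else {
      f <- ed$feature[vz, vy, vx] + 1L
      fidx <- arrayInd(f, dims)
      # refine over a small neighbourhood of candidate surface voxels
      dist_um[i] <- point_box_distance(P[i, ], voxel_centers_um(fidx, h), h)
      near_id[i] <- cset$labels[f]
    }
  }
  coloc <- dist_um < threshold_um
  nBc <- length(unique(near_id[coloc]))
  res <- new_coloc_result(nS, nC, sum(coloc), nBc, threshold_um,
                          "spot_surface")
  attr(res, "spot_distance_um") <- dist_um
  attr(res, "nearest_id") <- near_id
  res
}

point_box_distance <- function(p, box_center, h) {
  g <- pmax(abs(p - as.numeric(box_center)) - h / 2, 0)
  sqrt(sum(g^2))
}

# depth of a point inside the mask: distance to the nearest outside voxel
# box (0 if the containing voxel touches the boundary)
nearest_boundary_depth <- function(mask, vox, p, h) {
  d <- dim(mask)
  r <- 3L
  zr <- max(1, vox[1] - r):min(d[1], vox[1] + r)
  yr <- max(1, vox[2] - r):min(d[2], vox[2] + r)
  xr <- max(1, vox[3] - r):min(d[3], vox[3] + r)
  g <- as.matrix(expand.grid(z = zr, y = yr, x = xr))
  out <- g[!mask[g], , drop = FALSE]
  if (nrow(out) == 0) return(r * min(h))  # deep inside; depth is a floor
  min(vapply(seq_len(nrow(out)), function(i)
    point_box_distance(p, voxel_centers_um(out[i, , drop = FALSE], h), h),
    numeric(1)))
}

#' 5'/3' probe degradation directionality
#'
#' Interprets a 5'-vs-3' spot-spot colocalization as a transcript decay
#' readout: colocalized pairs are intact transcripts, orphan 5' spots are
#' 3'->5' decay intermediates, orphan 3' spots are 5'->3' intermediates.
#' Reports both per-direction colocalized fractions (A-in-B and B-in-A) and
#' the transcript-level fractions (intact / orphan5 / orphan3 summing to 1,
#' with the intact count estimated symmetrically from both channels).
#'
#' @param coloc a `colocalization_result` from [colocalize_spots()] where
#'   A is the 5' channel and B the 3' channel.
#' @return a list of class `decay_result`: `frac_intact`, `frac_orphan5`,
#'   `frac_orphan3`, `frac_intact_5with3`, `frac_intact_3with5`,
#'   `dominant_pathway` (`"3to5"` when orphan 5' spots dominate).
#' @export
degradation_directionality <- function(coloc) {
  stopifnot(inherits(coloc, "colocalization_result"))
  n5 <- coloc$n_A
  n3 <- coloc$n_B
  if (n5 == 0 || n3 == 0) {
    warning("a probe channel has zero spots; decay fractions undefined")
    return(structure(list(frac_intact = NA_real_, frac_orphan5 = NA_real_,
                          frac_orphan3 = NA_real_,
                          frac_intact_5with3 = NA_real_,
                          frac_intact_3with5 = NA_real_,
                          dominant_pathway = NA_character_),
                     class = "decay_result"))
  }
  intact <- (coloc$n_A_coloc + coloc$n_B_coloc) / 2
  total <- n5 + n3 - intact
  o5 <- n5 - intact   # 5' spots without a 3' partner
  o3 <- n3 - intact
  dom <- if (o5 > o3) "3to5" else if (o3 > o5) "5to3" else "balanced"
  structure(list(frac_intact = intact / total,
                 frac_orphan5 = o5 / total,
                 frac_orphan3 = o3 / total,
                 frac_intact_5with3 = coloc$frac_A_coloc,
                 frac_intact_3with5 = coloc$frac_B_coloc,
                 dominant_pathway = dom),
            class = "decay_result")
}

#' @export
print.decay_result <- function(x, ...) {
  cat(sprintf("<decay> intact %.1f%%, orphan5' %.1f%%, orphan3' %.1f%% (%s)\n",
              100 * x$frac_intact, 100 * x$frac_orphan5,
              100 * x$frac_orphan3,
              switch(x$dominant_pathway, "3to5" = "3'->5' dominant",
                     "5to3" = "5'->3' dominant", "balanced")))
  invisible(x)
}

#' Count condensates by association class before and after photobleaching
#'
#' Segments condensates independently in the pre- and post-bleach stacks,
#' restricts to the bleached ROI, classifies each by the <= 0 um rule
#' against the organelle field, and reports class counts plus the percent
#' difference between cytoplasmic and associated counts in the post image
#' (convention: relative to the associated count, i.e. "X% more cytoplasmic
#' condensates than associated"). The readout is object counts in the field
#' of view, not an intensity-recovery curve.
#'
#' @param pre_stack,post_stack [image_stack]s sharing geometry.
#' @param bleach_roi named list of `z_um`, `y_um`, `x_um` ranges.
#' @param ofield an `organelle_field` (segmented from either stack).
#' @param min_volume_um3 volume gate passed to segmentation.
#' @return list of class `frap_result`: `pre` and `post` count tables and
#'   `percent_more_cytoplasmic`.
#' @export
frap_recovery_counts <- function(pre_stack, post_stack, bleach_roi, ofield,
                                 min_volume_um3 = 0.05) {
  if (!identical(dim(pre_stack$data)[3:5], dim(post_stack$data)[3:5]))
    stop("pre and post stacks have different geometry")
  count_classes <- function(stack) {
    cs <- segment_condensates(stack, min_volume_um3 = min_volume_um3)
    cs <- assign_association(cs, ofield)
    o <- cs$objects
    if (nrow(o)) {
      r <- bleach_roi
      inroi <- o$z_um >= r$z_um[1] & o$z_um <= r$z_um[2] &
        o$y_um >= r$y_um[1] & o$y_um <= r$y_um[2] &
        o$x_um >= r$x_um[1] & o$x_um <= r$x_um[2]
      o <- o[inroi, , drop = FALSE]
    }
    c(associated = sum(o$assoc_class == "associated"),
      cytoplasmic = sum(o$assoc_class == "cytoplasmic"))
  }
  pre <- count_classes(pre_stack)
  if (sum(pre) == 0)
    warning("no condensates detected in the ROI pre-bleach")
  post <- count_classes(post_stack)
  pct <- if (post["associated"] > 0)
    percent_difference(post[["cytoplasmic"]], post[["associated"]],
                       reference = "second") else NA_real_
  structure(list(pre = pre, post = post,
                 percent_more_cytoplasmic = unname(pct)),
            class = "frap_result")
}

#' @export
print.frap_result <- function(x, ...) {
  cat("<frap> pre: ", paste(names(x$pre), x$pre, collapse = ", "), "\n")
  cat("       post:", paste(names(x$post), x$post, collapse = ", "), "\n")
  if (!is.na(x$percent_more_cytoplasmic))
    cat(sprintf("       %.0f%% more cytoplasmic than associated post-bleach\n",
                x$percent_more_cytoplasmic))
  invisible(x)
}
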