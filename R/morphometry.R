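#' Base of a spine
#'
#' The set of dendrite voxels 26-adjacent to at least one voxel of the
#' spine region: the spine's attachment footprint on the dendrite.  A
#' spine with an empty base is flagged detached and its neck features are
#' undefined.
#'
#' @param region n x 3 voxel matrix `(z, y, x)` of the spine region.
#' @param dendrite logical 3-D array marking dendrite voxels.
#' @return m x 3 voxel matrix (possibly 0-row).
#' @export
spine_base <- function(region, dendrite) {
  d <- dim(dendrite)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  nb <- region[rep(seq_len(nrow(region)), each = nrow(off)), , drop = FALSE] +
    off[rep(seq_len(nrow(off)), times = nrow(region)), , drop = FALSE]
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  nb <- nb[ok, , drop = FALSE]
  nb <- unique(nb)
  base <- nb[dendrite[nb], , drop = FALSE]
  colnames(base) <- c("z", "y", "x")
  base
}

#' Central base point
#'
#' Arithmetic centroid of the base voxels (a real-valued point).  For path
#' computations the centroid is snapped to the nearest voxel of the base
#' or region (physical distance; ties resolved in `(z, y, x)` order); the
#' unsnapped point is what feature tables report.
#'
#' @param base m x 3 voxel matrix from [spine_base()].
#' @return numeric length-3 centroid with the snap candidates available
#'   through `snap_to_voxel()`.
#' @export
central_base_point <- function(base) {
  if (!nrow(base)) stop("undefined landmark: empty base (detached spine)")
  colMeans(base)
}

# snap a real-valued (z,y,x) point to the nearest candidate voxel row;
# ties -> lexicographically smallest (z, y, x)
snap_to_voxel <- function(point, candidates, spacing) {
  dd <- sweep(candidates, 2, point)
  dist2 <- as.numeric((dd^2) %*% (spacing^2))
  best <- which(dist2 <= min(dist2) + 1e-12)
  cand <- candidates[best, , drop = FALSE]
  o <- order(cand[, 1], cand[, 2], cand[, 3])
  cand[o[1], ]
}

#' Locally deepest points
#'
#' Voxels of the region whose depth (FDT of the region in isolation) is
#' maximal over the `(2l+1)^3` neighbourhood intersected with the region;
#' `l = 2` suppresses noisy local maxima.  Plateaus qualify, so a uniform
#' filament returns every voxel.
#'
#' @param region n x 3 voxel matrix.
#' @param omega FDT map of the region in isolation (array).
#' @param l neighbourhood radius in voxels.
#' @return logical vector over the rows of `region`.
#' @export
locally_deepest_points <- function(region, omega, l = 2L) {
  d <- dim(omega)
  mask <- array(FALSE, d)
  mask[region] <- TRUE
  hp <- array(.cpp_local_maxima(as.numeric(omega), as.logical(mask),
                                as.integer(d), as.integer(l)), d)
  hp[region]
}

#' Center of the head
#'
#' The deepest of the locally deepest points; when several tie at the
#' maximal depth their centroid is taken and snapped to the nearest tied
#' voxel.
#'
#' @param hp m x 3 matrix of locally deepest voxels.
#' @param omega region FDT map.
#' @param spacing voxel spacing (um).
#' @return list with `point` (real-valued centroid) and `voxel` (snapped).
#' @export
center_of_head <- function(hp, omega, spacing) {
  depth <- omega[hp]
  tied <- hp[depth >= max(depth) - 1e-12, , drop = FALSE]
  point <- colMeans(tied)
  list(point = point, voxel = snap_to_voxel(point, tied, spacing))
}

#' Tip of a spine
#'
#' The region point farthest from the central base point in fuzzy geodesic
#' distance (unit membership on the region).  Ties are resolved by the
#' centroid of the tied set snapped to the nearest tied voxel.
#'
#' @param region n x 3 voxel matrix.
#' @param cbp_voxel snapped central base point.
#' @param shape volume dim.
#' @param spacing voxel spacing (um).
#' @return list with `point`, `voxel`, `distance_um` and `dist_map` (the
#'   geodesic distance of every region voxel from the central base point).
#' @export
spine_tip <- function(region, cbp_voxel, shape, spacing) {
  mask <- array(0, shape)
  mask[region] <- 1
  mask[rbind(cbp_voxel)] <- 1
  dist <- .cpp_geodesic(as.numeric(mask), as.integer(shape), spacing,
                        vox_to_idx(cbp_voxel, shape))
  dr <- dist[vox_to_idx(region, shape)]
  tied <- region[is.finite(dr) & dr >= max(dr[is.finite(dr)]) - 1e-9, , drop = FALSE]
  point <- colMeans(tied)
  vox <- snap_to_voxel(point, tied, spacing)
  list(point = point, voxel = vox, distance_um = max(dr[is.finite(dr)]),
       dist_map = array(dist, shape))
}

#' Central paths of a spine
#'
#' Base-to-head path `BH` from the snapped central base point to the head
#' centre, and head-to-tip path `HT` from the head centre to the tip, both
#' confined to the region plus the base voxels and computed as minimum
#' node-weight paths over the region FDT.
#'
#' Two weightings are available.  The default, `mode = "deep"`, uses the
#' medialness weight `max(omega) + step/2 - omega(p)` (with `step` the
#' minimal voxel size), so the path runs through the deepest voxels --- the
#' central path through the neck and head --- while the half-step offset
#' penalises detours.  `mode = "sum"` minimises the plain sum of the FDT
#' over path voxels; because many shallow surface voxels then cost less
#' than a few deep ones, such paths crawl along the region surface, which
#' distorts neck length and width readings; it is retained for
#' comparison.
#'
#' @param region,base voxel matrices.
#' @param omega region FDT map (with spacing attribute).
#' @param cbp_voxel,ch_voxel,tip_voxel snapped landmarks.
#' @param mode `"deep"` (central, default) or `"sum"` (plain depth sum).
#' @return list with `bh` and `ht` path results (see [min_weight_path()]).
#' @export
central_paths <- function(region, base, omega, cbp_voxel, ch_voxel, tip_voxel,
                          mode = c("deep", "sum")) {
  mode <- match.arg(mode)
  d <- dim(omega)
  sp <- attr(omega, "spacing")
  w <- if (mode == "deep") {
    structure(array(max(omega) + min(sp) / 2 - omega, d), spacing = sp)
  } else omega
  allowed <- array(FALSE, d)
  allowed[region] <- TRUE
  allowed[base] <- TRUE
  allowed[rbind(cbp_voxel)] <- TRUE
  bh <- min_weight_path(w, cbp_voxel, ch_voxel, allowed)
  in_region <- array(FALSE, d)
  in_region[region] <- TRUE
  ht <- min_weight_path(w, ch_voxel, tip_voxel, in_region)
  list(bh = bh, ht = ht)
}

#' Measure one spine region
#'
#' Computes the full landmark-and-feature record for a single segmented
#' spine: the region FDT (region alone, dendrite treated as background),
#' base, central base point, locally deepest points, head centre, tip,
#' central paths, and the derived features.  Width features are reported
#' as diameters (twice the FDT depth).
#'
#' Length features are measured as unit-membership geodesic distances
#' between the landmarks (base-to-head `BH`, head-to-tip `HT`): the
#' geodesic is the taut path, so lengths do not pick up the meandering a
#' depth-weighted walking path exhibits inside wide heads.  Neck length is
#' the base-to-head distance minus the head depth, clamped at zero; spine
#' length is the base-to-head plus head-to-tip distance.  Minimum neck
#' width is taken along the explicit central path restricted to region
#' voxels, but measured on the FDT of the full foreground (region plus
#' dendrite): on the isolated-region map every voxel near the
#' spine/dendrite cut face has near-zero depth by construction, because
#' the cut face is treated as background even though it is not an
#' anatomical surface, and the neck-width reading would collapse to half
#' a voxel there.  Average head width averages the depth of the
#' significant locally deepest points (those within `depth_frac` of the
#' maximal depth, which suppresses shallow plateau maxima along the
#' neck).
#'
#' @param region n x 3 voxel matrix of the spine.
#' @param dendrite logical 3-D array of dendrite voxels.
#' @param spacing voxel size `(dz, dy, dx)` in micrometres.
#' @param l deepest-point neighbourhood radius (voxels).
#' @param depth_frac fraction of the maximal depth a locally deepest point
#'   must reach to count towards the head statistics.
#' @param path_mode central-path weighting, see [central_paths()].
#' @param omega_ref optional FDT of the full foreground object used for
#'   the neck-width reading; computed from `region` plus `dendrite` when
#'   `NULL` ([measure_spines()] shares one map across all spines).
#' @return a `spine_region` list with landmarks, paths and features.
#' @export
measure_spine <- function(region, dendrite, spacing, l = 2L, depth_frac = 0.6,
                          path_mode = c("deep", "sum"), omega_ref = NULL) {
  shape <- dim(dendrite)
  n <- nrow(region)
  mask <- array(0, shape)
  mask[region] <- 1
  omega <- structure(array(.cpp_fdt(as.numeric(mask), as.integer(shape), spacing),
                           shape), spacing = spacing)
  if (is.null(omega_ref)) {
    comb <- mask
    comb[dendrite] <- 1
    omega_ref <- array(.cpp_fdt(as.numeric(comb), as.integer(shape), spacing),
                       shape)
  }
  vol_um3 <- n * prod(spacing)

  base <- spine_base(region, dendrite)
  detached <- nrow(base) == 0L

  hp_flag <- locally_deepest_points(region, omega, l = l)
  hp <- region[hp_flag, , drop = FALSE]
  ch <- center_of_head(hp, omega, spacing)
  head_depth <- omega[rbind(ch$voxel)]
  hp_sig <- hp[omega[hp] >= depth_frac * head_depth - 1e-12, , drop = FALSE]
  ahw <- 2 * mean(omega[hp_sig])

  out <- list(region = region, omega = omega, omega_ref = omega_ref,
              base = base,
              n_voxels = n, volume_um3 = vol_um3,
              hp = hp, hp_sig = hp_sig, ch = ch,
              head_depth_um = head_depth, avg_head_width_um = ahw,
              detached = detached, spacing = spacing, shape = shape)
  class(out) <- "spine_region"
  if (detached) {
    out$neck_length_um <- NA_real_
    out$min_neck_width_um <- NA_real_
    out$spine_length_um <- NA_real_
    return(out)
  }

  cbp_point <- central_base_point(base)
  cbp_voxel <- snap_to_voxel(cbp_point, rbind(base, region), spacing)
  # geodesic position of every region voxel relative to the central base
  # point: tip, base-to-head distance and the spread statistic read off it
  tip <- spine_tip(region, cbp_voxel, shape, spacing)
  bh_len <- tip$dist_map[rbind(ch$voxel)]
  mask_num <- array(0, shape)
  mask_num[region] <- 1
  d_ch <- .cpp_geodesic(as.numeric(mask_num), as.integer(shape), spacing,
                        vox_to_idx(ch$voxel, shape))
  ht_len <- d_ch[vox_to_idx(tip$voxel, shape)]

  paths <- central_paths(region, base, omega, cbp_voxel, ch$voxel, tip$voxel,
                         mode = path_mode)
  in_region <- array(FALSE, shape)
  in_region[region] <- TRUE
  on_bh <- paths$bh$path[in_region[paths$bh$path], , drop = FALSE]
  mnw <- if (nrow(on_bh)) 2 * min(omega_ref[on_bh]) else NA_real_

  nl_raw <- bh_len - head_depth
  out$cbp <- list(point = cbp_point, voxel = cbp_voxel)
  out$tip <- tip
  out$bh <- paths$bh
  out$ht <- paths$ht
  out$hp_sig_pos <- tip$dist_map[vox_to_idx(hp_sig, shape)]
  out$bh_length_um <- bh_len
  out$ht_length_um <- ht_len
  out$neck_length_raw_um <- nl_raw
  out$neck_length_um <- max(0, nl_raw)
  out$min_neck_width_um <- mnw
  out$spine_length_um <- bh_len + ht_len
  out
}

#' @export
print.spine_region <- function(x, ...) {
  cat(sprintf("<spine_region> %d voxels, volume %.3g um^3%s\n", x$n_voxels,
              x$volume_um3, if (x$detached) " [detached]" else ""))
  if (!x$detached)
    cat(sprintf("  NL %.3g um, MNW %.3g um, AHW %.3g um, L %.3g um\n",
                x$neck_length_um, x$min_neck_width_um,
                x$avg_head_width_um, x$spine_length_um))
  invisible(x)
}

#' Measure all spines of a segmentation
#'
#' @param seg segmentation from [extract_spine_components()].
#' @param l,depth_frac,path_mode see [measure_spine()].
#' @return list of `spine_region` records, one per region.
#' @export
measure_spines <- function(seg, l = 2L, depth_frac = 0.6,
                           path_mode = c("deep", "sum")) {
  dendrite <- seg$labels == 1L
  shape <- dim(seg$labels)
  omega_ref <- array(.cpp_fdt(as.numeric(seg$labels > 0L), as.integer(shape),
                              seg$spacing), shape)
  lapply(seg$regions, measure_spine, dendrite = dendrite,
         spacing = seg$spacing, l = l, depth_frac = depth_frac,
         path_mode = path_mode, omega_ref = omega_ref)
}
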