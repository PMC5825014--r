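#' Default classification thresholds
#'
#' Tunable parameters of the rule cascade, all exposed so a decision trace
#' can reproduce any label.
#'
#' * `tau_stubby` (um): a measured neck length at or below this value is
#'   treated as zero (a neck shorter than the coarsest sampling step ---
#'   one 0.2 um axial step at typical confocal settings --- is below
#'   measurement resolution) and the spine is stubby.
#' * `tau_spread` (dimensionless): minimum spread of the significant
#'   locally deepest points along the central path, as a fraction of the
#'   spine length, for a filopodium.
#' * `tau_ratio` (dimensionless): maximum base-to-head over total length
#'   ratio for a mushroom; larger ratios are spine-head protrusions.
#'   Since the tip lies about one head radius beyond the head centre, the
#'   ratio is near `(n + r) / (n + 2r)` for neck length `n` and head
#'   radius `r`: short-necked mushrooms sit a little above one half, and
#'   the ratio grows towards one with neck length.  The default is
#'   calibrated on the phantom suite, where the two populations separate
#'   at about 0.65.
#' * `tau_branch` (dimensionless): a locally deepest cluster counts as a
#'   separate head if its depth exceeds `tau_branch` times the depth of
#'   the narrowest point on its path to the base (a bulge test).
#'
#' @return named list of thresholds.
#' @export
classify_defaults <- function() {
  list(tau_stubby = 0.2, tau_spread = 0.6, tau_ratio = 0.65, tau_branch = 1.5)
}

#' Spread of the deepest points along the spine
#'
#' The significant locally deepest points are located by their geodesic
#' distance from the central base point (their position along the spine
#' axis); the statistic is the extent of those positions divided by the
#' spine length.  A single deepest point gives 0; a uniform filament,
#' whose deepest points cover its whole axis, gives a value near 1.
#' Heads concentrate the deepest points, so mushrooms and spine-head
#' protrusions score low.
#'
#' @param spine a `spine_region` from [measure_spine()].
#' @return statistic in `[0, 1]`.
#' @export
deepest_point_spread <- function(spine) {
  if (spine$detached || is.na(spine$spine_length_um) ||
      spine$spine_length_um <= 0) return(0)
  pos <- spine$hp_sig_pos
  pos <- pos[is.finite(pos)]
  if (length(pos) < 2L) return(0)
  min(1, (max(pos) - min(pos)) / spine$spine_length_um)
}

#' Detect branched (bifurcated) spines
#'
#' A spine is branched when it carries at least two distinct heads.  The
#' significant locally deepest points are clustered by 26-connectivity;
#' each cluster's deepest voxel is a head candidate if it is a true bulge
#' (its depth exceeds `tau_branch` times the minimum depth along its
#' base-to-cluster path outside the head ball) and it is geodesically
#' separated from every already-accepted head by more than the sum of the
#' two depths.  Bulge depths are read from the full-foreground FDT (see
#' [measure_spine()]): near the base the isolated-region map is zeroed by
#' the artificial spine/dendrite cut face, which would make every path
#' look like a neck.  Branched spines bypass the four-way classification
#' and are only flagged.
#'
#' @param spine a `spine_region`.
#' @param tau_branch bulge threshold, see [classify_defaults()].
#' @return logical.
#' @export
flag_branched <- function(spine, tau_branch = classify_defaults()$tau_branch) {
  if (spine$detached) return(FALSE)
  shape <- spine$shape
  sp <- spine$spacing
  omega <- spine$omega
  omega_ref <- if (is.null(spine$omega_ref)) omega else spine$omega_ref
  hp_mask <- array(FALSE, shape)
  hp_mask[spine$hp_sig] <- TRUE
  comp <- array(.cpp_label_components(as.logical(hp_mask), as.integer(shape)),
                shape)
  ids <- sort(unique(comp[comp > 0]))
  if (length(ids) < 2L) return(FALSE)
  # deepest voxel of each cluster, deepest clusters first
  heads <- t(vapply(ids, function(k) {
    vox <- which(comp == k, arr.ind = TRUE)
    vox[which.max(omega[vox]), ]
  }, numeric(3)))
  depth <- omega[heads]
  o <- order(-depth)
  heads <- heads[o, , drop = FALSE]
  depth <- depth[o]

  allowed <- array(FALSE, shape)
  allowed[spine$region] <- TRUE
  allowed[spine$base] <- TRUE
  allowed[rbind(spine$cbp$voxel)] <- TRUE
  in_region <- array(FALSE, shape)
  in_region[spine$region] <- TRUE

  mask_num <- array(0, shape)
  mask_num[spine$region] <- 1
  w <- structure(array(max(omega) + min(sp) / 2 - omega, shape), spacing = sp)

  accepted <- matrix(numeric(0), 0, 3)
  acc_depth <- numeric(0)
  for (i in seq_len(nrow(heads))) {
    h <- heads[i, ]
    p <- tryCatch(min_weight_path(w, spine$cbp$voxel, h, allowed),
                  error = function(e) NULL)
    if (is.null(p)) next
    on <- p$path[in_region[p$path], , drop = FALSE]
    if (!nrow(on)) next
    phys <- sqrt(as.numeric(sweep(on, 2, h)^2 %*% (sp^2)))
    neck <- on[phys > omega_ref[rbind(h)] + 1e-9, , drop = FALSE]
    if (!nrow(neck)) next
    if (omega_ref[rbind(h)] < tau_branch * min(omega_ref[neck])) next
    if (nrow(accepted)) {
      geo <- .cpp_geodesic(as.numeric(mask_num), as.integer(shape), sp,
                           vox_to_idx(h, shape))
      sep <- vapply(seq_len(nrow(accepted)), function(j) {
        geo[vox_to_idx(accepted[j, ], shape)] >
          omega[rbind(h)] + acc_depth[j] + 1e-9
      }, logical(1))
      if (!all(sep)) next
    }
    accepted <- rbind(accepted, h)
    acc_depth <- c(acc_depth, omega[rbind(h)])
    if (nrow(accepted) >= 2L) return(TRUE)
  }
  FALSE
}

#' Classify one spine
#'
#' Rule cascade in fixed order: (1) zero neck length (below `tau_stubby`)
#' is a stubby spine; (2) deepest points spread along the length beyond
#' `tau_spread` is a filopodium; (3) base-to-head distance short relative
#' to the spine length (ratio at most `tau_ratio`) is a mushroom;
#' (4) otherwise a spine-head protrusion.  Detached or branched spines
#' bypass the cascade.  The decision trace records every statistic and
#' threshold so the label can be reproduced.
#'
#' @param spine a `spine_region`.
#' @param thresholds named list, see [classify_defaults()].
#' @param branched logical from [flag_branched()] (computed if `NULL`).
#' @return a `spine_class` list: `label`, `branched`, `trace`.
#' @export
classify_spine <- function(spine, thresholds = classify_defaults(),
                           branched = NULL) {
  th <- utils::modifyList(classify_defaults(), thresholds)
  if (spine$detached) {
    return(structure(list(label = NA_character_, branched = FALSE,
                          trace = list(rule = "detached", thresholds = th)),
                     class = "spine_class"))
  }
  if (is.null(branched)) branched <- flag_branched(spine, th$tau_branch)
  spread <- deepest_point_spread(spine)
  ratio <- spine$bh_length_um / spine$spine_length_um
  tr <- list(neck_length_um = spine$neck_length_um, spread = spread,
             bh_over_l = ratio, thresholds = th)
  if (branched) {
    tr$rule <- "branched"
    return(structure(list(label = NA_character_, branched = TRUE, trace = tr),
                     class = "spine_class"))
  }
  if (spine$neck_length_um <= th$tau_stubby) {
    tr$rule <- "neck-length-zero"
    label <- "Stubby"
  } else if (spread >= th$tau_spread) {
    tr$rule <- "deepest-points-spread"
    label <- "Filopodia"
  } else if (ratio <= th$tau_ratio) {
    tr$rule <- "short-base-to-head"
    label <- "Mushroom"
  } else {
    tr$rule <- "default"
    label <- "SpineHeadProtrusion"
  }
  structure(list(label = label, branched = FALSE, trace = tr),
            class = "spine_class")
}

#' @export
print.spine_class <- function(x, ...) {
  cat(sprintf("<spine_class> %s (rule: %s)\n",
              if (is.na(x$label)) if (x$branched) "branched" else "unclassified"
              else x$label, x$trace$rule))
  invisible(x)
}

#' Feature table with classification for a list of spines
#'
#' @param spines list of `spine_region` records from [measure_spines()].
#' @param thresholds see [classify_defaults()].
#' @return `data.frame`, one row per spine, with features, class label,
#'   flags and 0-based landmark coordinates (file/CSV convention).
#' @export
classify_spines <- function(spines, thresholds = classify_defaults()) {
  if (!length(spines)) return(empty_feature_table())
  rows <- lapply(seq_along(spines), function(i) {
    s <- spines[[i]]
    cl <- classify_spine(s, thresholds)
    pt0 <- function(p) if (is.null(p)) c(NA_real_, NA_real_, NA_real_) else p - 1
    data.frame(spine_id = i, n_voxels = s$n_voxels, volume_um3 = s$volume_um3,
               neck_length_um = s$neck_length_um,
               min_neck_width_um = s$min_neck_width_um,
               avg_head_width_um = s$avg_head_width_um,
               head_depth_um = s$head_depth_um,
               spine_length_um = s$spine_length_um,
               bh_length_um = if (s$detached) NA_real_ else s$bh_length_um,
               spread = if (s$detached) NA_real_ else cl$trace$spread,
               class = if (is.na(cl$label)) "" else cl$label,
               detached = s$detached, branched = cl$branched,
               rule = cl$trace$rule,
               cbp_z = pt0(s$cbp$point)[1], cbp_y = pt0(s$cbp$point)[2],
               cbp_x = pt0(s$cbp$point)[3],
               ch_z = pt0(s$ch$point)[1], ch_y = pt0(s$ch$point)[2],
               ch_x = pt0(s$ch$point)[3],
               tip_z = pt0(s$tip$point)[1], tip_y = pt0(s$tip$point)[2],
               tip_x = pt0(s$tip$point)[3])
  })
  do.call(rbind, rows)
}
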