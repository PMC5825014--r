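#' Foreground extraction by thresholding and connectivity analysis
#'
#' Step one of the segmentation: voxels with intensity at or above `theta`
#' form the combined spine-plus-dendrite object; 26-connected components
#' smaller than `min_voxels` are discarded as noise.  The membership of
#' the retained support is the fuzzy union of the spine and dendrite
#' memberships when `bands` are supplied, otherwise 1 (binary object).
#'
#' @param vol `spine_volume`.
#' @param theta intensity threshold; `"otsu"` for an automatic single
#'   Otsu threshold on the full volume; or `"otsu2"` (the default used by
#'   the pipeline) for the lower of a two-level Otsu, which separates the
#'   background from the dim spine band when the histogram is trimodal
#'   (background / spine / dendrite) rather than merging dim spines into
#'   the background.
#' @param min_voxels minimum component size kept.
#' @param bands optional [intensity_bands()] used to build the fuzzy
#'   membership of the retained support.
#' @return a [fuzzy_object()] whose support is the cleaned foreground.
#' @export
threshold_foreground <- function(vol, theta = "otsu2", min_voxels = 27L,
                                 bands = NULL) {
  d <- dim(vol)
  if (identical(theta, "otsu")) theta <- otsu_thresholds(vol, k = 1L)
  else if (identical(theta, "otsu2")) theta <- otsu_thresholds(vol, k = 2L)[1]
  fg <- unclass(vol) >= theta
  if (!any(fg)) stop("empty foreground: no voxel reaches theta = ", signif(theta, 4))
  lab <- array(.cpp_label_components(as.logical(fg), as.integer(d)), d)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  fg <- array(lab %in% keep, d)
  if (!any(fg)) stop("empty foreground: all components smaller than min_voxels")
  mu <- array(0, d)
  if (is.null(bands)) {
    mu[fg] <- 1
  } else {
    i <- unclass(vol)[fg]
    mu[fg] <- pmax(membership_spine(i, bands), membership_dendrite(i, bands))
    mu[fg] <- pmax(mu[fg], 1e-6)  # support must stay exactly the threshold set
  }
  obj <- fuzzy_object(mu, spacing(vol))
  attr(obj, "theta") <- theta
  obj
}

#' Multi-scale opening of fused spine and dendrite objects
#'
#' Seeded separation of two mutually fused fuzzy objects.  Initial depth
#' maps are computed for each object from the composite membership with
#' the rival's seeds and all separators added to the background
#' (`omega_spine0`, `omega_dendrite0`).  The two objects then grow from
#' their seeds across descending scales: at scale `s` each object claims
#' the unclaimed voxels whose own initial depth is at least `s`, so
#' large-scale cores are claimed first and fine peripheral detail last.
#' Within a scale the two objects race by fuzzy geodesic distance from
#' their already-claimed sets (competitive multi-source propagation); a
#' voxel goes to the first-arriving object, and on an exact distance tie
#' to the object whose seed set is geodesically nearer (full ties to the
#' dendrite).  Voxels that remain
#' unclaimed after the final scale (separator-isolated, and the separator
#' voxels themselves) are assigned to the dendrite and counted.
#'
#' @param obj composite [fuzzy_object()] from [threshold_foreground()].
#' @param seeds a [seed_set()]; spine and dendrite seeds must be non-empty
#'   and inside the support.
#' @param intensity optional intensity volume; with `bands` it pre-claims
#'   the pure dendrite band (intensities at or above the dendrite level
#'   are unambiguous) before growth starts.
#' @param bands optional [intensity_bands()], see `intensity`.
#' @param scale_step scale decrement in micrometres; default one minimal
#'   voxel step.
#' @return a `segmentation` object: `labels` (0 background, 1 dendrite,
#'   2 spine), per-object initial FDT maps, seed distances, and the count
#'   of voxels force-assigned to the dendrite.
#' @export
multi_scale_opening <- function(obj, seeds, intensity = NULL, bands = NULL,
                                scale_step = NULL) {
  d <- dim(obj$mu)
  if (!nrow(seeds$spine) || !nrow(seeds$dendrite))
    stop("both spine and dendrite seed sets must be non-empty")
  i_sp <- vox_to_idx(seeds$spine, d)
  i_de <- vox_to_idx(seeds$dendrite, d)
  i_se <- if (nrow(seeds$separator)) vox_to_idx(seeds$separator, d) else integer(0)
  if (any(obj$mu[c(i_sp, i_de)] <= 0))
    stop("all spine and dendrite seeds must lie inside the support")
  if (is.null(scale_step)) scale_step <- min(obj$spacing)

  mu <- as.numeric(obj$mu)
  # rival-suppressed membership fields for the initial FDT maps
  mu_s <- mu; mu_s[c(i_de, i_se)] <- 0
  mu_d <- mu; mu_d[c(i_sp, i_se)] <- 0
  om_s <- .cpp_fdt(mu_s, as.integer(d), obj$spacing)
  om_d <- .cpp_fdt(mu_d, as.integer(d), obj$spacing)
  dist_s <- .cpp_geodesic(mu_s, as.integer(d), obj$spacing, i_sp)
  dist_d <- .cpp_geodesic(mu_d, as.integer(d), obj$spacing, i_de)

  init <- integer(prod(d))
  init[mu <= 0] <- -1L
  if (!is.null(intensity) && !is.null(bands)) {
    pure_d <- mu > 0 & as.numeric(intensity) >= bands$i_dendrite
    init[pure_d] <- 1L
  }
  init[i_de] <- 1L
  init[i_sp] <- 2L
  init[i_se] <- 3L

  res <- .cpp_mso_grow(om_s, om_d, init, dist_s, dist_d, mu,
                       as.integer(d), obj$spacing, scale_step)
  labels <- array(0L, d)
  labels[res$labels == 1L] <- 1L
  labels[res$labels == 2L] <- 2L
  if (res$n_forced > 0)
    message(res$n_forced, " unclaimed voxel(s) assigned to the dendrite")
  structure(list(labels = labels,
                 omega_spine0 = array(om_s, d),
                 omega_dendrite0 = array(om_d, d),
                 seeds = seeds,
                 spacing = obj$spacing,
                 n_forced = res$n_forced),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %s voxels: %d dendrite, %d spine%s\n",
              paste(dim(x$labels), collapse = " x "),
              sum(x$labels == 1L), sum(x$labels > 1L),
              if (!is.null(x$K)) sprintf(" in %d region(s)", x$K) else ""))
  invisible(x)
}

#' Extract connected spine regions
#'
#' Decomposes the spine-labelled voxels into 26-connected components.
#' Components that contain no spine seed are merged back into the
#' dendrite (with a message), so every returned region holds at least one
#' seed and the dendrite/spine labels still partition the support.
#' Region labels in the updated volume are `1 + i` for region `i`.
#'
#' @param seg a `segmentation` from [multi_scale_opening()].
#' @return the segmentation with `K`, `regions` (list of n x 3 voxel
#'   matrices) and relabelled `labels` added.
#' @export
extract_spine_components <- function(seg) {
  d <- dim(seg$labels)
  comp <- array(.cpp_label_components(as.logical(seg$labels == 2L),
                                      as.integer(d)), d)
  seed_idx <- vox_to_idx(seg$seeds$spine, d)
  seeded <- sort(unique(comp[seed_idx]))
  seeded <- seeded[seeded > 0]
  stray <- setdiff(unique(comp[comp > 0]), seeded)
  if (length(stray)) {
    message(length(stray), " unseeded spine component(s) merged into the dendrite")
    seg$labels[comp %in% stray] <- 1L
  }
  labels <- seg$labels
  regions <- vector("list", length(seeded))
  for (i in seq_along(seeded)) {
    vox <- which(comp == seeded[i], arr.ind = TRUE)
    colnames(vox) <- c("z", "y", "x")
    regions[[i]] <- vox
    labels[comp == seeded[i]] <- 1L + i
  }
  seg$K <- length(seeded)
  seg$regions <- regions
  seg$labels <- labels
  seg
}
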