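#' Fuzzy objects
#'
#' A fuzzy object is a per-voxel membership map \eqn{\mu \in [0,1]} over a
#' 3-D grid; its support is the set of voxels with non-zero membership and
#' everything else (including space outside the array) is background.
#'
#' @param membership numeric 3-D array in `[0, 1]`, `(z, y, x)`.
#' @param spacing voxel size `(dz, dy, dx)` in micrometres.
#' @return a `fuzzy_object`.
#' @export
fuzzy_object <- function(membership, spacing = c(1, 1, 1)) {
  if (length(dim(membership)) != 3L) stop("`membership` must be a 3-D array")
  check_spacing(spacing)
  if (min(membership) < 0 || max(membership) > 1)
    stop("membership values must lie in [0, 1]")
  structure(list(mu = membership, spacing = as.numeric(spacing)),
            class = "fuzzy_object")
}

#' @export
print.fuzzy_object <- function(x, ...) {
  cat(sprintf("<fuzzy_object> %s voxels, support %d, spacing %s um\n",
              paste(dim(x$mu), collapse = " x "), sum(x$mu > 0),
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

# 1-based (z,y,x) matrix -> 1-based linear indices for dim d
vox_to_idx <- function(m, d) {
  m <- rbind(m)
  as.integer(m[, 1] + d[1] * ((m[, 2] - 1) + d[2] * (m[, 3] - 1)))
}

idx_to_vox <- function(i, d) {
  i0 <- i - 1L
  z <- i0 %% d[1]
  r <- i0 %/% d[1]
  cbind(z = z + 1L, y = r %% d[2] + 1L, x = r %/% d[2] + 1L)
}

is_adjacent26 <- function(p, q) {
  dd <- abs(p - q)
  all(dd <= 1) && any(dd > 0)
}

#' Length of a single link between adjacent voxels
#'
#' The link from `p` to `q` has length
#' \eqn{\tfrac{1}{2}(\mu(p)+\mu(q))\,\|p-q\|}, where the Euclidean step
#' \eqn{\|p-q\|} is measured in physical units using the anisotropic voxel
#' spacing.  Path lengths are sums of link lengths.
#'
#' @param p,q integer voxel coordinates `(z, y, x)`, 26-adjacent.
#' @param obj a [fuzzy_object()].
#' @return link length in micrometres.
#' @export
link_length <- function(p, q, obj) {
  if (!is_adjacent26(p, q)) stop("p and q must be distinct 26-adjacent voxels")
  step <- sqrt(sum(((p - q) * obj$spacing)^2))
  0.5 * (obj$mu[rbind(p)] + obj$mu[rbind(q)]) * step
}

#' Fuzzy distance between two voxels
#'
#' Length of the shortest membership-weighted 26-connected path between
#' two support voxels.  Voxels in different connected components of the
#' support have no path; `Inf` is returned.
#'
#' @inheritParams link_length
#' @return distance in micrometres (`Inf` if unreachable).
#' @export
fuzzy_distance <- function(p, q, obj) {
  d <- dim(obj$mu)
  ip <- vox_to_idx(p, d); iq <- vox_to_idx(q, d)
  if (obj$mu[ip] <= 0 || obj$mu[iq] <= 0)
    stop("both voxels must lie in the support")
  dist <- .cpp_geodesic(as.numeric(obj$mu), as.integer(d), obj$spacing, ip)
  dist[iq]
}

#' Fuzzy distance transform
#'
#' For every support voxel, the length of the shortest membership-weighted
#' path to the background (a depth map inside the fuzzy object).  The path
#' terminates with a half-link into the background: a support voxel facing
#' the background across a step of physical length \eqn{s} contributes
#' \eqn{\tfrac{1}{2}\mu(p)\,s} for that final link.  Space outside the
#' array counts as background.  Background voxels map to 0.
#'
#' @param obj a [fuzzy_object()].
#' @return an `fdt_map`: numeric array of distances (micrometres) with the
#'   spacing attached.
#' @export
fuzzy_distance_transform <- function(obj) {
  d <- dim(obj$mu)
  if (all(obj$mu <= 0)) {
    warning("empty support: fuzzy distance transform is identically zero")
    return(structure(array(0, d), spacing = obj$spacing,
                     class = c("fdt_map", "array")))
  }
  om <- .cpp_fdt(as.numeric(obj$mu), as.integer(d), obj$spacing)
  structure(array(om, d), spacing = obj$spacing, class = c("fdt_map", "array"))
}

#' @export
print.fdt_map <- function(x, ...) {
  cat(sprintf("<fdt_map> %s voxels, max depth %.4g um\n",
              paste(dim(x), collapse = " x "), max(x)))
  invisible(x)
}

#' Intensity bands for the two-object membership model
#'
#' Intensities below `i_spine` are pure spine, at or above `i_dendrite`
#' pure dendrite, and the interval between them is the shared band where
#' the two memberships ramp linearly and sum to one.
#'
#' @param i_min,i_max observed intensity range.
#' @param i_spine,i_dendrite representative spine and dendrite
#'   intensities, `i_min <= i_spine < i_dendrite <= i_max`.
#' @return an `intensity_bands` object.
#' @export
intensity_bands <- function(i_min, i_spine, i_dendrite, i_max) {
  if (!(i_min <= i_spine && i_spine < i_dendrite && i_dendrite <= i_max))
    stop("bands must satisfy i_min <= i_spine < i_dendrite <= i_max")
  structure(list(i_min = i_min, i_spine = i_spine,
                 i_dendrite = i_dendrite, i_max = i_max),
            class = "intensity_bands")
}

#' @export
print.intensity_bands <- function(x, ...) {
  cat(sprintf("<intensity_bands> pure spine [%g, %g), shared [%g, %g), pure dendrite [%g, %g]\n",
              x$i_min, x$i_spine, x$i_spine, x$i_dendrite, x$i_dendrite, x$i_max))
  invisible(x)
}

#' Dendrite membership from intensity
#'
#' Zero below the spine band limit, a linear ramp across the shared band,
#' one at and above the dendrite intensity.
#'
#' @param intensity numeric vector/array of intensities.
#' @param bands an [intensity_bands()].
#' @return memberships in `[0, 1]`, same shape as `intensity`.
#' @export
membership_dendrite <- function(intensity, bands) {
  mu <- (intensity - bands$i_spine) / (bands$i_dendrite - bands$i_spine)
  mu[intensity < bands$i_spine] <- 0
  mu[intensity >= bands$i_dendrite] <- 1
  mu
}

#' Spine membership from intensity
#'
#' One on the pure spine band, the complementary ramp across the shared
#' band, zero below `i_min` and at or above the dendrite intensity.
#'
#' @inheritParams membership_dendrite
#' @export
membership_spine <- function(intensity, bands) {
  mu <- (bands$i_dendrite - intensity) / (bands$i_dendrite - bands$i_spine)
  mu[intensity < bands$i_spine] <- 1
  mu[intensity < bands$i_min] <- 0
  mu[intensity >= bands$i_dendrite] <- 0
  mu
}

#' Fuzzy union of two objects
#'
#' Voxelwise maximum of the membership maps; the composite object used by
#' the opening algorithm.
#'
#' @param a,b [fuzzy_object()]s of identical shape and spacing.
#' @export
fuzzy_union <- function(a, b) {
  if (!identical(dim(a$mu), dim(b$mu)) || !identical(a$spacing, b$spacing))
    stop("objects must share shape and spacing")
  fuzzy_object(pmax(a$mu, b$mu), a$spacing)
}

#' Minimum node-weight path between two voxels
#'
#' Among all 26-connected paths inside `region`, returns one minimising
#' the sum of `weight` over visited voxels (both endpoints counted once).
#' Ties are broken by fewer voxels, then by a fixed predecessor order, so
#' repeated calls return the same path.
#'
#' @param weight numeric 3-D array of node weights (an FDT map).
#' @param src,dst voxel coordinates `(z, y, x)`, inside `region`.
#' @param region logical 3-D array: voxels the path may visit.
#' @return list with `path` (n x 3 voxel matrix), `cost`, and `length_um`
#'   (physical path length using the spacing attached to `weight`, unit
#'   memberships).
#' @export
min_weight_path <- function(weight, src, dst, region) {
  d <- dim(weight)
  res <- .cpp_min_weight_path(as.numeric(weight), as.logical(region),
                              as.integer(d),
                              vox_to_idx(src, d), vox_to_idx(dst, d))
  if (!length(res$path)) stop("no path: endpoints are disconnected within the region")
  vox <- idx_to_vox(res$path, d)
  sp <- attr(weight, "spacing")
  len <- if (is.null(sp)) NA_real_ else path_physical_length(vox, sp)
  list(path = vox, cost = res$cost, length_um = len)
}

# physical length of a voxel path under unit membership (sum of step norms)
path_physical_length <- function(vox, spacing) {
  if (nrow(vox) < 2L) return(0)
  steps <- diff(vox) * rep(spacing, each = nrow(vox) - 1L)
  sum(sqrt(rowSums(steps^2)))
}

#' Otsu thresholds
#'
#' Histogram-based Otsu thresholding generalised to `k` thresholds
#' (exhaustive search over histogram bins maximising the between-class
#' variance).  With `k = 2` this picks the two band limits of a trimodal
#' foreground histogram.
#'
#' @param x numeric values.
#' @param k number of thresholds (1 or 2).
#' @param n_bins histogram resolution.
#' @return numeric vector of `k` thresholds (ascending).
#' @export
otsu_thresholds <- function(x, k = 1L, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rep(rng[1], k))
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- h / sum(h)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  # between-class variance of a bin range [a, b]: w * (mean - grand)^2
  seg <- function(a, b) {
    ww <- cw[b] - if (a > 1) cw[a - 1] else 0
    if (ww <= 0) return(0)
    mm <- (cm[b] - if (a > 1) cm[a - 1] else 0) / ww
    ww * mm^2
  }
  if (k == 1L) {
    best <- -Inf; tb <- 1L
    for (t in 1:(n_bins - 1L)) {
      v <- seg(1L, t) + seg(t + 1L, n_bins)
      if (v > best) { best <- v; tb <- t }
    }
    return(mids[tb])
  }
  if (k != 2L) stop("only k = 1 or k = 2 supported")
  best <- -Inf; t1b <- 1L; t2b <- 2L
  for (t1 in 1:(n_bins - 2L)) {
    s1 <- seg(1L, t1)
    for (t2 in (t1 + 1L):(n_bins - 1L)) {
      v <- s1 + seg(t1 + 1L, t2) + seg(t2 + 1L, n_bins)
      if (v > best) { best <- v; t1b <- t1; t2b <- t2 }
    }
  }
  c(mids[t1b], mids[t2b])
}

#' Automatic band selection
#'
#' Two-threshold Otsu on the foreground intensities: the lower threshold
#' becomes the spine band limit, the upper one the dendrite intensity.
#'
#' @param intensity numeric intensities of the foreground voxels.
#' @return an [intensity_bands()].
#' @export
auto_bands <- function(intensity) {
  t2 <- otsu_thresholds(intensity, k = 2L)
  intensity_bands(min(intensity), t2[1], t2[2], max(intensity))
}

#' Export an FDT map as a 32-bit float TIFF
#'
#' Depth values are stored in the `[0, 1]` range the float TIFF writer
#' supports; maps exceeding 1 um must be normalised by their maximum,
#' which is returned so values can be restored on read.
#'
#' @param map an `fdt_map`.
#' @param path output file.
#' @param normalize divide by `max(map)` before writing.
#' @return (invisibly) the scale factor that restores micrometres.
#' @export
write_fdt <- function(map, path, normalize = FALSE) {
  scale <- 1
  m <- unclass(map)
  if (normalize && max(m) > 0) {
    scale <- max(m)
    m <- m / scale
  }
  if (max(m) > 1)
    stop("depth values exceed 1; write with normalize = TRUE")
  pages <- lapply(seq_len(dim(m)[1]), function(z) m[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}
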