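#' Intensity volumes
#'
#' A `spine_volume` is a plain 3-D numeric array in `(z, y, x)` axis order
#' (z-slice first, matching multi-page TIFF ordering) carrying the physical
#' voxel spacing in micrometres as an attribute.  All coordinates handled
#' in R are 1-based; files on disk (seed CSVs, feature tables) use 0-based
#' coordinates, converted at the I/O boundary.
#'
#' @param data numeric 3-D array, `(z, y, x)`.
#' @param spacing numeric length-3, voxel size in micrometres per axis
#'   `(dz, dy, dx)`; all components must be positive.
#' @return `as_volume()` returns a `spine_volume`; `spacing()` its voxel
#'   size; `intensity_range()` the observed `(I_min, I_max)`.
#' @examples
#' v <- as_volume(array(0, c(3, 4, 4)), spacing = c(0.2, 0.07, 0.07))
#' spacing(v)
#' intensity_range(v)
#' @export
as_volume <- function(data, spacing = c(1, 1, 1)) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array (z, y, x)")
  check_spacing(spacing)
  structure(data, spacing = as.numeric(spacing),
            class = c("spine_volume", class(array(0, c(1, 1, 1)))))
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || !is.numeric(spacing) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes (dz, dy, dx) in um")
  invisible(spacing)
}

#' @rdname as_volume
#' @param x a `spine_volume` (or any array with a `spacing` attribute).
#' @export
spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) stop("object carries no voxel spacing")
  s
}

#' @rdname as_volume
#' @export
intensity_range <- function(x) range(as.numeric(x))

#' @export
print.spine_volume <- function(x, ...) {
  d <- dim(x)
  r <- intensity_range(x)
  cat(sprintf("<spine_volume> %d x %d x %d voxels (z, y, x), spacing %s um, intensity [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(spacing(x), 3), collapse = " x "),
              r[1], r[2]))
  invisible(x)
}

#' Read a confocal z-stack from TIFF
#'
#' Reads a single- or multi-page grayscale TIFF as an intensity volume with
#' z as axis 1.  Integer sample values are preserved bit-exactly (the file
#' is read `as.is`, without rescaling to `[0, 1]`).
#'
#' @param path TIFF file path.
#' @param spacing voxel size `(dz, dy, dx)` in micrometres.
#' @return a [as_volume()] `spine_volume` of dim `(n_pages, height, width)`.
#' @export
read_stack <- function(path, spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p  # drop extra channels
  })
  if (length(pages) == 1L && length(dim(pages[[1L]])) == 2L)
    warning("single-page TIFF read as a (1, y, x) volume")
  d <- dim(pages[[1L]])
  vol <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) vol[i, , ] <- pages[[i]]
  as_volume(vol, spacing)
}

#' Write a volume as a multi-page TIFF
#'
#' Integer data are stored at the stated bit depth and round-trip exactly
#' through [read_stack()].
#'
#' @param vol 3-D array (`spine_volume` or plain).
#' @param path output file.
#' @param bits bits per sample: 8 or 16.
#' @export
write_stack <- function(vol, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16")
  top <- 2^bits - 1
  v <- unclass(vol)
  attr(v, "spacing") <- NULL
  if (min(v) < 0 || max(v) > top)
    stop("volume values out of range for ", bits, "-bit storage")
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Gaussian denoising of a z-stack
#'
#' Separable Gaussian filter applied once per axis with reflect padding
#' (no dark-edge artefacts near the volume border).  `sigma` is given in
#' voxels per axis; a zero component skips that axis, so
#' `sigma = c(0, 0, 0)` returns the input unchanged.
#'
#' @param vol `spine_volume` (or 3-D array).
#' @param sigma numeric length-3, Gaussian standard deviation in voxels
#'   per axis `(z, y, x)`; all components must be `>= 0`.
#' @return the filtered volume with the same spacing.
#' @export
gaussian_denoise <- function(vol, sigma = c(1, 1, 1)) {
  if (length(sigma) != 3L || any(sigma < 0))
    stop("`sigma` must be three non-negative values (voxels per axis)")
  sp <- attr(vol, "spacing")
  v <- as.numeric(vol)
  d <- dim(vol)
  for (axis in 1:3) {
    if (sigma[axis] == 0) next
    k <- gaussian_kernel(sigma[axis])
    v <- .cpp_convolve_axis(v, as.integer(d), k, as.integer(axis))
  }
  out <- array(v, d)
  if (!is.null(sp)) out <- as_volume(out, sp)
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Seed sets for seeded segmentation
#'
#' The opening algorithm starts from user-placed seed voxels for the spine
#' and dendrite classes plus optional separator voxels that neither object
#' may ever claim.  The three sets must be pairwise disjoint and inside
#' the volume.
#'
#' @param spine,dendrite,separator integer matrices with columns
#'   `(z, y, x)`, 1-based voxel coordinates (possibly 0-row).
#' @return a `seed_set` object.
#' @export
seed_set <- function(spine = NULL, dendrite = NULL, separator = NULL) {
  norm <- function(m) {
    if (is.null(m)) return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("seed coordinates must have 3 columns (z, y, x)")
    storage.mode(m) <- "integer"
    colnames(m) <- c("z", "y", "x")
    m
  }
  s <- list(spine = norm(spine), dendrite = norm(dendrite), separator = norm(separator))
  keys <- lapply(s, function(m) paste(m[, 1], m[, 2], m[, 3]))
  for (a in 1:2) for (b in (a + 1):3) {
    dup <- intersect(keys[[a]], keys[[b]])
    if (length(dup))
      stop("seed classes overlap at voxel(s): ", paste(dup, collapse = "; "))
  }
  structure(s, class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d spine, %d dendrite, %d separator voxel(s)\n",
              nrow(x$spine), nrow(x$dendrite), nrow(x$separator)))
  invisible(x)
}

#' Read seeds from a CSV file or a label volume
#'
#' The CSV dialect has columns `z, y, x, class` with 0-based voxel
#' coordinates and `class` one of `spine`, `dendrite`, `separator`.
#' Alternatively an integer label volume may be given (1 = spine,
#' 2 = dendrite, 3 = separator, 0 = none).
#'
#' @param path CSV file path, or a 3-D integer array.
#' @param shape optional volume dim `(nz, ny, nx)` for bounds validation.
#' @return a [seed_set()].
#' @export
read_seeds <- function(path, shape = NULL) {
  if (is.array(path)) {
    lab <- path
    coords_of <- function(v) {
      w <- which(lab == v, arr.ind = TRUE)
      colnames(w) <- c("z", "y", "x")
      w
    }
    return(seed_set(coords_of(1L), coords_of(2L), coords_of(3L)))
  }
  if (!file.exists(path)) stop("cannot read seeds: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("z", "y", "x", "class")
  if (!all(need %in% names(df)))
    stop("seed CSV must have columns z, y, x, class (0-based coordinates)")
  df$class <- tolower(trimws(df$class))
  bad <- setdiff(unique(df$class), c("spine", "dendrite", "separator"))
  if (length(bad)) stop("unknown seed class(es): ", paste(bad, collapse = ", "))
  m <- as.matrix(df[, c("z", "y", "x")]) + 1L  # 0-based on disk -> 1-based in R
  if (!is.null(shape)) {
    oob <- m[, 1] < 1 | m[, 1] > shape[1] | m[, 2] < 1 | m[, 2] > shape[2] |
      m[, 3] < 1 | m[, 3] > shape[3]
    if (any(oob))
      stop("seed voxel(s) outside the volume: rows ",
           paste(which(oob), collapse = ", "))
  }
  seed_set(m[df$class == "spine", , drop = FALSE],
           m[df$class == "dendrite", , drop = FALSE],
           m[df$class == "separator", , drop = FALSE])
}

#' Write seeds to the CSV dialect
#'
#' @param seeds a [seed_set()].
#' @param path output CSV path (coordinates written 0-based).
#' @export
write_seeds <- function(seeds, path) {
  rows <- function(m, cls) {
    if (!nrow(m)) return(NULL)
    data.frame(z = m[, 1] - 1L, y = m[, 2] - 1L, x = m[, 3] - 1L, class = cls)
  }
  df <- rbind(rows(seeds$spine, "spine"), rows(seeds$dendrite, "dendrite"),
              rows(seeds$separator, "separator"))
  if (is.null(df)) df <- data.frame(z = integer(0), y = integer(0),
                                    x = integer(0), class = character(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write segmentation outputs
#'
#' Writes the label volume as a multi-page TIFF (0 = background,
#' 1 = dendrite, `1 + i` = spine region i) and the per-spine feature table
#' as CSV.  Feature-table landmark coordinates are 0-based `(z, y, x)`.
#'
#' @param labels integer 3-D label array.
#' @param features per-spine feature `data.frame` (from
#'   [measure_spines()] / [classify_spines()]), or `NULL` for none.
#' @param dir output directory (created if missing).
#' @return (invisibly) the paths written.
#' @export
write_outputs <- function(labels, features, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lab_path <- file.path(dir, "labels.tif")
  csv_path <- file.path(dir, "spine_features.csv")
  bits <- if (max(labels) > 255) 16L else 8L
  write_stack(as_volume(labels, c(1, 1, 1)), lab_path, bits = bits)
  if (is.null(features))
    features <- empty_feature_table()
  utils::write.csv(features, csv_path, row.names = FALSE)
  invisible(c(labels = lab_path, features = csv_path))
}

empty_feature_table <- function() {
  data.frame(spine_id = integer(0), n_voxels = integer(0),
             volume_um3 = numeric(0), neck_length_um = numeric(0),
             min_neck_width_um = numeric(0), avg_head_width_um = numeric(0),
             head_depth_um = numeric(0), spine_length_um = numeric(0),
             bh_length_um = numeric(0), spread = numeric(0),
             class = character(0), detached = logical(0), branched = logical(0),
             rule = character(0),
             cbp_z = numeric(0), cbp_y = numeric(0), cbp_x = numeric(0),
             ch_z = numeric(0), ch_y = numeric(0), ch_x = numeric(0),
             tip_z = numeric(0), tip_y = numeric(0), tip_x = numeric(0))
}
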