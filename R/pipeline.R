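#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end run in one serialisable
#' record; the effective configuration is written next to the outputs of
#' every run so results can be reproduced exactly.
#'
#' @param denoise_sigma Gaussian denoising sigma (voxels per axis); the
#'   default uses half a voxel axially, reflecting the roughly three-fold
#'   coarser axial sampling of a typical confocal z-stack.
#' @param theta foreground threshold: numeric, `"otsu"` or `"otsu2"` (see
#'   [threshold_foreground()]).
#' @param min_voxels minimum foreground component size.
#' @param bands `"auto"` (two-threshold Otsu on the foreground) or a
#'   numeric `c(i_spine, i_dendrite)`.
#' @param scale_step opening scale decrement (um); `NULL` for one minimal
#'   voxel step.
#' @param l deepest-point neighbourhood radius (voxels).
#' @param depth_frac significant-depth fraction for head statistics.
#' @param thresholds classification thresholds, see [classify_defaults()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(denoise_sigma = c(0.5, 1, 1), theta = "otsu2",
                            min_voxels = 27L, bands = "auto",
                            scale_step = NULL, l = 2L, depth_frac = 0.6,
                            thresholds = classify_defaults()) {
  structure(list(denoise_sigma = denoise_sigma, theta = theta,
                 min_voxels = min_voxels, bands = bands,
                 scale_step = scale_step, l = l, depth_frac = depth_frac,
                 thresholds = utils::modifyList(classify_defaults(), thresholds)),
            class = "pipeline_config")
}

#' Run the full segmentation and morphometry pipeline
#'
#' Denoise, extract the foreground, build the intensity-band memberships,
#' separate spines from the dendrite by multi-scale opening, decompose the
#' spine voxels into seeded regions, measure and classify each spine, and
#' (optionally) write the label volume, the feature table and the
#' effective configuration to an output directory.
#'
#' @param vol `spine_volume`, or a TIFF path (then `spacing` is required).
#' @param seeds [seed_set()], or a seed CSV path.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param spacing voxel spacing when `vol` is a path.
#' @return list with `seg` (segmentation, labels 0/1/1+i), `spines`
#'   (region records), `features` (classified feature table), `bands`,
#'   `log` (per-stage counts).
#' @export
run_pipeline <- function(vol, seeds, config = pipeline_config(),
                         out_dir = NULL, spacing = NULL) {
  if (is.character(vol)) {
    if (is.null(spacing)) stop("`spacing` is required when reading a stack from file")
    vol <- read_stack(vol, spacing)
  }
  if (is.character(seeds)) seeds <- read_seeds(seeds, shape = dim(vol))
  logi <- list()

  den <- gaussian_denoise(vol, config$denoise_sigma)
  fg <- threshold_foreground(den, theta = config$theta,
                             min_voxels = config$min_voxels)
  logi$n_foreground <- sum(fg$mu > 0)

  fg_int <- unclass(den)[fg$mu > 0]
  bands <- if (identical(config$bands, "auto")) auto_bands(fg_int)
  else intensity_bands(min(fg_int), config$bands[1], config$bands[2], max(fg_int))
  mu <- array(0, dim(den))
  mu[fg$mu > 0] <- pmax(pmax(membership_spine(fg_int, bands),
                             membership_dendrite(fg_int, bands)), 1e-6)
  obj <- fuzzy_object(mu, spacing(vol))

  seg <- multi_scale_opening(obj, seeds, intensity = unclass(den),
                             bands = bands, scale_step = config$scale_step)
  seg <- extract_spine_components(seg)
  logi$K <- seg$K
  logi$n_spine_voxels <- sum(seg$labels > 1L)

  spines <- measure_spines(seg, l = config$l, depth_frac = config$depth_frac)
  features <- classify_spines(spines, config$thresholds)

  if (!is.null(out_dir)) {
    write_outputs(seg$labels, features, out_dir)
    eff <- config
    eff$bands <- c(i_spine = bands$i_spine, i_dendrite = bands$i_dendrite)
    eff$theta <- attr(fg, "theta")
    yaml::write_yaml(lapply(unclass(eff), function(v)
      if (is.null(v)) "default" else unname(v)),
      file.path(out_dir, "config.yaml"))
    writeLines(sprintf("%s: %s", names(logi), unlist(logi)),
               file.path(out_dir, "run_log.txt"))
  }
  list(seg = seg, spines = spines, features = features, bands = bands,
       log = logi)
}

#' Agreement statistics between two measurement series
#'
#' Pearson's correlation plus the Bland-Altman summary of the paired
#' differences: mean difference, its standard deviation, the agreement
#' band at 1.5 standard deviations and the fraction of pairs falling
#' inside it.
#'
#' @param a,b paired numeric series of equal length (at least 3, no
#'   missing values).
#' @param band_sd half-width of the agreement band in standard deviations.
#' @return list with `pearson_r`, `mean_diff`, `sd_diff`, `band`
#'   (lower/upper), `frac_within`.
#' @export
agreement_stats <- function(a, b, band_sd = 1.5) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance: Pearson correlation undefined")
    NA_real_
  } else stats::cor(a, b)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  band <- c(lower = m - band_sd * s, upper = m + band_sd * s)
  frac <- if (s == 0) 1 else mean(d >= band[1] & d <= band[2])
  list(pearson_r = r, mean_diff = m, sd_diff = s, band = band,
       frac_within = frac)
}

#' Multi-rater reproducibility: percent standard deviation
#'
#' For each measured spine, the standard deviation of the raters'
#' estimates divided by their mean, in percent; the summary is the mean of
#' that percentage over the population.  Spines whose rater mean is zero
#' are excluded with a warning.
#'
#' @param ratings numeric matrix, raters in columns, spines in rows (at
#'   least 2 raters).
#' @return list with `percent_sd` (per spine) and `mean_percent_sd`.
#' @export
reproducibility_stats <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2L) stop("need at least 2 raters")
  if (anyNA(ratings)) stop("the rater x spine matrix must be complete")
  m <- rowMeans(ratings)
  s <- apply(ratings, 1, stats::sd)
  keep <- m != 0
  if (!all(keep)) warning(sum(!keep), " spine(s) with zero mean excluded")
  pct <- 100 * s[keep] / m[keep]
  list(percent_sd = pct, mean_percent_sd = mean(pct))
}
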