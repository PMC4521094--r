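# Synthetic phantom volumes and cohort tables calibrated to the published
# group-wise CCTXR distributions, so every downstream stage has seedable,
# statistically realistic input without access to scan data.

#' Specify a labeled uptake phantom
#'
#' A phantom stands in for a spatially normalized amyloid-PET scan plus its
#' atlas: a 3-D uptake grid and an integer label grid. Regions are laid out
#' as consecutive slabs along the third (z) axis; rows sharing a `roi` name
#' with sides `"L"`/`"R"` share a slab split at the x midline, so bilateral
#' ROIs have a left and a right label.
#'
#' @param grid_shape integer(3), voxel counts per axis.
#' @param voxel_size numeric(3), voxel edge length in mm.
#' @param regions data frame with columns `label` (unique positive integer),
#'   `name`, `ratio` (true uptake relative to the reference region, > 0),
#'   and optionally `roi` (grouping name) and `side` (`"L"`, `"R"` or `"B"`).
#' @param reference_label label id of the reference region (must appear in
#'   `regions`).
#' @param noise_sd additive Gaussian noise SD, in uptake units (>= 0).
#' @param smoothing_fwhm_mm full width at half maximum of an isotropic
#'   Gaussian blur emulating spill-over between regions; 0 disables it.
#' @param reference_value uptake assigned to the reference region; every
#'   region's noise-free value is `ratio * reference_value`.
#' @param seed integer seed governing the noise draw.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 48L),
                         voxel_size = c(2, 2, 2),
                         regions = default_phantom_regions(),
                         reference_label = 99L,
                         noise_sd = 0,
                         smoothing_fwhm_mm = 0,
                         reference_value = 1,
                         seed = 1L) {
  regions <- tibble::as_tibble(regions)
  stopifnot(
    length(grid_shape) == 3, all(grid_shape >= 2),
    length(voxel_size) == 3, all(voxel_size > 0),
    all(c("label", "name", "ratio") %in% names(regions)),
    noise_sd >= 0, smoothing_fwhm_mm >= 0, reference_value > 0
  )
  if (anyDuplicated(regions$label))
    stop("overlapping labels: region label ids must be unique")
  if (any(regions$ratio <= 0)) stop("all uptake ratios must be > 0")
  if (!reference_label %in% regions$label)
    stop("reference_label not present in regions")
  if (!"roi" %in% names(regions)) regions$roi <- regions$name
  if (!"side" %in% names(regions)) regions$side <- "B"
  structure(
    list(
      grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
      regions = regions, reference_label = as.integer(reference_label),
      noise_sd = noise_sd, smoothing_fwhm_mm = smoothing_fwhm_mm,
      reference_value = reference_value, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Default phantom atlas: 12 bilateral grey-matter ROIs plus reference
#'
#' The 12 ROIs mirror the bilateral grey-matter atlas regions used for
#' amyloid quantification (temporal, frontal, occipital, parietal, insula,
#' anterior/posterior cingulate, caudate, putamen, thalamus, hippocampus,
#' parahippocampal gyrus); labels `2k-1`/`2k` are the left/right parts of
#' ROI `k`. Label 99 is the cerebellar reference, label 50 a white-matter
#' compartment used to emulate spill-over. Ratios follow the published
#' younger-HC regional means.
#'
#' @param ratios named numeric of per-ROI uptake ratios; defaults to a
#'   healthy-control-like pattern.
#' @param wm_ratio uptake ratio of the white-matter compartment.
#' @return A tibble suitable for the `regions` field of [phantom_spec()].
#' @export
default_phantom_regions <- function(ratios = NULL, wm_ratio = 1.8) {
  rois <- c(
    "temporal", "frontal", "occipital", "parietal", "insula",
    "anterior_cingulate", "posterior_cingulate", "caudate", "putamen",
    "thalamus", "hippocampus", "parahippocampal"
  )
  if (is.null(ratios)) {
    ratios <- c(
      temporal = 1.26, frontal = 1.27, occipital = 1.31, parietal = 1.26,
      insula = 1.15, anterior_cingulate = 1.22, posterior_cingulate = 1.26,
      caudate = 0.83, putamen = 1.17, thalamus = 0.94, hippocampus = 1.08,
      parahippocampal = 1.09
    )
  }
  stopifnot(all(rois %in% names(ratios)))
  bilateral <- tibble::tibble(
    label = as.integer(c(rbind(2 * seq_along(rois) - 1, 2 * seq_along(rois)))),
    name = as.vector(rbind(paste0(rois, "_l"), paste0(rois, "_r"))),
    roi = rep(rois, each = 2),
    side = rep(c("L", "R"), times = length(rois)),
    tissue = "GM",
    ratio = rep(unname(ratios[rois]), each = 2)
  )
  extra <- tibble::tibble(
    label = c(50L, 99L),
    name = c("white_matter", "cerebellum"),
    roi = c("white_matter", "cerebellum"),
    side = "B",
    tissue = c("WM", "GM"),
    ratio = c(wm_ratio, 1.0)
  )
  rbind(bilateral, extra)
}

#' Construct a labeled volume
#'
#' @param uptake 3-D non-negative numeric array.
#' @param labels 3-D integer array of the same shape.
#' @param region_map data frame mapping `label` to at least `name`.
#' @param voxel_size numeric(3) voxel size in mm.
#' @return A `labeled_volume` object.
#' @export
labeled_volume <- function(uptake, labels, region_map, voxel_size = c(2, 2, 2)) {
  stopifnot(identical(dim(uptake), dim(labels)), length(dim(uptake)) == 3)
  region_map <- tibble::as_tibble(region_map)
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, region_map$label)
  if (length(missing))
    stop("labels present in grid but absent from region_map: ",
         paste(missing, collapse = ", "))
  structure(
    list(uptake = uptake, labels = labels, region_map = region_map,
         voxel_size = as.numeric(voxel_size)),
    class = "labeled_volume"
  )
}

# Slab layout of the label grid: one z-slab per ROI group, split at the x
# midline when the group has L/R sides.
build_label_array <- function(spec) {
  dims <- spec$grid_shape
  labels <- array(0L, dim = dims)
  groups <- unique(spec$regions$roi)
  edges <- floor(seq(0, dims[3], length.out = length(groups) + 1))
  xm <- floor(dims[1] / 2)
  for (g in seq_along(groups)) {
    z <- (edges[g] + 1):edges[g + 1]
    if (edges[g + 1] <= edges[g])
      stop("empty region: grid too small for region group '", groups[g], "'")
    rows <- spec$regions[spec$regions$roi == groups[g], ]
    for (i in seq_len(nrow(rows))) {
      xs <- switch(rows$side[i],
        L = seq_len(xm),
        R = (xm + 1):dims[1],
        seq_len(dims[1])
      )
      labels[xs, , z] <- rows$label[i]
    }
  }
  for (lab in spec$regions$label)
    if (!any(labels == lab))
      stop("empty region: label ", lab, " received no voxels")
  labels
}

# Separable Gaussian blur with kernel renormalization at the edges, so a
# constant field is preserved exactly.
gaussian_blur_3d <- function(x, fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(x)
  sigma_vox <- (fwhm_mm / 2.354820045) / voxel_size
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-8) next
    half <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-half, half), sd = s)
    x <- convolve_along(x, k, axis)
  }
  x
}

convolve_along <- function(x, kernel, axis) {
  d <- dim(x)
  n <- d[axis]
  half <- (length(kernel) - 1L) / 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  wsum <- numeric(n)
  for (j in seq_along(kernel)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kernel[j] * m[src[ok], ]
    wsum[ok] <- wsum[ok] + kernel[j]
  }
  out <- out / wsum
  dim(out) <- dim(xp)
  aperm(out, order(perm))
}

#' Generate a labeled uptake phantom
#'
#' Each region's noise-free voxel value is its configured ratio times the
#' reference value; additive Gaussian noise and an optional Gaussian blur
#' (spill-over) are then applied to the uptake grid. The label grid is never
#' touched by noise or blur.
#'
#' @param spec a [phantom_spec()].
#' @return A [labeled_volume()] with `tissue` and `side` columns in its
#'   region map.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- build_label_array(spec)
  ratio_of <- setNames(spec$regions$ratio, spec$regions$label)
  uptake <- array(0, dim = spec$grid_shape)
  nz <- labels != 0L
  uptake[nz] <- spec$reference_value * ratio_of[as.character(labels[nz])]
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    uptake <- uptake + rnorm(length(uptake), sd = spec$noise_sd)
  }
  uptake <- gaussian_blur_3d(uptake, spec$smoothing_fwhm_mm, spec$voxel_size)
  uptake[uptake < 0] <- 0
  rm <- spec$regions
  if (!"tissue" %in% names(rm)) rm$tissue <- "GM"
  labeled_volume(uptake, labels, rm, spec$voxel_size)
}

#' Write / read a labeled volume as a NIfTI-1 pair
#'
#' The uptake grid and the integer label map are stored as two NIfTI files
#' sharing the voxel grid.
#'
#' @param vol a [labeled_volume()].
#' @param uptake_path,labels_path output file paths (`.nii` / `.nii.gz`).
#' @return `write_labeled_volume()` returns the paths invisibly;
#'   `read_labeled_volume()` returns a [labeled_volume()].
#' @export
write_labeled_volume <- function(vol, uptake_path, labels_path) {
  stopifnot(inherits(vol, "labeled_volume"))
  up <- RNifti::asNifti(vol$uptake)
  RNifti::pixdim(up) <- vol$voxel_size
  RNifti::writeNifti(up, uptake_path)
  lb <- RNifti::asNifti(array(as.integer(vol$labels), dim = dim(vol$labels)))
  RNifti::pixdim(lb) <- vol$voxel_size
  RNifti::writeNifti(lb, labels_path, datatype = "int16")
  invisible(c(uptake_path, labels_path))
}

#' @rdname write_labeled_volume
#' @param region_map region dictionary for the labels read back.
#' @export
read_labeled_volume <- function(uptake_path, labels_path, region_map) {
  up <- RNifti::readNifti(uptake_path)
  lb <- RNifti::readNifti(labels_path)
  vs <- RNifti::pixdim(up)
  labeled_volume(array(as.numeric(up), dim = dim(up)),
                 array(as.integer(lb), dim = dim(lb)),
                 region_map, voxel_size = vs[1:3])
}

#' Gaussian mixture distribution helpers
#'
#' Density, distribution function and random generation for a univariate
#' Gaussian mixture, used for the configured CCTXR distributions.
#'
#' @param x,q numeric vector of quantiles.
#' @param n number of draws.
#' @param weights,means,sds component parameters; weights must sum to 1.
#' @return `dgmix`/`pgmix` a numeric vector; `rgmix` a list with `values`
#'   and the latent `component` index.
#' @export
dgmix <- function(x, weights, means, sds) {
  check_mixture(weights, means, sds)
  rowSums(vapply(seq_along(weights),
                 function(k) weights[k] * dnorm(x, means[k], sds[k]),
                 numeric(length(x))))
}

#' @rdname dgmix
#' @export
pgmix <- function(q, weights, means, sds) {
  check_mixture(weights, means, sds)
  rowSums(vapply(seq_along(weights),
                 function(k) weights[k] * pnorm(q, means[k], sds[k]),
                 numeric(length(q))))
}

#' @rdname dgmix
#' @export
rgmix <- function(n, weights, means, sds) {
  check_mixture(weights, means, sds)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  list(values = rnorm(n, means[comp], sds[comp]), component = comp)
}

check_mixture <- function(weights, means, sds) {
  stopifnot(
    length(weights) == length(means), length(means) == length(sds),
    all(weights > 0), abs(sum(weights) - 1) < 1e-8, all(sds >= 0)
  )
  invisible(TRUE)
}

#' Default cohort calibration
#'
#' One row per stratum (diagnosis x age group) with the published CCTXR
#' mixture parameters, sample sizes, demographics and ApoE4 carrier rates:
#' younger HC is a two-component mixture (1.23 +/- 0.08, n 110; 1.52 +/- 0.08,
#' n 13), older HC a single normal (1.26 +/- 0.16), younger AD a single
#' normal (1.48 +/- 0.17), older AD a two-component mixture (1.08 +/- 0.13,
#' n 15; 1.48 +/- 0.13, n 54), and both MCI groups single normals
#' (1.36 +/- 0.19, 1.35 +/- 0.20). ApoE4 carrier probabilities are
#' per-component where subgroup rates were published (69% vs 26% in younger
#' HC; 74% vs 7% in older AD), marginal otherwise.
#'
#' @return A tibble with list-columns `weights`, `means`, `sds`,
#'   `apoe4_prob` (one entry per mixture component).
#' @export
default_strata <- function() {
  tibble::tibble(
    diagnosis = rep(c("HC", "MCI", "AD"), each = 2),
    age_group = rep(c("younger", "older"), times = 3),
    n = c(123L, 123L, 171L, 171L, 69L, 69L),
    weights = list(c(110, 13) / 123, 1, 1, 1, 1, c(15, 54) / 69),
    means = list(c(1.23, 1.52), 1.26, 1.36, 1.35, 1.48, c(1.08, 1.48)),
    sds = list(c(0.08, 0.08), 0.16, 0.19, 0.20, 0.17, c(0.13, 0.13)),
    apoe4_prob = list(c(0.26, 0.69), 28 / 123, 89 / 170, 63 / 169,
                      53 / 67, c(0.07, 0.74)),
    prob_male = c(55, 66, 105, 106, 35, 45) / c(123, 123, 171, 171, 69, 69),
    mmse_mean = c(29.1, 29.0, 27.9, 27.7, 22.6, 22.3),
    mmse_sd = c(1.1, 1.2, 1.8, 1.7, 3.4, 2.7),
    edu_mean = c(16.3, 16.4, 16.3, 15.6, 15.9, 15.7),
    edu_sd = c(2.7, 2.8, 2.7, 2.9, 2.6, 2.8),
    age_lo = rep(c(55, 76), times = 3),
    age_hi = rep(c(75, 93), times = 3)
  )
}

#' Default regional SUVR model
#'
#' Regional SUVRs are generated as linear transforms of the subject's CCTXR,
#' `suvr = a + b * cctxr + noise`, with slope and intercept anchored at the
#' published younger-HC and younger-AD group means of each ROI (so the
#' generated group means reproduce the published regional ordering). The
#' residual SD of each ROI is set to its published younger-HC SD: the total
#' generated ROI variance then somewhat exceeds the published marginal
#' variance (conservative), but the noise-to-slope ratio preserves the
#' published discrimination ordering, with the putamen - steepest slope,
#' moderate residual - the most discriminative ROI.
#'
#' @return A tibble with columns `roi`, `intercept`, `slope`, `resid_sd`.
#' @export
default_roi_model <- function() {
  tab <- tibble::tibble(
    roi = c("frontal", "temporal", "parietal", "occipital",
            "anterior_cingulate", "posterior_cingulate", "insula",
            "caudate", "putamen", "thalamus", "parahippocampal",
            "hippocampus"),
    hc_mean = c(1.27, 1.26, 1.26, 1.31, 1.22, 1.26, 1.15, 0.83, 1.17, 0.94,
                1.09, 1.08),
    ad_mean = c(1.48, 1.48, 1.49, 1.49, 1.53, 1.62, 1.35, 1.00, 1.57, 0.92,
                1.15, 1.07),
    hc_sd = c(0.13, 0.11, 0.13, 0.10, 0.18, 0.18, 0.12, 0.17, 0.14, 0.12,
              0.08, 0.08)
  )
  cctxr_hc <- 1.26   # younger-HC CCTXR mean
  cctxr_ad <- 1.48   # younger-AD CCTXR mean
  slope <- (tab$ad_mean - tab$hc_mean) / (cctxr_ad - cctxr_hc)
  tibble::tibble(
    roi = tab$roi,
    intercept = tab$hc_mean - slope * cctxr_hc,
    slope = slope,
    resid_sd = tab$hc_sd
  )
}

#' Configure a synthetic cohort
#'
#' @param strata stratum calibration table, see [default_strata()].
#' @param roi_model regional SUVR model, see [default_roi_model()].
#' @param regional_cor shared intra-subject correlation of the regional
#'   residuals, in `[0, 1)`; the published analyses do not constrain it, so
#'   it is a free parameter.
#' @param apoe4_effect additive shift on CCTXR for ApoE4 carriers, in CCTXR
#'   units. The default 0 keeps each stratum's CCTXR distribution exactly at
#'   its configured mixture; the ApoE4-amyloid association is carried by the
#'   component-wise carrier probabilities instead.
#' @param tracer tracer label recorded per subject.
#' @param cohort cohort label recorded per subject.
#' @param seed integer seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(strata = default_strata(),
                          roi_model = default_roi_model(),
                          regional_cor = 0.3,
                          apoe4_effect = 0,
                          tracer = "florbetapir",
                          cohort = "synthetic-florbetapir",
                          seed = 1L) {
  strata <- tibble::as_tibble(strata)
  stopifnot(
    all(c("diagnosis", "age_group", "n", "weights", "means", "sds") %in%
          names(strata)),
    all(strata$n >= 1),
    regional_cor >= 0, regional_cor < 1
  )
  for (i in seq_len(nrow(strata))) {
    w <- strata$weights[[i]]
    if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
    if (any(strata$sds[[i]] <= 0)) stop("mixture SDs must be > 0")
    if (length(w) != length(strata$means[[i]]) ||
        length(w) != length(strata$sds[[i]]))
      stop("weights/means/sds length mismatch in stratum ", i)
    if (!strata$diagnosis[i] %in% c("HC", "MCI", "AD"))
      stop("diagnosis must be HC, MCI or AD")
  }
  structure(
    list(strata = strata, roi_model = tibble::as_tibble(roi_model),
         regional_cor = regional_cor, apoe4_effect = apoe4_effect,
         tracer = tracer, cohort = cohort, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort table
#'
#' Per subject: a latent mixture component is drawn from the stratum's
#' configured weights, CCTXR from that component's Gaussian (redrawn if a
#' draw is non-positive; the count of such truncations is attached as the
#' `n_truncated` attribute), ApoE4 carrier status from the component-wise
#' probability, an optional additive ApoE4 shift applied, and the 12
#' regional SUVRs derived from the ROI model with correlated residuals. The
#' latent component index is recorded for recovery scoring only; analysis
#' stages never read it.
#'
#' @param config a [cohort_config()].
#' @return A tibble with one row per subject: demographics, `cctxr`, one
#'   `suvr_<roi>` column per ROI, and `true_component`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_trunc <- 0L
  rows <- vector("list", nrow(config$strata))
  for (i in seq_len(nrow(config$strata))) {
    s <- config$strata[i, ]
    n <- s$n
    w <- s$weights[[1]]; mu <- s$means[[1]]; sg <- s$sds[[1]]
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    cctxr <- rnorm(n, mu[comp], sg[comp])
    bad <- which(cctxr <= 0)
    while (length(bad)) {
      n_trunc <- n_trunc + length(bad)
      cctxr[bad] <- rnorm(length(bad), mu[comp[bad]], sg[comp[bad]])
      bad <- bad[cctxr[bad] <= 0]
    }
    p4 <- s$apoe4_prob[[1]]
    if (length(p4) == 1) p4 <- rep(p4, length(w))
    apoe4 <- rbinom(n, 1, p4[comp]) == 1
    cctxr <- cctxr + config$apoe4_effect * apoe4
    age <- runif(n, s$age_lo, s$age_hi)
    sex <- ifelse(runif(n) < s$prob_male, "m", "f")
    mmse <- pmin(30, pmax(0, round(rnorm(n, s$mmse_mean, s$mmse_sd))))
    edu <- pmax(0, round(rnorm(n, s$edu_mean, s$edu_sd)))
    rows[[i]] <- tibble::tibble(
      diagnosis = s$diagnosis, age_group = s$age_group,
      age = round(age, 1), sex = sex, education = edu,
      apoe4 = apoe4, mmse = mmse, true_component = comp, cctxr = cctxr
    )
  }
  out <- do.call(rbind, rows)
  out <- tibble::add_column(
    out,
    subject_id = sprintf("S%04d", seq_len(nrow(out))),
    cohort = config$cohort, tracer = config$tracer,
    .before = 1
  )
  # Regional SUVRs: shared + ROI-specific residuals, truncated at 0 by redraw
  rho <- config$regional_cor
  z_shared <- rnorm(nrow(out))
  for (j in seq_len(nrow(config$roi_model))) {
    rm <- config$roi_model[j, ]
    z <- sqrt(rho) * z_shared + sqrt(1 - rho) * rnorm(nrow(out))
    v <- rm$intercept + rm$slope * out$cctxr + rm$resid_sd * z
    bad <- which(v <= 0)
    if (length(bad)) {
      # resample the full residual from the normal truncated to keep the
      # SUVR positive (inverse-CDF), dropping the shared component for
      # these rare draws; each is counted as a truncation
      n_trunc <- n_trunc + length(bad)
      det <- rm$intercept + rm$slope * out$cctxr[bad]
      lo <- pnorm(-det / rm$resid_sd)
      u <- pmin(runif(length(bad), lo, 1), 1 - 1e-16)
      v[bad] <- det + rm$resid_sd * qnorm(u)
    }
    out[[paste0("suvr_", rm$roi)]] <- v
  }
  attr(out, "n_truncated") <- n_trunc
  attr(out, "seed") <- config$seed
  out
}

#' Map composite-ratio values between tracers
#'
#' Applies the fitted cross-tracer linear relation `y = slope * x +
#' intercept` (for the published PIB-to-Florbetapir relation, `y = 1.13 x -
#' 0.28`), optionally with Gaussian residual noise.
#'
#' @param values numeric CCTXR values on the source-tracer scale.
#' @param slope,intercept coefficients of the linear map; `slope > 0`.
#' @param residual_sd SD of additive Gaussian residuals (0 = deterministic).
#' @param seed seed for the residual draw; ignored when `residual_sd = 0`.
#' @return Numeric vector on the target-tracer scale.
#' @export
apply_tracer_transform <- function(values, slope, intercept,
                                   residual_sd = 0, seed = NULL) {
  stopifnot(slope > 0, residual_sd >= 0)
  out <- slope * values + intercept
  if (residual_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    out <- out + rnorm(length(out), sd = residual_sd)
  }
  out
}

#' Write / read a cohort table as CSV
#'
#' Columns: `subject_id`, `cohort`, `tracer`, `diagnosis` (HC/MCI/AD),
#' `age_group` (younger/older), `age`, `sex` (m/f), `education` (years),
#' `apoe4` (TRUE/FALSE), `mmse` (0-30), `true_component` (latent; synthetic
#' only), `cctxr`, and one `suvr_<roi>` column per ROI.
#'
#' @param cohort a cohort tibble from [generate_cohort()].
#' @param path file path.
#' @return `read_cohort_csv()` returns the cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if ("apoe4" %in% names(out)) out$apoe4 <- as.logical(out$apoe4)
  out
}
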