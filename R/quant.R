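# Regional SUVR quantification: reference-region scaling, bilateral ROI
# extraction over the voxel union, the composite neocortical ratio, and
# benchmarking of candidate reference regions.

#' Reference-region uptake statistic
#'
#' Computes the chosen statistic (median for PIB-style cerebellar grey
#' matter; mean for the Florbetapir whole-cerebellum convention) over all
#' voxels carrying any of the reference labels.
#'
#' @param vol a [labeled_volume()].
#' @param reference_labels integer label ids forming the reference region.
#' @param statistic `"median"` or `"mean"`.
#' @return Scalar uptake value.
#' @export
compute_reference_value <- function(vol, reference_labels,
                                    statistic = c("median", "mean")) {
  stopifnot(inherits(vol, "labeled_volume"))
  statistic <- match.arg(statistic)
  vox <- vol$uptake[vol$labels %in% reference_labels]
  if (!length(vox))
    stop("empty reference region: no voxels carry labels ",
         paste(reference_labels, collapse = ", "),
         " (misconfigured atlas?)")
  if (statistic == "median") median(vox) else mean(vox)
}

#' Scale an uptake volume to SUVR
#'
#' Divides every voxel by the reference value, turning uptake into
#' standardized uptake value ratios. Labels are untouched. The operation is
#' deliberately not idempotent: applying it twice divides twice.
#'
#' @param vol a [labeled_volume()].
#' @param reference_value positive scalar from [compute_reference_value()].
#' @return A [labeled_volume()] whose `uptake` holds ratios.
#' @export
compute_suvr_image <- function(vol, reference_value) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (!is.numeric(reference_value) || length(reference_value) != 1 ||
      reference_value <= 0)
    stop("reference_value must be a positive scalar")
  vol$uptake <- vol$uptake / reference_value
  vol
}

#' Bilateral ROI definitions from a region map
#'
#' Builds the ROI-to-label table grouping left and right labels of each
#' bilateral ROI, excluding the reference and non-GM compartments.
#'
#' @param region_map region map of a [labeled_volume()] with `roi`,
#'   `label` and optionally `tissue` columns.
#' @param exclude roi names to drop (reference region, white matter).
#' @return A tibble with columns `roi`, `label`.
#' @export
roi_definitions <- function(region_map,
                            exclude = c("cerebellum", "white_matter")) {
  stopifnot(all(c("roi", "label") %in% names(region_map)))
  keep <- !(region_map$roi %in% exclude)
  tibble::tibble(roi = region_map$roi[keep], label = region_map$label[keep])
}

#' Extract bilateral ROI mean SUVRs
#'
#' Each ROI value is the mean SUVR over the union of all voxels carrying any
#' of its labels (left plus right) - not the mean of hemispheric means, so
#' unequal hemispheric volumes are weighted by voxel count.
#'
#' @param suvr_vol a SUVR-scaled [labeled_volume()].
#' @param roi_defs tibble with columns `roi`, `label` mapping each ROI to
#'   its constituent labels.
#' @return Named numeric vector of ROI means, with an `n_voxels` attribute
#'   giving each ROI's voxel count.
#' @export
extract_roi_means <- function(suvr_vol, roi_defs) {
  stopifnot(inherits(suvr_vol, "labeled_volume"),
            all(c("roi", "label") %in% names(roi_defs)))
  rois <- unique(roi_defs$roi)
  means <- numeric(length(rois))
  counts <- integer(length(rois))
  for (i in seq_along(rois)) {
    labs <- roi_defs$label[roi_defs$roi == rois[i]]
    sel <- suvr_vol$labels %in% labs
    if (!any(sel))
      stop("missing label: ROI '", rois[i], "' has no voxels in the volume")
    means[i] <- mean(suvr_vol$uptake[sel])
    counts[i] <- sum(sel)
  }
  names(means) <- rois
  names(counts) <- rois
  attr(means, "n_voxels") <- counts
  means
}

#' Composite neocortical ratio
#'
#' Weighted average of the frontal, parietal and (basal/lateral) temporal
#' ROI SUVRs. The default weights are the ROI voxel counts carried by
#' [extract_roi_means()], which makes the composite equal to the direct
#' voxel-level mean over the union of the composite regions.
#'
#' @param roi_means named vector from [extract_roi_means()].
#' @param weights named positive weights covering exactly the composite
#'   ROIs; `NULL` uses the voxel counts (equal weights if absent).
#' @param composite_rois names of the composite ROIs.
#' @return Scalar CCTXR.
#' @export
compute_cctxr <- function(roi_means, weights = NULL,
                          composite_rois = c("frontal", "parietal",
                                             "temporal")) {
  missing_rois <- setdiff(composite_rois, names(roi_means))
  if (length(missing_rois))
    stop("composite ROIs absent from roi_means: ",
         paste(missing_rois, collapse = ", "))
  if (is.null(weights)) {
    nv <- attr(roi_means, "n_voxels")
    weights <- if (is.null(nv)) setNames(rep(1, length(composite_rois)),
                                         composite_rois) else nv
  }
  if (!all(composite_rois %in% names(weights)))
    stop("weights must cover exactly the composite ROIs")
  w <- weights[composite_rois]
  if (any(w <= 0)) stop("weights must be > 0")
  if (sum(w) == 0) stop("zero total weight")
  sum(w * roi_means[composite_rois]) / sum(w)
}

#' Quantify one labeled volume end to end
#'
#' Convenience wrapper: reference statistic, SUVR scaling, bilateral ROI
#' means and CCTXR in one call.
#'
#' @param vol a [labeled_volume()] with raw uptake.
#' @param reference_labels reference label ids; default takes the labels of
#'   the `cerebellum` roi in the region map.
#' @param statistic reference statistic, `"median"` or `"mean"`.
#' @param roi_defs ROI definitions; default [roi_definitions()] of the
#'   volume's region map.
#' @param subject_id identifier recorded in the output row.
#' @inheritParams compute_cctxr
#' @return One-row tibble: `subject_id`, `reference_value`,
#'   `reference_statistic`, one `suvr_<roi>` column per ROI, `cctxr`.
#' @export
quantify_volume <- function(vol, reference_labels = NULL,
                            statistic = c("median", "mean"),
                            roi_defs = NULL, subject_id = "S0001",
                            weights = NULL,
                            composite_rois = c("frontal", "parietal",
                                               "temporal")) {
  statistic <- match.arg(statistic)
  if (is.null(reference_labels))
    reference_labels <-
      vol$region_map$label[vol$region_map$roi == "cerebellum"]
  if (is.null(roi_defs)) roi_defs <- roi_definitions(vol$region_map)
  ref <- compute_reference_value(vol, reference_labels, statistic)
  suvr <- compute_suvr_image(vol, ref)
  rm_ <- extract_roi_means(suvr, roi_defs)
  cctxr <- compute_cctxr(rm_, weights = weights,
                         composite_rois = composite_rois)
  row <- tibble::tibble(subject_id = subject_id, reference_value = ref,
                        reference_statistic = statistic)
  for (r in names(rm_)) row[[paste0("suvr_", r)]] <- unname(rm_[r])
  row$cctxr <- cctxr
  row
}

#' Benchmark candidate reference regions
#'
#' Recomputes the CCTXR of every subject under each candidate reference
#' definition and reports, per candidate, the coefficient of variation of
#' the healthy-control CCTXR and Cohen's d between the HC and AD groups -
#' the two criteria used to prefer whole cerebellum over cerebellar grey
#' matter for tracers with strong white-matter spill-over.
#'
#' @param hc_vols,ad_vols lists of raw-uptake [labeled_volume()] objects.
#' @param candidates named list; each element `list(labels =, statistic =)`.
#' @param roi_defs,composite_rois passed to the quantification.
#' @return Tibble with columns `candidate`, `hc_cv`, `cohens_d`,
#'   `best_cv`, `best_d`. Degenerate (zero-variance) groups yield `NA` d.
#' @export
evaluate_reference_regions <- function(hc_vols, ad_vols, candidates,
                                       roi_defs = NULL,
                                       composite_rois = c("frontal",
                                                          "parietal",
                                                          "temporal")) {
  stopifnot(length(hc_vols) >= 2, length(ad_vols) >= 2,
            length(candidates) >= 1)
  cand_names <- names(candidates)
  if (is.null(cand_names)) cand_names <- paste0("candidate_", seq_along(candidates))
  cctxr_under <- function(vol, cand) {
    ref <- compute_reference_value(vol, cand$labels, cand$statistic)
    suvr <- compute_suvr_image(vol, ref)
    defs <- if (is.null(roi_defs)) roi_definitions(vol$region_map) else roi_defs
    compute_cctxr(extract_roi_means(suvr, defs),
                  composite_rois = composite_rois)
  }
  res <- lapply(seq_along(candidates), function(i) {
    hc <- vapply(hc_vols, cctxr_under, numeric(1), cand = candidates[[i]])
    ad <- vapply(ad_vols, cctxr_under, numeric(1), cand = candidates[[i]])
    d <- cohens_d(hc, ad)
    tibble::tibble(candidate = cand_names[i],
                   hc_cv = sd(hc) / mean(hc),
                   cohens_d = d)
  })
  out <- do.call(rbind, res)
  out$best_cv <- seq_len(nrow(out)) == which.min(out$hc_cv)
  out$best_d <- seq_len(nrow(out)) ==
    which.max(ifelse(is.na(abs(out$cohens_d)), -Inf, abs(out$cohens_d)))
  out
}
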