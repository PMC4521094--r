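# SUVR quantification: reference statistics, ratio images, bilateral
# union means, the composite neocortical ratio and reference-region
# benchmarking.

test_that("reference statistic is the chosen summary over reference voxels", {
  vol <- flat_volume(list(`1` = c(1, 2, 9), `99` = rep(5, 4)))
  expect_identical(compute_reference_value(vol, 99L, "median"), 5)
  expect_identical(compute_reference_value(vol, 99L, "mean"), 5)
  expect_identical(compute_reference_value(vol, 1L, "median"), 2)
  expect_identical(compute_reference_value(vol, 1L, "mean"), 4)
  expect_error(compute_reference_value(vol, 7L), "empty reference")
  expect_error(compute_reference_value(vol, 99L, "mode"))
})

test_that("SUVR scaling divides voxels and is deliberately not idempotent", {
  vol <- flat_volume(list(`1` = c(2.4, 1.2), `99` = c(1.2, 1.2)))
  s1 <- compute_suvr_image(vol, 1)
  expect_identical(s1$uptake, vol$uptake)
  s2 <- compute_suvr_image(vol, 1.2)
  expect_equal(s2$uptake[1], 2.0)
  expect_identical(s2$labels, vol$labels)
  s3 <- compute_suvr_image(s2, 1.2)
  expect_equal(s3$uptake, vol$uptake / 1.2^2)
  expect_error(compute_suvr_image(vol, 0), "positive")
  expect_error(compute_suvr_image(vol, -2), "positive")
})

test_that("bilateral ROI means are voxel-union means, not means of means", {
  rm_ <- tibble::tibble(label = c(1L, 2L, 99L),
                        name = c("putamen_l", "putamen_r", "ref"),
                        roi = c("putamen", "putamen", "ref"))
  vol <- flat_volume(list(`1` = rep(1.5, 6), `2` = rep(1.7, 6),
                          `99` = rep(1, 3)), region_map = rm_)
  defs <- tibble::tibble(roi = "putamen", label = c(1L, 2L))
  expect_equal(unname(extract_roi_means(vol, defs)["putamen"]), 1.6)

  vol2 <- flat_volume(list(`1` = rep(1.0, 10), `2` = rep(2.0, 30),
                           `99` = rep(1, 3)), region_map = rm_)
  m <- extract_roi_means(vol2, defs)
  expect_equal(unname(m["putamen"]), 1.75)  # union mean, not (1+2)/2
  expect_identical(unname(attr(m, "n_voxels")["putamen"]), 40L)
  expect_error(extract_roi_means(vol2, tibble::tibble(roi = "x", label = 5L)),
               "missing label")
})

test_that("ROI means are invariant to label renumbering", {
  spec <- gm_wm_spec(gm_ratio = 1.3, wm_ratio = 2.0, noise_sd = 0.05)
  vol <- generate_phantom(spec)
  defs <- tibble::tibble(roi = c("gm", "wm"), label = c(1L, 2L))
  m1 <- extract_roi_means(vol, defs)
  # renumber: 1 -> 11, 2 -> 22
  vol2 <- vol
  vol2$labels[vol$labels == 1L] <- 11L
  vol2$labels[vol$labels == 2L] <- 22L
  vol2$region_map$label <- c(11L, 22L, 99L)
  m2 <- extract_roi_means(vol2, tibble::tibble(roi = c("gm", "wm"),
                                               label = c(11L, 22L)))
  expect_identical(unname(m1), unname(m2))
})

test_that("CCTXR is the weighted average of the composite ROI SUVRs", {
  vals <- c(frontal = 1.42, parietal = 1.42, temporal = 1.42)
  expect_equal(compute_cctxr(vals, c(frontal = 3, parietal = 1,
                                     temporal = 10)), 1.42)
  vals2 <- c(frontal = 1.2, parietal = 1.4, temporal = 1.6)
  expect_equal(compute_cctxr(vals2, c(frontal = 1, parietal = 1,
                                      temporal = 2)), 1.45)
  expect_error(compute_cctxr(vals2, c(frontal = 1, parietal = 1)),
               "cover exactly")
  expect_error(compute_cctxr(vals2, c(frontal = 0, parietal = 0,
                                      temporal = 0)))
  expect_error(compute_cctxr(c(frontal = 1.2), composite_rois = "parietal"),
               "absent")
})

test_that("voxel-count weights make CCTXR equal the direct composite mean", {
  vol <- generate_phantom(phantom_spec(noise_sd = 0.1, seed = 3L))
  ref <- compute_reference_value(vol, 99L, "mean")
  suvr <- compute_suvr_image(vol, ref)
  defs <- roi_definitions(vol$region_map)
  m <- extract_roi_means(suvr, defs)
  cctxr <- compute_cctxr(m)  # default: voxel-count weights
  comp_labels <- defs$label[defs$roi %in% c("frontal", "parietal",
                                            "temporal")]
  direct <- mean(suvr$uptake[suvr$labels %in% comp_labels])
  expect_equal(cctxr, direct, tolerance = 1e-12)
  # CCTXR lies within the range of its component ROI SUVRs
  comp <- m[c("frontal", "parietal", "temporal")]
  expect_gte(cctxr, min(comp))
  expect_lte(cctxr, max(comp))
})

test_that("reference self-ratio on the SUVR image is exactly 1 for the mean", {
  vol <- generate_phantom(gm_wm_spec(noise_sd = 0.2, seed = 8L))
  ref <- compute_reference_value(vol, 99L, "mean")
  suvr <- compute_suvr_image(vol, ref)
  expect_equal(compute_reference_value(suvr, 99L, "mean"), 1,
               tolerance = 1e-12)
  # and for the median statistic, the median self-ratio is 1
  refm <- compute_reference_value(vol, 99L, "median")
  suvrm <- compute_suvr_image(vol, refm)
  expect_equal(compute_reference_value(suvrm, 99L, "median"), 1,
               tolerance = 1e-12)
})

test_that("reference benchmarking ranks clean over contaminated references", {
  # WM ratio varies across subjects -> a reference containing WM inherits
  # that variability; the clean cerebellar reference does not.
  make_vol <- function(wm_ratio, gm_ratio, seed)
    generate_phantom(gm_wm_spec(gm_ratio = gm_ratio, wm_ratio = wm_ratio,
                                noise_sd = 0.02, seed = seed))
  set.seed(1)
  hc <- lapply(1:6, function(i) make_vol(1.6 + 0.5 * runif(1), 1.2, i))
  ad <- lapply(1:6, function(i) make_vol(1.6 + 0.5 * runif(1), 1.8, 100 + i))
  defs <- tibble::tibble(roi = c("frontal", "parietal", "temporal"),
                         label = c(1L, 1L, 1L))
  cands <- list(
    clean = list(labels = 99L, statistic = "mean"),
    contaminated = list(labels = c(99L, 2L), statistic = "mean")
  )
  tab <- evaluate_reference_regions(hc, ad, cands, roi_defs = defs)
  expect_lt(tab$hc_cv[tab$candidate == "clean"],
            tab$hc_cv[tab$candidate == "contaminated"])
  expect_true(tab$best_cv[tab$candidate == "clean"])
  # identical candidates give identical results
  tab2 <- evaluate_reference_regions(hc, ad,
                                     list(a = cands$clean, b = cands$clean),
                                     roi_defs = defs)
  expect_equal(tab2$hc_cv[1], tab2$hc_cv[2])
  expect_equal(tab2$cohens_d[1], tab2$cohens_d[2])
})

test_that("identical group distributions give a near-zero effect size", {
  vols <- lapply(1:8, function(i)
    generate_phantom(gm_wm_spec(gm_ratio = 1.3, noise_sd = 0.05,
                                seed = 200L + i)))
  defs <- tibble::tibble(roi = c("frontal", "parietal", "temporal"),
                         label = c(1L, 1L, 1L))
  tab <- evaluate_reference_regions(
    vols[1:4], vols[5:8],
    list(ref = list(labels = 99L, statistic = "mean")), roi_defs = defs)
  expect_lt(abs(tab$cohens_d), 1.5)  # no systematic separation
})

test_that("labeled volumes survive a NIfTI round trip", {
  vol <- generate_phantom(gm_wm_spec(noise_sd = 0.05, seed = 4L))
  up <- withr::local_tempfile(fileext = ".nii.gz")
  lb <- withr::local_tempfile(fileext = ".nii.gz")
  write_labeled_volume(vol, up, lb)
  back <- read_labeled_volume(up, lb, vol$region_map)
  expect_equal(back$uptake, vol$uptake, tolerance = 1e-6)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$voxel_size, vol$voxel_size)
})
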