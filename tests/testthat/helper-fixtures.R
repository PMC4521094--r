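# Small in-code fixtures shared across test files.

# A labeled volume built directly from per-region constant values.
# regions: list(name = list(label, value, nvox)) laid out consecutively
# along a 1-voxel-thick column (geometry is irrelevant to quantification).
flat_volume <- function(values_by_label, region_map = NULL) {
  labs <- rep(as.integer(names(values_by_label)),
              vapply(values_by_label, length, integer(1)))
  up <- unlist(values_by_label, use.names = FALSE)
  n <- length(up)
  dims <- c(n, 1L, 1L)
  if (is.null(region_map))
    region_map <- tibble::tibble(
      label = as.integer(names(values_by_label)),
      name = paste0("r", names(values_by_label)),
      roi = paste0("r", names(values_by_label))
    )
  labeled_volume(array(up, dims), array(labs, dims), region_map)
}

# Three-region phantom spec: a GM region next to a WM region plus a
# reference slab, for spill-over and reference-contamination tests.
gm_wm_spec <- function(gm_ratio = 1.2, wm_ratio = 2.0, noise_sd = 0,
                       fwhm = 0, seed = 1L, grid = c(10L, 10L, 12L)) {
  regions <- tibble::tibble(
    label = c(1L, 2L, 99L),
    name = c("gm", "wm", "cerebellum"),
    roi = c("gm", "wm", "cerebellum"),
    side = "B",
    tissue = c("GM", "WM", "GM"),
    ratio = c(gm_ratio, wm_ratio, 1.0)
  )
  phantom_spec(grid_shape = grid, regions = regions, reference_label = 99L,
               noise_sd = noise_sd, smoothing_fwhm_mm = fwhm, seed = seed)
}

# Brute-force AUC over all positive-negative pairs, ties counted 1/2.
auc_pairwise <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Exhaustive closest-to-(0,1) search over every candidate threshold
# (all midpoints plus sentinels), the oracle for optimal_cutoff.
brute_force_optimum <- function(pos, neg) {
  uniq <- sort(unique(c(pos, neg)))
  thr <- c(-Inf, if (length(uniq) > 1) (head(uniq, -1) + uniq[-1]) / 2, Inf)
  best <- NULL
  for (t in thr) {
    se <- mean(pos > t); sp <- mean(neg <= t)
    d <- sqrt((1 - se)^2 + (1 - sp)^2)
    if (is.null(best) || d < best$d - 1e-12 ||
        (abs(d - best$d) <= 1e-12 &&
         (se > best$se + 1e-12 ||
          (abs(se - best$se) <= 1e-12 && t < best$t))))
      best <- list(t = t, se = se, sp = sp, d = d)
  }
  best
}

default_stratum <- function(diagnosis, age_group) {
  s <- default_strata()
  s[s$diagnosis == diagnosis & s$age_group == age_group, ]
}
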