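# End-to-end orchestration: generate -> quantify -> threshold -> harmonize
# -> mixture -> stats, with one top-level seed, per-stage derived seeds, a
# hashed output manifest and a deterministic text report.

#' Configure a pipeline scenario
#'
#' The default scenario ("paper-default") generates the calibrated
#' Florbetapir cohort (726 subjects in six diagnosis-by-age strata), one
#' demonstration phantom, derives ROC cut-offs per age group, applies the
#' published Florbetapir cut-off 1.34 for positivity tables, harmonizes the
#' PIB cut-off 1.42 through the published linear relation y = 1.13x - 0.28,
#' fits one- and two-component mixtures per stratum and runs the cohort
#' statistics.
#'
#' @param name scenario name.
#' @param cohort a [cohort_config()]; its seed is overridden by the
#'   scenario seed.
#' @param phantom a [phantom_spec()] for the demonstration volume.
#' @param apply_cutoff cut-off used for the positivity tables.
#' @param harmonization list with `slope`, `intercept`, `source_cutoff`.
#' @param mixture_restarts EM restarts per two-component fit.
#' @param ci_method AUC confidence-interval method.
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @return A `run_config` object.
#' @export
scenario_config <- function(name = "paper-default",
                            cohort = cohort_config(),
                            phantom = phantom_spec(noise_sd = 0.05,
                                                   smoothing_fwhm_mm = 4),
                            apply_cutoff = 1.34,
                            harmonization = list(slope = 1.13,
                                                 intercept = -0.28,
                                                 source_cutoff = 1.42),
                            mixture_restarts = 20L,
                            ci_method = "delong",
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(phantom, "phantom_spec"),
            apply_cutoff > 0,
            all(c("slope", "intercept", "source_cutoff") %in%
                  names(harmonization)))
  structure(
    list(name = name, cohort = cohort, phantom = phantom,
         apply_cutoff = apply_cutoff, harmonization = harmonization,
         mixture_restarts = as.integer(mixture_restarts),
         ci_method = ci_method, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run a scenario end to end
#'
#' Executes all stages in order, writes every intermediate table under
#' `out_dir` and returns the result bundle plus a manifest (stage seeds,
#' package version, md5 hash of every output file). Re-running with the
#' same configuration and seed reproduces byte-identical tables.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `manifest`, `results`, `out_dir`.
#' @export
run_scenario <- function(config = scenario_config(), out_dir = tempfile("amypet_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- vapply(c("phantom", "cohort", "threshold", "mixture", "stats"),
                  function(s) stage_seed(config$seed, s), integer(1))
  results <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- phantom + quantification demo ----------------------------------------
  results$phantom <- run_stage("phantom", {
    spec <- config$phantom
    spec$seed <- seeds[["phantom"]]
    vol <- generate_phantom(spec)
    write_labeled_volume(vol, file.path(out_dir, "phantom_uptake.nii.gz"),
                         file.path(out_dir, "phantom_labels.nii.gz"))
    q <- quantify_volume(vol, statistic = "mean", subject_id = "phantom-01")
    write.csv(q, file.path(out_dir, "phantom_quant.csv"), row.names = FALSE)
    q
  })

  # -- cohort ---------------------------------------------------------------
  cohort <- run_stage("cohort", {
    cc <- config$cohort
    cc$seed <- seeds[["cohort"]]
    co <- generate_cohort(cc)
    write_cohort_csv(co, file.path(out_dir, "cohort.csv"))
    co
  })
  results$cohort <- cohort

  # -- threshold ------------------------------------------------------------
  results$threshold <- run_stage("threshold", {
    th <- list()
    for (grp in c("younger", "older")) {
      sub <- cohort[cohort$age_group == grp &
                      cohort$diagnosis %in% c("HC", "AD"), ]
      rc <- roc_curve(sub$cctxr, sub$diagnosis, positive = "AD",
                      ci_method = config$ci_method,
                      seed = seeds[["threshold"]])
      oc <- optimal_cutoff(rc)
      th[[grp]] <- list(roc = rc, optimum = oc)
    }
    pos <- classify_amyloid(
      cohort$cctxr, config$apply_cutoff,
      strata = paste(cohort$age_group, cohort$diagnosis, sep = "_"))
    write.csv(pos$table, file.path(out_dir, "positivity.csv"),
              row.names = FALSE)
    roc_tab <- do.call(rbind, lapply(names(th), function(g)
      tibble::add_column(th[[g]]$roc$curve, age_group = g, .before = 1)))
    write.csv(roc_tab, file.path(out_dir, "roc_curves.csv"),
              row.names = FALSE)
    sub_y <- cohort[cohort$age_group == "younger" &
                      cohort$diagnosis %in% c("HC", "AD"), ]
    roi_cols <- grep("^suvr_", names(cohort), value = TRUE)
    ranking <- rank_roi_discrimination(sub_y[roi_cols], sub_y$diagnosis)
    write.csv(ranking, file.path(out_dir, "roi_ranking.csv"),
              row.names = FALSE)
    cut_json <- list(
      applied_cutoff = config$apply_cutoff,
      younger = th$younger$optimum, older = th$older$optimum,
      younger_auc = th$younger$roc$auc, younger_auc_ci = th$younger$roc$auc_ci,
      older_auc = th$older$roc$auc, older_auc_ci = th$older$roc$auc_ci)
    jsonlite::write_json(cut_json, file.path(out_dir, "cutoffs.json"),
                         auto_unbox = TRUE, digits = NA)
    list(by_group = th, positivity = pos$table, ranking = ranking)
  })

  # -- harmonization --------------------------------------------------------
  results$harmonization <- run_stage("harmonize", {
    h <- config$harmonization
    map <- linear_map(h$slope, h$intercept)
    conv <- convert_cutoff(map, h$source_cutoff)
    out <- list(slope = h$slope, intercept = h$intercept,
                source_cutoff = h$source_cutoff,
                converted_cutoff = conv$value,
                converted_cutoff_display = conv$display)
    jsonlite::write_json(out, file.path(out_dir, "harmonization.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  # -- mixture --------------------------------------------------------------
  results$mixture <- run_stage("mixture", {
    strata <- unique(cohort[c("diagnosis", "age_group")])
    fits <- list()
    dens_rows <- list()
    for (i in seq_len(nrow(strata))) {
      d <- strata$diagnosis[i]; g <- strata$age_group[i]
      key <- paste(g, d, sep = "_")
      v <- cohort$cctxr[cohort$diagnosis == d & cohort$age_group == g]
      f1 <- fit_gaussian_mixture(v, K = 1L, seed = seeds[["mixture"]])
      f2 <- fit_gaussian_mixture(v, K = 2L,
                                 n_restarts = config$mixture_restarts,
                                 seed = seeds[["mixture"]])
      sel <- select_model(f1, f2)
      nt <- test_normality(v, n_mc = 2000L,
                           seed = stage_seed(config$seed, "normality"))
      fits[[key]] <- list(selected_K = sel$K, delta_bic = sel$delta_bic,
                          normality_p = nt$p,
                          fit = sel$chosen[c("K", "weights", "means",
                                             "sds", "loglik", "bic")])
      grid <- seq(0.6, 2.6, by = 0.02)
      dens_rows[[key]] <- tibble::tibble(
        stratum = key, cctxr = grid,
        density = dgmix(grid, sel$chosen$weights, sel$chosen$means,
                        sel$chosen$sds))
    }
    jsonlite::write_json(fits, file.path(out_dir, "mixture_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(do.call(rbind, dens_rows),
              file.path(out_dir, "density_data.csv"), row.names = FALSE)
    fits
  })

  # -- cohort statistics ----------------------------------------------------
  results$stats <- run_stage("stats", {
    roi_cols <- grep("^suvr_|^cctxr$", names(cohort), value = TRUE)
    anova_one <- function(dx) {
      sub <- cohort[cohort$diagnosis == dx, ]
      rows <- lapply(roi_cols, function(rc) {
        at <- two_way_anova(sub[[rc]], sub$age_group, sub$apoe4)
        tibble::add_column(tibble::as_tibble(at),
                           response = sub(("^suvr_"), "", rc), .before = 1)
      })
      do.call(rbind, rows)
    }
    anova_hc <- anova_one("HC")
    anova_ad <- anova_one("AD")
    write.csv(anova_hc, file.path(out_dir, "anova_hc.csv"),
              row.names = FALSE)
    write.csv(anova_ad, file.path(out_dir, "anova_ad.csv"),
              row.names = FALSE)
    ad <- cohort[cohort$diagnosis == "AD", ]
    apoe_tab <- table(ad$age_group, ad$apoe4)
    apoe_test <- chi_squared_test(apoe_tab)
    list(anova_hc = anova_hc, anova_ad = anova_ad,
         ad_apoe4_by_age = apoe_test)
  })

  files <- sort(list.files(out_dir, full.names = FALSE))
  manifest <- list(
    scenario = config$name, seed = config$seed,
    stage_seeds = as.list(seeds),
    package_version = as.character(utils::packageVersion("amypet")),
    files = lapply(setNames(files, files), function(f)
      unname(md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results, out_dir = out_dir))
}

#' Render a text report from a result bundle
#'
#' Deterministic, human-readable summary of whichever stages the bundle
#' contains; missing stages are listed explicitly. SUVR/CCTXR values are
#' shown at 2 decimals (half-even) and proportions as integer percentages,
#' the display precision of the published tables.
#'
#' @param bundle the list returned by [run_scenario()], or any subset of
#'   its `results` element.
#' @return Character vector of report lines.
#' @export
make_report <- function(bundle) {
  res <- if (!is.null(bundle$results)) bundle$results else bundle
  lines <- c("amypet scenario report",
             "======================")
  stage_names <- c("phantom", "cohort", "threshold", "harmonization",
                   "mixture", "stats")
  for (s in setdiff(stage_names, names(res)))
    lines <- c(lines, sprintf("[%s] MISSING", s))
  if (!is.null(res$phantom)) {
    lines <- c(lines, "", "[phantom]",
               sprintf("  reference value %.2f (%s), CCTXR %.2f",
                       res$phantom$reference_value,
                       res$phantom$reference_statistic, res$phantom$cctxr))
  }
  if (!is.null(res$cohort)) {
    tab <- table(res$cohort$age_group, res$cohort$diagnosis)
    lines <- c(lines, "", "[cohort]",
               sprintf("  %d subjects: %s", nrow(res$cohort),
                       paste(sprintf("%s/%s n=%d",
                                     rep(rownames(tab), ncol(tab)),
                                     rep(colnames(tab), each = nrow(tab)),
                                     as.vector(tab)), collapse = ", ")))
  }
  if (!is.null(res$threshold)) {
    lines <- c(lines, "", "[threshold]")
    for (g in names(res$threshold$by_group)) {
      bg <- res$threshold$by_group[[g]]
      lines <- c(lines, sprintf(
        "  %s: AUC %.3f [%.3f-%.3f]; optimum %.2f (sens %.0f%%, spec %.0f%%)",
        g, bg$roc$auc, bg$roc$auc_ci[1], bg$roc$auc_ci[2],
        bg$optimum$cutoff, 100 * bg$optimum$sensitivity,
        100 * bg$optimum$specificity))
    }
    pt <- res$threshold$positivity
    lines <- c(lines, sprintf("  positivity at applied cut-off: %s",
                              paste(sprintf("%s %.0f%%", pt$stratum,
                                            pt$pct_positive),
                                    collapse = ", ")))
  }
  if (!is.null(res$harmonization)) {
    h <- res$harmonization
    lines <- c(lines, "", "[harmonization]",
               sprintf("  y = %.2fx %+.2f: source cut-off %.2f -> %.2f",
                       h$slope, h$intercept, h$source_cutoff,
                       h$converted_cutoff_display))
  }
  if (!is.null(res$mixture)) {
    lines <- c(lines, "", "[mixture]")
    for (key in names(res$mixture)) {
      f <- res$mixture[[key]]
      lines <- c(lines, sprintf(
        "  %s: K = %d (dBIC %.1f), means %s", key, f$selected_K,
        f$delta_bic, paste(sprintf("%.2f", f$fit$means), collapse = " / ")))
    }
  }
  if (!is.null(res$stats)) {
    sig <- res$stats$anova_hc
    sig <- sig[sig$effect == "apoe4" & !is.na(sig$p) & sig$p < 0.05, ]
    lines <- c(lines, "", "[stats]",
               sprintf("  HC ANOVA: ApoE4 main effect significant in %d responses",
                       nrow(sig)),
               sprintf("  AD ApoE4-by-age chi-squared p = %.3g",
                       res$stats$ad_apoe4_by_age$p))
  }
  lines
}
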