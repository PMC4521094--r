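# Cohort construction and group-level inference: seeded greedy covariate
# matching, two-way type III ANOVA, chi-squared tests, Spearman rank
# correlation, Cohen's kappa and d, and percent agreement.

#' Randomized 1:1 covariate matching
#'
#' For each reference subject (visited in seeded random order), selects the
#' nearest unused pool subject that agrees exactly on `exact_vars` (e.g.
#' sex) and minimizes the summed squared standardized distance over
#' `nearest_vars` (e.g. age, MMSE; each scaled by its pool SD). Greedy,
#' without replacement.
#'
#' @param pool,reference cohort tibbles with a `subject_id` column.
#' @param exact_vars character, variables requiring exact agreement.
#' @param nearest_vars character, variables matched by scaled distance.
#' @param seed integer seed for the visiting order.
#' @return A `match_result`: `matches` (tibble of reference_id, matched_id,
#'   distance), `balance` (standardized mean differences matched vs
#'   reference), `seed`.
#' @export
match_cohorts <- function(pool, reference, exact_vars = "sex",
                          nearest_vars = c("age", "mmse"), seed = 1L) {
  stopifnot(nrow(pool) >= nrow(reference),
            all(c(exact_vars, nearest_vars, "subject_id") %in% names(pool)),
            all(c(exact_vars, nearest_vars, "subject_id") %in%
                  names(reference)))
  # strata feasibility: every exact-vars cell must be large enough
  if (length(exact_vars)) {
    ref_cells <- table(interaction(reference[exact_vars], drop = FALSE))
    pool_cells <- table(interaction(pool[exact_vars], drop = FALSE))
    short <- names(ref_cells)[ref_cells >
      ifelse(is.na(pool_cells[names(ref_cells)]), 0,
             pool_cells[names(ref_cells)])]
    if (length(short))
      stop("pool exhausted for strata: ", paste(short, collapse = ", "))
  }
  scales <- vapply(nearest_vars, function(v) {
    s <- sd(pool[[v]]); if (is.na(s) || s == 0) 1 else s
  }, numeric(1))
  set.seed(seed)
  order_ref <- sample.int(nrow(reference))
  used <- rep(FALSE, nrow(pool))
  res <- vector("list", nrow(reference))
  for (i in order_ref) {
    ok <- !used
    for (v in exact_vars)
      ok <- ok & (pool[[v]] == reference[[v]][i])
    if (!any(ok))
      stop("pool exhausted while matching reference subject ",
           reference$subject_id[i])
    d <- rep(0, nrow(pool))
    for (v in seq_along(nearest_vars)) {
      vn <- nearest_vars[v]
      d <- d + ((pool[[vn]] - reference[[vn]][i]) / scales[v])^2
    }
    d[!ok] <- Inf
    j <- which.min(d)
    used[j] <- TRUE
    res[[i]] <- tibble::tibble(reference_id = reference$subject_id[i],
                               matched_id = pool$subject_id[j],
                               distance = sqrt(d[j]))
  }
  matches <- do.call(rbind, res)
  sel <- pool[match(matches$matched_id, pool$subject_id), ]
  bal <- vapply(nearest_vars, function(v) {
    s <- sd(c(sel[[v]], reference[[v]]))
    if (is.na(s) || s == 0) 0 else (mean(sel[[v]]) - mean(reference[[v]])) / s
  }, numeric(1))
  structure(
    list(matches = matches,
         balance = tibble::tibble(variable = nearest_vars, smd = unname(bal)),
         seed = seed),
    class = "match_result"
  )
}

#' Two-way ANOVA with type III sums of squares
#'
#' Tests the main effects of two two-level factors (age group and ApoE4
#' carrier status in the published analysis) and their interaction on a
#' regional uptake response. Type III sums of squares with sum-to-zero
#' contrasts are used so unbalanced cells are handled as SPSS does. If a
#' design cell is empty, the interaction is inestimable: it is reported as
#' NA and the main effects come from the additive model, with a warning.
#'
#' @param response numeric response (e.g. an ROI SUVR).
#' @param factor_a,factor_b factors (coerced), same length as `response`.
#' @param a_name,b_name effect names used in the output.
#' @return An `AnovaTable` tibble: effect, F, df1, df2, p; cell means and
#'   SDs attached as the `cells` attribute.
#' @export
two_way_anova <- function(response, factor_a, factor_b,
                          a_name = "age_group", b_name = "apoe4") {
  fa <- droplevels(as.factor(factor_a))
  fb <- droplevels(as.factor(factor_b))
  stopifnot(length(response) == length(fa), length(fa) == length(fb))
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("both factors must have at least 2 observed levels")
  cell <- table(fa, fb)
  if (sum(cell >= 2) < 3 || length(response) < 4)
    stop("need >= 2 observations in at least 3 cells")
  dat <- data.frame(y = response, a = fa, b = fb)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  empty_cell <- any(cell == 0)
  if (empty_cell) {
    warning("empty design cell: interaction inestimable, ",
            "main effects from the additive model")
    fit <- lm(y ~ a + b, data = dat)
  } else {
    fit <- lm(y ~ a * b, data = dat)
  }
  a3 <- car::Anova(fit, type = 3)
  rn <- rownames(a3)
  pick <- function(term) {
    i <- match(term, rn)
    if (is.na(i)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(a3[i, "F value"], a3[i, "Df"], a3["Residuals", "Df"], a3[i, "Pr(>F)"])
  }
  eff <- rbind(pick("a"), pick("b"), if (empty_cell)
    c(NA_real_, NA_real_, NA_real_, NA_real_) else pick("a:b"))
  out <- tibble::tibble(
    effect = c(a_name, b_name, paste0(a_name, ":", b_name)),
    F = eff[, 1], df1 = eff[, 2], df2 = eff[, 3], p = eff[, 4]
  )
  cells <- aggregate(dat$y, by = list(a = dat$a, b = dat$b),
                     FUN = function(v) c(mean = mean(v), sd = sd(v),
                                         n = length(v)))
  attr(out, "cells") <- tibble::tibble(
    a = cells$a, b = cells$b, mean = cells$x[, "mean"],
    sd = cells$x[, "sd"], n = as.integer(cells$x[, "n"])
  )
  class(out) <- c("AnovaTable", class(out))
  out
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction by default (matching the published usage);
#' Yates' correction is available behind the `correct` flag.
#'
#' @param counts matrix of nonnegative integer counts (usually 2x2).
#' @param correct apply Yates' continuity correction.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_squared_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: every row and column must have a positive total")
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Spearman rank correlation
#'
#' Midrank-based rho. The p-value is exact (permutation distribution) for
#' n <= 12 without ties and uses the t approximation otherwise.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  p <- if (!ties && n <= 12) {
    cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) >= 1) {
    0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement.
#'
#' @param rater1,rater2 categorical vectors of equal length.
#' @return List with `kappa`, `p_observed`, `p_expected`; `kappa` is NA
#'   (undefined) when expected agreement is 1.
#' @export
cohens_kappa <- function(rater1, rater2) {
  stopifnot(length(rater1) == length(rater2), length(rater1) >= 1)
  levels_all <- sort(unique(c(as.character(rater1), as.character(rater2))))
  if (length(levels_all) < 2)
    stop("need at least 2 observed categories")
  f1 <- factor(rater1, levels = levels_all)
  f2 <- factor(rater2, levels = levels_all)
  tab <- table(f1, f2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  k <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_
       else (po - pe) / (1 - pe)
  list(kappa = k, p_observed = po, p_expected = pe)
}

#' Percent agreement between two raters
#'
#' @param rater1,rater2 vectors of equal, positive length.
#' @return Proportion of identical labels, in `[0, 1]`.
#' @export
percent_agreement <- function(rater1, rater2) {
  stopifnot(length(rater1) == length(rater2))
  if (!length(rater1)) stop("empty input")
  mean(as.character(rater1) == as.character(rater2))
}

#' Cohen's d standardized mean difference
#'
#' `(mean(groupA) - mean(groupB)) / pooled SD`, with the pooled SD using
#' n-1 weighting.
#'
#' @param group_a,group_b numeric vectors, both `n >= 2`.
#' @return Scalar d; NA (undefined) when the pooled SD is 0.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}
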