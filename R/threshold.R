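# Amyloid-positivity cut-offs: empirical ROC with DeLong confidence
# intervals, closest-to-(0,1) optimal-point selection, strict-threshold
# classification, per-ROI discrimination ranking and cross-tracer cut-off
# harmonization via the regional-mean linear relation.

#' Empirical ROC curve for a continuous amyloid score
#'
#' Positivity at threshold t is `score > t`. The threshold grid consists of
#' the midpoints between adjacent distinct pooled scores plus -Inf/+Inf
#' sentinels, so every attainable (sensitivity, specificity) pair appears
#' exactly once. The AUC is the trapezoidal area, equal to the Mann-Whitney
#' statistic with ties counted one half; its 95% CI uses the DeLong
#' placement-value variance estimate (a stratified bootstrap CI is
#' available via `ci_method = "bootstrap"`).
#'
#' @param scores numeric scores (higher = more amyloid).
#' @param labels class labels, same length.
#' @param positive label of the positive (disease) class.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed seed for the bootstrap.
#' @return A `roc_result`: list with `curve` (tibble of threshold,
#'   sensitivity, specificity), `auc`, `auc_ci`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = "AD",
                      ci_method = c("delong", "bootstrap"),
                      boot_n = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (!length(pos) || !length(neg))
    stop("both classes must be non-empty (positive class: ", positive, ")")
  uniq <- sort(unique(c(pos, neg)))
  thr <- c(-Inf, if (length(uniq) > 1) (head(uniq, -1) + uniq[-1]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  auc <- auc_mann_whitney(pos, neg)
  ci <- if (ci_method == "delong") {
    delong_ci(pos, neg)
  } else {
    set.seed(seed)
    reps <- replicate(boot_n, auc_mann_whitney(
      sample(pos, replace = TRUE), sample(neg, replace = TRUE)))
    unname(quantile(reps, c(0.025, 0.975)))
  }
  structure(
    list(curve = tibble::tibble(threshold = thr, sensitivity = sens,
                                specificity = spec),
         auc = auc, auc_ci = ci, ci_method = ci_method,
         n_pos = length(pos), n_neg = length(neg), positive = positive),
    class = "roc_result"
  )
}

# AUC as the Mann-Whitney probability with ties counted 1/2, computed from
# midranks (O(n log n)).
auc_mann_whitney <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n0 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance via placement values.
delong_ci <- function(pos, neg, level = 0.95) {
  n1 <- length(pos); n0 <- length(neg)
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  auc <- mean(v10)
  s <- if (n1 > 1) var(v10) / n1 else 0
  s <- s + if (n0 > 1) var(v01) / n0 else 0
  z <- qnorm(1 - (1 - level) / 2)
  pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(s)))
}

#' Optimal cut-off: the ROC point closest to (0, 1)
#'
#' Returns the threshold minimizing the Euclidean distance
#' sqrt((1 - sensitivity)^2 + (1 - specificity)^2) to the ideal corner.
#' Distance ties are broken toward higher sensitivity, then lower
#' threshold. With perfectly separated classes the returned cut-off is the
#' midpoint of the separating gap.
#'
#' @param roc a `roc_result` from [roc_curve()].
#' @return List with `cutoff`, `sensitivity`, `specificity`, `distance`.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  cv <- roc$curve
  d <- sqrt((1 - cv$sensitivity)^2 + (1 - cv$specificity)^2)
  ord <- order(d, -cv$sensitivity, cv$threshold)
  i <- ord[1]
  list(cutoff = cv$threshold[i], sensitivity = cv$sensitivity[i],
       specificity = cv$specificity[i], distance = d[i])
}

#' Classify amyloid positivity at a cut-off
#'
#' Positivity is strict: a value exactly equal to the cut-off is negative.
#'
#' @param values numeric CCTXR values.
#' @param cutoff positive scalar cut-off.
#' @param strata optional factor/character of the same length; when given,
#'   the count table is reported per stratum.
#' @return List with `positive` (logical vector) and `table` (tibble of
#'   stratum, n, n_positive, pct_positive).
#' @export
classify_amyloid <- function(values, cutoff, strata = NULL) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  pos <- values > cutoff
  if (is.null(strata)) strata <- rep("all", length(values))
  tab <- aggregate(pos, by = list(stratum = as.character(strata)),
                   FUN = function(p) c(n = length(p), n_positive = sum(p)))
  out <- tibble::tibble(
    stratum = tab$stratum,
    n = as.integer(tab$x[, "n"]),
    n_positive = as.integer(tab$x[, "n_positive"])
  )
  out$pct_positive <- 100 * out$n_positive / out$n
  list(positive = pos, table = out)
}

#' Rank ROIs by HC-vs-AD discrimination
#'
#' Computes the ROC AUC (with CI) of every ROI score and ranks ROIs in
#' descending AUC order (ties broken alphabetically for a stable order).
#' When a second tracer's scores are supplied, the rank shift of each ROI
#' relative to the first tracer's ranking is reported.
#'
#' @param roi_scores data frame, one column per ROI.
#' @param labels class labels for the rows.
#' @param roi_scores2 optional second tracer's data frame (same ROIs).
#' @param positive positive class label.
#' @return Tibble with per-ROI `auc`, `ci_lo`, `ci_hi`, `rank` and, with a
#'   second tracer, `auc2`, `rank2`, `rank_shift` (`rank - rank2`; positive
#'   means the ROI ranks better under the second tracer).
#' @export
rank_roi_discrimination <- function(roi_scores, labels, roi_scores2 = NULL,
                                    positive = "AD") {
  roi_scores <- as.data.frame(roi_scores)
  if (ncol(roi_scores) < 2) stop("need at least 2 ROIs to rank")
  one <- function(df) {
    res <- lapply(names(df), function(r) {
      rc <- roc_curve(df[[r]], labels, positive = positive)
      tibble::tibble(roi = r, auc = rc$auc, ci_lo = rc$auc_ci[1],
                     ci_hi = rc$auc_ci[2])
    })
    out <- do.call(rbind, res)
    out$rank <- rank_desc(out$auc, out$roi)
    out
  }
  a <- one(roi_scores)
  if (!is.null(roi_scores2)) {
    roi_scores2 <- as.data.frame(roi_scores2)
    stopifnot(setequal(names(roi_scores), names(roi_scores2)))
    b <- one(roi_scores2[names(roi_scores)])
    a$auc2 <- b$auc
    a$ci2_lo <- b$ci_lo
    a$ci2_hi <- b$ci_hi
    a$rank2 <- b$rank
    a$rank_shift <- a$rank - a$rank2
  }
  a[order(a$rank), ]
}

rank_desc <- function(auc, name) {
  ord <- order(-auc, name)
  rk <- integer(length(auc))
  rk[ord] <- seq_along(auc)
  rk
}

#' Fit the cross-tracer regional-mean linear relation
#'
#' Ordinary least squares of tracer-B ROI mean SUVRs on tracer-A ROI mean
#' SUVRs, with the Spearman rank correlation (midranks; exact p for n <= 12
#' without ties, t approximation otherwise) and the R-squared of the fit.
#'
#' @param means_a,means_b per-ROI mean SUVRs for the two tracers, same ROI
#'   order, `n >= 3`.
#' @param group optional label for the subject group the means came from.
#' @return A `linear_map`: list with `slope`, `intercept`, `rho`, `p`,
#'   `r_squared`, `n`, `group`.
#' @export
fit_cross_tracer_line <- function(means_a, means_b, group = NULL) {
  stopifnot(length(means_a) == length(means_b), length(means_a) >= 3)
  if (var(means_a) == 0) stop("zero variance in tracer-A means")
  fit <- lm(means_b ~ means_a)
  sp <- spearman(means_a, means_b)
  linear_map(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    rho = sp$rho, p = sp$p, r_squared = cor(means_a, means_b)^2,
    n = length(means_a), group = group
  )
}

#' Construct a cross-tracer linear map
#'
#' Container for a fitted (or published) linear relation between two
#' tracers' composite-ratio scales.
#'
#' @param slope,intercept coefficients of `y = slope * x + intercept`.
#' @param rho,p,r_squared,n,group optional fit diagnostics.
#' @return A `linear_map` object.
#' @export
linear_map <- function(slope, intercept, rho = NA_real_, p = NA_real_,
                       r_squared = NA_real_, n = NA_integer_, group = NULL) {
  stopifnot(is.numeric(slope), is.numeric(intercept))
  if (!is.na(r_squared)) stopifnot(r_squared >= 0, r_squared <= 1)
  if (!is.na(rho)) stopifnot(rho >= -1, rho <= 1)
  structure(
    list(slope = slope, intercept = intercept, rho = rho, p = p,
         r_squared = r_squared, n = n, group = group),
    class = "linear_map"
  )
}

#' Convert a cut-off to another tracer's scale
#'
#' Applies the linear map to a cut-off on the source-tracer scale; the
#' published PIB cut-off 1.42 maps through `y = 1.13 x - 0.28` to 1.3246,
#' displayed as 1.32. Display rounding is half-even at 2 decimals; the full
#' precision value is always returned alongside.
#'
#' @param map a `linear_map`.
#' @param cutoff cut-off on the source scale.
#' @return List with `value` (full precision) and `display` (2 decimals).
#' @export
convert_cutoff <- function(map, cutoff) {
  stopifnot(inherits(map, "linear_map"))
  v <- map$slope * cutoff + map$intercept
  list(value = v, display = round(v, 2))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (positive = %s): AUC %.3f [%.3f-%.3f], n+ = %d, n- = %d\n",
              x$positive, x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("linear map: y = %.4f x + %.4f", x$slope, x$intercept))
  if (!is.na(x$rho))
    cat(sprintf("  (rho = %.3f, p = %.3g, R2 = %.3f, n = %d)",
                x$rho, x$p, x$r_squared, x$n))
  cat("\n")
  invisible(x)
}
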