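# Gaussian-mixture decomposition of composite-ratio distributions:
# Lilliefors-corrected normality testing, EM fitting with restarts, BIC
# model selection between one and two components, hard assignment into
# low/high amyloid subpopulations and their demographic characterization.

#' Normality test with Lilliefors correction
#'
#' One-sample Kolmogorov-Smirnov statistic against a normal distribution
#' with mean and SD estimated from the data. Because the parameters are
#' estimated, the naive KS p-value is conservative; the p-value is instead
#' obtained from a seeded Monte-Carlo null (refitting the parameters on
#' each simulated normal sample), the same correction SPSS applies.
#'
#' @param values numeric sample, `n >= 5`.
#' @param n_mc Monte-Carlo replicates for the null distribution.
#' @param seed seed for the Monte-Carlo draw.
#' @return List with `statistic` (the KS D), `p`, `n`, `n_mc`.
#' @export
test_normality <- function(values, n_mc = 10000L, seed = 1L) {
  n <- length(values)
  stopifnot(n >= 5)
  if (sd(values) == 0) stop("zero variance: normality test undefined")
  d_obs <- lilliefors_d(values)
  set.seed(seed)
  d_null <- vapply(seq_len(n_mc),
                   function(i) lilliefors_d(rnorm(n)), numeric(1))
  p <- (1 + sum(d_null >= d_obs)) / (n_mc + 1)
  list(statistic = d_obs, p = p, n = n, n_mc = n_mc)
}

# max |ECDF - Phi_hat| with parameters estimated from the sample; both
# one-sided ECDF gaps are taken, as in the classical KS statistic.
lilliefors_d <- function(x) {
  n <- length(x)
  z <- pnorm(sort(x), mean(x), sd(x))
  max(seq_len(n) / n - z, z - (seq_len(n) - 1) / n)
}

#' Fit a one- or two-component Gaussian mixture by EM
#'
#' For `K = 1` the maximum-likelihood solution is closed form (mean and
#' 1/n-variance). For `K = 2` the EM algorithm is run from multiple starts:
#' the first is a split at the sample median, the second a k-means
#' partition, and the remainder random pairs of data points; the best
#' converged log-likelihood wins. Convergence is declared when the
#' log-likelihood gain drops below `tol` (default 1e-8) or after `max_iter`
#' iterations. Component variances are floored at `1e-4` times the sample
#' variance so no component can collapse onto a single point. Components
#' are reported in ascending mean order.
#'
#' @param values numeric sample, `n > 3 * K`.
#' @param K number of components, 1 or 2.
#' @param n_restarts number of EM starts for `K = 2`.
#' @param seed seed for the random restarts.
#' @param max_iter,tol EM stopping rule.
#' @return A `mixture_fit`: list with `K`, `weights`, `means`, `sds`,
#'   `loglik`, `bic`, `responsibilities` (n x K), `n_iter`, `converged`,
#'   `loglik_trace` (of the winning start), `n`, `seed`.
#' @export
fit_gaussian_mixture <- function(values, K = 2L, n_restarts = 20L, seed = 1L,
                                 max_iter = 500L, tol = 1e-8) {
  n <- length(values)
  stopifnot(K %in% c(1L, 2L), n > 3 * K)
  if (var(values) == 0) {
    if (K == 2) stop("all values identical: a 2-component fit is refused")
    warning("all values identical: returning a degenerate K=1 fit")
    floor_sd <- 1e-6 * max(1, abs(values[1]))
    ll <- sum(dnorm(values, values[1], floor_sd, log = TRUE))
    return(new_mixture_fit(1L, 1, values[1], floor_sd, ll,
                           bic_of(ll, 1L, n), matrix(1, n, 1), 0L, TRUE,
                           ll, n, seed))
  }
  if (K == 1L) {
    mu <- mean(values)
    sg <- sqrt(mean((values - mu)^2))
    ll <- sum(dnorm(values, mu, sg, log = TRUE))
    return(new_mixture_fit(1L, 1, mu, sg, ll, bic_of(ll, 1L, n),
                           matrix(1, n, 1), 0L, TRUE, ll, n, seed))
  }
  var_floor <- 1e-4 * var(values)
  set.seed(seed)
  starts <- em_starts(values, n_restarts)
  best <- NULL
  for (st in starts) {
    fit <- em_run(values, st, max_iter, tol, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$means)
  new_mixture_fit(2L, best$weights[ord], best$means[ord], best$sds[ord],
                  best$loglik, bic_of(best$loglik, 2L, n),
                  best$resp[, ord, drop = FALSE], best$n_iter,
                  best$converged, best$trace, n, seed)
}

# free parameters: K means + K sds + (K-1) weights
bic_of <- function(loglik, K, n) -2 * loglik + (3 * K - 1) * log(n)

em_starts <- function(x, n_restarts) {
  n <- length(x)
  med_split <- split_params(x, x <= median(x))
  starts <- list(med_split)
  if (n_restarts >= 2) {
    km <- tryCatch(kmeans(x, centers = 2, nstart = 1),
                   error = function(e) NULL)
    if (!is.null(km)) starts <- c(starts, list(split_params(x, km$cluster == 1)))
  }
  # on tiny samples the likelihood has isolated near-degenerate optima (one
  # narrow component on a single point); enumerate singleton starts when the
  # restart budget allows, so best-of-restarts can reach them
  if (n + length(starts) <= n_restarts) {
    floor_sd <- 1e-2 * sd(x)
    for (i in seq_len(n)) {
      rest <- x[-i]
      starts <- c(starts, list(list(
        weights = c(1, n - 1) / n, means = c(x[i], mean(rest)),
        sds = c(floor_sd, max(sd(rest), floor_sd, na.rm = TRUE)))))
    }
  }
  while (length(starts) < n_restarts) {
    mu <- sample(x, 2)
    if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * sd(x) / 10
    starts <- c(starts, list(list(weights = c(0.5, 0.5), means = mu,
                                  sds = rep(sd(x), 2))))
  }
  starts
}

split_params <- function(x, in_low) {
  if (all(in_low) || !any(in_low))
    in_low <- x <= median(x)
  lo <- x[in_low]; hi <- x[!in_low]
  sds <- c(sd(lo), sd(hi))
  sds[!is.finite(sds) | sds == 0] <- sd(x) / 4
  list(weights = c(length(lo), length(hi)) / length(x),
       means = c(mean(lo), mean(hi)), sds = sds)
}

em_run <- function(x, start, max_iter, tol, var_floor) {
  n <- length(x)
  w <- start$weights; mu <- start$means; sg <- pmax(start$sds, sqrt(var_floor))
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  resp <- matrix(0.5, n, 2)
  for (it in seq_len(max_iter)) {
    # E step
    dens <- cbind(w[1] * dnorm(x, mu[1], sg[1]),
                  w[2] * dnorm(x, mu[2], sg[2]))
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    resp <- dens / rowsum_
    ll <- sum(log(rowsum_))
    trace <- c(trace, ll)
    if (ll - ll_old < tol && it > 1) { converged <- TRUE; break }
    ll_old <- ll
    # M step
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(pmax(colSums(resp * (outer(x, mu, "-"))^2) / nk, var_floor))
  }
  list(weights = w, means = mu, sds = sg, loglik = ll, resp = resp,
       n_iter = it, converged = converged, trace = trace)
}

new_mixture_fit <- function(K, weights, means, sds, loglik, bic, resp,
                            n_iter, converged, trace, n, seed) {
  structure(
    list(K = K, weights = weights, means = means, sds = sds,
         loglik = loglik, bic = bic, responsibilities = resp,
         n_iter = n_iter, converged = converged, loglik_trace = trace,
         n = n, seed = seed),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture, K = %d (n = %d, logLik %.2f, BIC %.2f)\n",
              x$K, x$n, x$loglik, x$bic))
  for (k in seq_len(x$K))
    cat(sprintf("  comp %d: weight %.3f, mean %.3f, sd %.3f\n",
                k, x$weights[k], x$means[k], x$sds[k]))
  invisible(x)
}

#' Choose between one- and two-component fits by BIC
#'
#' The fit with the lower BIC wins; an exact tie is broken toward the
#' smaller K (parsimony).
#'
#' @param fit1,fit2 `mixture_fit` objects on the same data.
#' @return List with `K` (chosen), `delta_bic` (`BIC(K=2) - BIC(K=1)`;
#'   negative favours two components), `chosen`, `fits`.
#' @export
select_model <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "mixture_fit"), inherits(fit2, "mixture_fit"),
            fit1$n == fit2$n)
  fits <- list(fit1, fit2)[order(c(fit1$K, fit2$K))]
  delta <- fits[[2]]$bic - fits[[1]]$bic
  chosen <- if (delta < 0) fits[[2]] else fits[[1]]
  list(K = chosen$K, delta_bic = delta, chosen = chosen, fits = fits)
}

#' Hard assignment into low/high amyloid subpopulations
#'
#' Each subject is assigned to the component with the larger
#' responsibility; exact ties go to the higher-mean component. Components
#' are already in ascending mean order, so component 1 is the low-amyloid
#' and component 2 the high-amyloid subpopulation.
#'
#' @param fit a two-component `mixture_fit`.
#' @return Character vector of `"low"` / `"high"` labels.
#' @export
assign_components <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (fit$K != 2) stop("component assignment requires a K = 2 fit")
  ifelse(fit$responsibilities[, 2] >= fit$responsibilities[, 1],
         "high", "low")
}

#' Compare low- and high-amyloid subgroups on covariates
#'
#' For each covariate, reports per-subgroup summaries and a test:
#' chi-squared (no continuity correction) for categorical covariates,
#' Welch two-sample t for continuous ones. Tests are suppressed (NA) when
#' either subgroup has fewer than 2 subjects.
#'
#' @param labels `"low"`/`"high"` assignment per subject.
#' @param cohort cohort tibble aligned with `labels`.
#' @param categorical,continuous covariate column names.
#' @return Tibble: covariate, type, low/high summaries, statistic, p.
#' @export
characterize_subgroups <- function(labels, cohort,
                                   categorical = c("apoe4", "sex"),
                                   continuous = c("age", "education",
                                                  "mmse")) {
  stopifnot(length(labels) == nrow(cohort),
            all(labels %in% c("low", "high")))
  if (!any(labels == "low") || !any(labels == "high"))
    stop("both subgroups must be non-empty")
  can_test <- sum(labels == "low") >= 2 && sum(labels == "high") >= 2
  lo <- cohort[labels == "low", ]; hi <- cohort[labels == "high", ]
  rows <- list()
  for (v in intersect(categorical, names(cohort))) {
    x <- as.factor(cohort[[v]])
    top <- levels(x)[length(levels(x))]  # e.g. TRUE for apoe4, "m" for sex
    summ <- function(d) sprintf("%d/%d (%.0f%%)", sum(d[[v]] == top),
                                nrow(d), 100 * mean(d[[v]] == top))
    stat <- p <- NA_real_
    if (can_test && nlevels(droplevels(x)) >= 2) {
      tb <- table(labels, x)
      ct <- suppressWarnings(chisq.test(tb, correct = FALSE))
      stat <- unname(ct$statistic); p <- ct$p.value
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      covariate = v, type = "categorical", low = summ(lo), high = summ(hi),
      statistic = stat, p = p, test = "chi-squared")
  }
  for (v in intersect(continuous, names(cohort))) {
    summ <- function(d) sprintf("%.1f +/- %.1f", mean(d[[v]]), sd(d[[v]]))
    stat <- p <- NA_real_
    if (can_test && sd(cohort[[v]]) > 0) {
      tt <- tryCatch(t.test(lo[[v]], hi[[v]]), error = function(e) NULL)
      if (!is.null(tt)) { stat <- unname(tt$statistic); p <- tt$p.value }
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      covariate = v, type = "continuous", low = summ(lo), high = summ(hi),
      statistic = stat, p = p, test = "t")
  }
  do.call(rbind, rows)
}
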