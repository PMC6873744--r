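#' Cochran / Ruecker heterogeneity statistic
#'
#' Heterogeneity of the per-SNP Wald ratios about the pooled fit. In the
#' `"ivw"` context this is Cochran's Q about the fixed-effect IVW estimate
#' with weights `(beta_exposure / se_outcome)^2` on n - 1 df; in the
#' `"egger"` context it is Ruecker's Q' — the weighted residual sum of
#' squares about the Egger regression — on n - 2 df. p-values from the
#' chi-square upper tail.
#'
#' @param panel An [instrument_panel()].
#' @param context `"ivw"` or `"egger"`.
#' @return List of class `heterogeneity_result`: `statistic`, `df`,
#'   `p_value`, `context`.
#' @export
cochran_q <- function(panel, context = c("ivw", "egger")) {
  context <- match.arg(context)
  s <- panel_stats(panel)
  if (context == "ivw") {
    if (s$n < 2) stop("IVW heterogeneity needs >= 2 instruments")
    w <- (s$bx / s$sy)^2
    ratio <- s$by / s$bx
    b <- sum(w * ratio) / sum(w)
    q <- sum(w * (ratio - b)^2)
    df <- s$n - 1L
  } else {
    if (s$n < 3) stop("Egger heterogeneity needs >= 3 instruments")
    fit <- mr_egger(panel)
    flip <- sign(s$bx)
    bx <- s$bx * flip; by <- s$by * flip
    slope_int <- if (fit$slope$sign_convention == "per_sd_decrease")
      -fit$slope$beta else fit$slope$beta
    res <- by - fit$intercept$estimate - slope_int * bx
    q <- sum(res^2 / s$sy^2)
    df <- s$n - 2L
  }
  structure(list(statistic = q, df = df,
                 p_value = stats::pchisq(q, df, lower.tail = FALSE),
                 context = context),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Heterogeneity (%s): Q = %.4g on %d df, p = %.3g\n",
              x$context, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Leave-one-SNP-out sensitivity analysis
#'
#' Re-estimates the causal effect n times, each time excluding one
#' instrument, to check that no single SNP drives the pooled result.
#'
#' @param panel An [instrument_panel()] with at least 3 instruments.
#' @param method Estimator to use, by name: `"ivw"` (default),
#'   `"maximum_likelihood"`, `"weighted_median"` or `"weighted_mode"`.
#' @param ... Passed to the estimator.
#' @return List of class `loo_result`: `entries` (data frame with one row
#'   per excluded SNP: `excluded`, `n_snps`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `odds_ratio`, ...) and `full_panel_estimate`.
#' @export
leave_one_out <- function(panel, method = "ivw", ...) {
  s <- panel_stats(panel)
  if (s$n < 3) stop("leave-one-out needs >= 3 instruments")
  fun <- switch(method,
                ivw = mr_ivw,
                maximum_likelihood = mr_maximum_likelihood,
                weighted_median = mr_weighted_median,
                weighted_mode = mr_weighted_mode,
                stop("unknown method: ", method))
  conv <- sign_convention(panel)
  entries <- do.call(rbind, lapply(seq_len(s$n), function(i) {
    sub <- instrument_panel(as.data.frame(panel)[-i, , drop = FALSE],
                            sign_convention = conv)
    cbind(data.frame(excluded = panel$snp_id[i], stringsAsFactors = FALSE),
          estimates_table(fun(sub, ...)))
  }))
  structure(list(entries = entries,
                 full_panel_estimate = fun(panel, ...)),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat("Leave-one-out (", x$full_panel_estimate$method, "):\n", sep = "")
  print(x$entries[, c("excluded", "n_snps", "beta", "se", "p_value")])
  cat("full panel: ")
  print(x$full_panel_estimate)
  invisible(x)
}

# leave-one-out IVW slopes (weights 1/sy^2, regression through the origin)
# for observed or simulated betas, via totals
loo_slopes <- function(bx, by, sy) {
  wxy <- bx * by / sy^2
  wxx <- bx^2 / sy^2
  (sum(wxy) - wxy) / (sum(wxx) - wxx)
}

#' MR-PRESSO global and outlier test
#'
#' Residual-sum-of-squares resampling test for horizontal pleiotropy. The
#' observed RSS sums, over SNPs, the squared difference between each outcome
#' beta and its prediction from the leave-one-out IVW slope; by default
#' residuals are standardized by the outcome SE (weights `1/se_outcome^2`),
#' the convention of the reference implementation of this test (set
#' `weighted = FALSE` for raw residuals). Its null distribution is built
#' from `n_sim` parametric simulations under the no-pleiotropy model:
#' exposure betas resampled about their observed values, outcome betas about
#' the leave-one-out fitted values. Per-SNP outlier p-values compare each
#' observed squared residual with its simulated counterparts and are
#' Bonferroni-adjusted across SNPs; when outliers are flagged, a distortion
#' test compares the IVW estimate with and without them against random
#' same-size exclusions.
#'
#' @param panel An [instrument_panel()] with at least 4 instruments.
#' @param n_sim Number of null simulations (minimum 100; the global p is
#'   floored at `1/(n_sim+1)`). Default 5000.
#' @param seed Simulation seed (recorded in the result).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-SNP outlier flags. Default 0.05.
#' @param weighted Standardize residuals by the outcome SE. Default TRUE.
#' @return List of class `presso_result`: `rss_observed`, `global_p`,
#'   `per_snp_outlier_p` (Bonferroni-adjusted, named by rsID), `outliers`,
#'   `distortion_p` (NA when no outliers), `n_sim`, `seed`, `weighted`.
#' @export
mr_presso <- function(panel, n_sim = 5000, seed = 1L, outlier_alpha = 0.05,
                      weighted = TRUE) {
  s <- panel_stats(panel)
  if (s$n < 4) stop("MR-PRESSO needs >= 4 instruments")
  if (n_sim < 100) stop("n_sim must be >= 100 for usable p resolution")
  w <- if (weighted) 1 / s$sy^2 else rep(1, s$n)
  loo <- loo_slopes(s$bx, s$by, s$sy)
  res2_obs <- w * (s$by - loo * s$bx)^2
  rss_obs <- sum(res2_obs)
  set.seed(seed)
  bxs <- matrix(stats::rnorm(s$n * n_sim, s$bx, s$sx), s$n, n_sim)
  bys <- matrix(stats::rnorm(s$n * n_sim, loo * s$bx, s$sy), s$n, n_sim)
  wxy <- bxs * bys / s$sy^2
  wxx <- bxs^2 / s$sy^2
  lb <- (rep(colSums(wxy), each = s$n) - wxy) /
    (rep(colSums(wxx), each = s$n) - wxx)
  res2_sim <- w * (bys - lb * bxs)^2
  rss_sim <- colSums(res2_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + rowSums(res2_sim >= res2_obs)) / (n_sim + 1)
  p_adj <- pmin(1, p_snp * s$n)
  names(p_adj) <- panel$snp_id
  outliers <- panel$snp_id[p_adj < outlier_alpha]
  distortion_p <- NA_real_
  if (length(outliers) > 0 && length(outliers) < s$n - 1) {
    keep <- !(panel$snp_id %in% outliers)
    slope <- function(idx) sum((s$bx * s$by / s$sy^2)[idx]) /
      sum((s$bx^2 / s$sy^2)[idx])
    d_obs <- slope(seq_len(s$n)) - slope(which(keep))
    n_out <- length(outliers)
    d_null <- replicate(1000, {
      drop <- sample.int(s$n, n_out)
      slope(seq_len(s$n)) - slope(setdiff(seq_len(s$n), drop))
    })
    distortion_p <- mean(abs(d_null) >= abs(d_obs))
  }
  structure(list(rss_observed = rss_obs, global_p = global_p,
                 per_snp_outlier_p = p_adj, outliers = outliers,
                 distortion_p = distortion_p, n_sim = n_sim, seed = seed,
                 weighted = weighted),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: observed RSS %.4g, global p = %.3g (%d simulations)\n",
              x$rss_observed, x$global_p, x$n_sim))
  if (length(x$outliers) > 0) {
    cat("outliers:", paste(x$outliers, collapse = ", "))
    if (!is.na(x$distortion_p))
      cat(sprintf(" (distortion p = %.3g)", x$distortion_p))
    cat("\n")
  } else cat("no outlier SNPs flagged\n")
  invisible(x)
}

#' Compare two causal estimates by Cochran's Q
#'
#' Two-estimate heterogeneity test, e.g. an MR estimate against an
#' observational meta-analysis estimate on the same log-OR scale:
#' `Q = (beta_a - beta_b)^2 / (se_a^2 + se_b^2)` on 1 df.
#'
#' @param estimate_a,estimate_b `mr_estimate` objects, or lists with `beta`,
#'   `se` and (optionally) `sign_convention`. Conventions must match.
#' @return A `heterogeneity_result` with context `"estimate_comparison"`.
#' @export
compare_estimates_q <- function(estimate_a, estimate_b) {
  ca <- estimate_a$sign_convention
  cb <- estimate_b$sign_convention
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb))
    stop("estimates use different sign conventions: ", ca, " vs ", cb)
  q <- (estimate_a$beta - estimate_b$beta)^2 /
    (estimate_a$se^2 + estimate_b$se^2)
  structure(list(statistic = q, df = 1L,
                 p_value = stats::pchisq(q, 1, lower.tail = FALSE),
                 context = "estimate_comparison"),
            class = "heterogeneity_result")
}
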