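#' @title Summary-data causal estimators
#' @description Internal helpers shared by the estimators.
#' @name estimators-internal
#' @keywords internal
NULL

panel_stats <- function(panel) {
  list(bx = panel$beta_exposure, sx = panel$se_exposure,
       by = panel$beta_outcome, sy = panel$se_outcome,
       n = nrow(panel))
}

# Wald-ratio variance: first-order delta (outcome error only) or second-order
# (adds the exposure measurement-error term).
ratio_var <- function(bx, sx, by, sy, order = c("delta1", "delta2")) {
  order <- match.arg(order)
  v <- sy^2 / bx^2
  if (order == "delta2") v <- v + by^2 * sx^2 / bx^4
  v
}

new_mr_estimate <- function(method, b_int, se, n_snps, convention,
                            df = NULL, extra = list()) {
  stopifnot(se >= 0)
  beta <- if (convention == "per_sd_decrease") -b_int else b_int
  crit <- if (is.null(df)) stats::qnorm(0.975) else stats::qt(0.975, df)
  p <- if (se == 0) as.numeric(b_int == 0) else if (is.null(df))
    2 * stats::pnorm(-abs(b_int / se)) else 2 * stats::pt(-abs(b_int / se), df)
  if (se == 0 && b_int == 0) p <- 1
  out <- list(method = method, n_snps = n_snps, beta = beta, se = se,
              ci_low = beta - crit * se, ci_high = beta + crit * se,
              p_value = max(p, .Machine$double.xmin),
              odds_ratio = exp(beta),
              or_ci_low = exp(beta - crit * se),
              or_ci_high = exp(beta + crit * se),
              sign_convention = convention)
  structure(c(out, extra), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs, %s): beta %.4g (se %.3g), OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$method, x$n_snps, gsub("_", " ", x$sign_convention), x$beta,
              x$se, x$odds_ratio, x$or_ci_low, x$or_ci_high, x$p_value))
  invisible(x)
}

#' Tidy one or more MR estimates
#'
#' @param x An `mr_estimate`, an `egger_fit`, or a list of them.
#' @return Data frame with one row per estimate, mirroring the usual MR
#'   results-table layout (method, n_snp, beta, se, CI, p, OR).
#' @export
estimates_table <- function(x) {
  if (inherits(x, "mr_estimate")) x <- list(x)
  if (inherits(x, "egger_fit")) x <- list(x$slope)
  x <- lapply(x, function(e) if (inherits(e, "egger_fit")) e$slope else e)
  do.call(rbind, lapply(x, function(e) {
    data.frame(method = e$method, n_snps = e$n_snps, beta = e$beta,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               p_value = e$p_value, odds_ratio = e$odds_ratio,
               or_ci_low = e$or_ci_low, or_ci_high = e$or_ci_high,
               stringsAsFactors = FALSE)
  }))
}

#' Per-SNP Wald ratio estimate
#'
#' The single-instrument causal estimate `beta_outcome / beta_exposure`,
#' with a delta-method standard error (first-order by default, i.e. the
#' exposure is treated as measured without error).
#'
#' @param instr One harmonized instrument: a one-row `instrument_panel` (or
#'   any one-row data frame with the panel columns).
#' @param second_order Include the exposure measurement-error term in the SE.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(instr, second_order = FALSE) {
  s <- panel_stats(instr)
  if (s$n != 1) stop("wald_ratio expects exactly one instrument")
  if (s$bx == 0) stop("undefined Wald ratio: beta_exposure is zero")
  b <- s$by / s$bx
  se <- sqrt(ratio_var(s$bx, s$sx, s$by, s$sy,
                       if (second_order) "delta2" else "delta1"))
  new_mr_estimate("wald_ratio", b, se, 1L, sign_convention(instr))
}

#' Inverse-variance weighted estimate
#'
#' Combines the per-SNP Wald ratios with inverse-variance weights
#' `(beta_exposure / se_outcome)^2`, equivalent to weighted regression of
#' outcome betas on exposure betas through the origin. Under the default
#' multiplicative random-effects model the fixed-effect SE is inflated by
#' `sqrt(Q / (n - 1))` when the heterogeneity statistic exceeds its degrees
#' of freedom (underdispersion is floored, so the SE never drops below the
#' fixed-effect one); the point estimate is identical under both models.
#'
#' @param panel An [instrument_panel()].
#' @param variance_model `"multiplicative_re"` (default) or `"fixed"`.
#' @return An `mr_estimate` (extra fields `Q`, `variance_model`).
#' @export
mr_ivw <- function(panel, variance_model = c("multiplicative_re", "fixed")) {
  variance_model <- match.arg(variance_model)
  s <- panel_stats(panel)
  if (s$n == 0) stop("empty panel")
  if (s$n == 1) return(wald_ratio(panel))
  w <- s$bx^2 / s$sy^2
  ratio <- s$by / s$bx
  b <- sum(w * ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (ratio - b)^2)
  se <- if (variance_model == "multiplicative_re")
    se_fixed * max(1, sqrt(q / (s$n - 1))) else se_fixed
  new_mr_estimate("ivw", b, se, s$n, sign_convention(panel),
                  extra = list(Q = q, variance_model = variance_model))
}

#' Maximum-likelihood estimate
#'
#' Maximizes the joint summary-data likelihood in which each observed
#' exposure beta is normal about a latent instrument effect `gamma_i` and
#' each outcome beta is normal about `beta * gamma_i`, over
#' `(gamma_1..gamma_n, beta)`. Unlike IVW this models the sampling error of
#' the exposure associations. Solved by deterministic coordinate ascent from
#' the IVW start (each conditional update is closed-form); the SE comes from
#' the observed information at the optimum, profiled over the `gamma_i`.
#'
#' @param panel An [instrument_panel()].
#' @param tol Relative convergence tolerance on `beta`. Default 1e-12.
#' @param max_iter Iteration cap; exceeding it is an error carrying the last
#'   iterate. Default 500.
#' @return An `mr_estimate` (extra field `iterations`).
#' @export
mr_maximum_likelihood <- function(panel, tol = 1e-12, max_iter = 500) {
  s <- panel_stats(panel)
  if (s$n == 0) stop("empty panel")
  if (s$n == 1) return(wald_ratio(panel))
  b <- sum(s$bx * s$by / s$sy^2) / sum(s$bx^2 / s$sy^2)
  it <- 0L
  repeat {
    it <- it + 1L
    gamma <- (s$bx / s$sx^2 + b * s$by / s$sy^2) /
      (1 / s$sx^2 + b^2 / s$sy^2)
    b_new <- sum(gamma * s$by / s$sy^2) / sum(gamma^2 / s$sy^2)
    if (abs(b_new - b) <= tol * max(1, abs(b_new))) { b <- b_new; break }
    b <- b_new
    if (it >= max_iter)
      stop("maximum-likelihood fit did not converge after ", max_iter,
           " iterations (last beta = ", signif(b, 6), ")")
  }
  gamma <- (s$bx / s$sx^2 + b * s$by / s$sy^2) / (1 / s$sx^2 + b^2 / s$sy^2)
  # observed information blocks of the negative log-likelihood
  h_gg <- 1 / s$sx^2 + b^2 / s$sy^2
  h_bb <- sum(gamma^2 / s$sy^2)
  h_gb <- (2 * b * gamma - s$by) / s$sy^2
  se <- sqrt(1 / (h_bb - sum(h_gb^2 / h_gg)))
  new_mr_estimate("maximum_likelihood", b, se, s$n, sign_convention(panel),
                  extra = list(iterations = it))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept and weights `1 / se_outcome^2`, after orienting every
#' instrument to its exposure-increasing allele (the fit is not invariant to
#' per-SNP sign flips, so orientation is enforced here). The slope is the
#' causal estimate, robust to directional pleiotropy under the InSIDE
#' assumption; the intercept estimates the average direct (pleiotropic)
#' effect per SNP, and its test is the Egger pleiotropy test. Standard
#' errors use multiplicative residual scaling floored at 1; p-values and CIs
#' use the t distribution with n - 2 df.
#'
#' @param panel An [instrument_panel()] with at least 3 instruments.
#' @return List of class `egger_fit`: `slope` (an `mr_estimate`, method
#'   `"egger_slope"`) and `intercept` (`estimate`, `se`, `p_value`, `df`).
#' @export
mr_egger <- function(panel) {
  s <- panel_stats(panel)
  if (s$n < 3) stop("MR-Egger needs >= 3 instruments")
  flip <- sign(s$bx)
  bx <- s$bx * flip; by <- s$by * flip
  w <- 1 / s$sy^2
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  det <- sw * sxx - swx^2
  slope <- (sw * sxy - swx * swy) / det
  intercept <- (sxx * swy - swx * sxy) / det
  res <- by - intercept - slope * bx
  df <- s$n - 2L
  sigma2 <- max(1, sum(w * res^2) / df)
  se_slope <- sqrt(sigma2 * sw / det)
  se_int <- sqrt(sigma2 * sxx / det)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df)
  slope_est <- new_mr_estimate("egger_slope", slope, se_slope, s$n,
                               sign_convention(panel), df = df,
                               extra = list(residual_scale = sigma2))
  structure(list(slope = slope_est,
                 intercept = list(estimate = intercept, se = se_int,
                                  p_value = p_int, df = df)),
            class = "egger_fit")
}

#' @export
print.egger_fit <- function(x, ...) {
  print(x$slope)
  cat(sprintf("Egger intercept: %.4g (se %.3g), p = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$p_value))
  invisible(x)
}

# Interpolated weighted median of x with positive weights w: cumulative
# weight percentiles p_i = (cumsum(w) - w/2) / sum(w), linear interpolation
# at p = 0.5.
weighted_median_interp <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (length(x) == 1) return(x)
  stats::approx(p, x, xout = 0.5, rule = 2, ties = "ordered")$y
}

ratio_weights <- function(s, weighting) {
  1 / ratio_var(s$bx, s$sx, s$by, s$sy, weighting)
}

boot_draws <- function(s, n_boot, seed) {
  set.seed(seed)
  list(bx = matrix(stats::rnorm(s$n * n_boot, s$bx, s$sx), s$n, n_boot),
       by = matrix(stats::rnorm(s$n * n_boot, s$by, s$sy), s$n, n_boot))
}

#' Weighted median estimate
#'
#' The interpolated weighted median of the per-SNP Wald ratios, consistent
#' when instruments carrying at least half of the weight are valid. Weights
#' are the inverse Wald-ratio variances; by default the second-order
#' delta-method variance (including the exposure error term), the convention
#' of the standard two-sample MR tooling. The SE comes from a parametric
#' bootstrap: exposure and outcome betas are resampled from their normal
#' sampling distributions and the estimator recomputed.
#'
#' @param panel An [instrument_panel()] with at least 3 instruments.
#' @param weighting `"delta2"` (default) or `"delta1"`: Wald-ratio variance
#'   used for the weights.
#' @param n_boot Bootstrap replicates for the SE. Default 1000.
#' @param seed Seed for the bootstrap (recorded in the result).
#' @return An `mr_estimate` (extra fields `weighting`, `n_boot`, `seed`).
#' @export
mr_weighted_median <- function(panel, weighting = c("delta2", "delta1"),
                               n_boot = 1000, seed = 1L) {
  weighting <- match.arg(weighting)
  s <- panel_stats(panel)
  if (s$n < 3) stop("weighted median needs >= 3 instruments")
  b <- weighted_median_interp(s$by / s$bx, ratio_weights(s, weighting))
  d <- boot_draws(s, n_boot, seed)
  boots <- vapply(seq_len(n_boot), function(j) {
    sj <- list(bx = d$bx[, j], sx = s$sx, by = d$by[, j], sy = s$sy, n = s$n)
    weighted_median_interp(sj$by / sj$bx, ratio_weights(sj, weighting))
  }, numeric(1))
  se <- stats::sd(boots)
  new_mr_estimate("weighted_median", b, se, s$n, sign_convention(panel),
                  extra = list(weighting = weighting, n_boot = n_boot,
                               seed = seed))
}

mode_bandwidth <- function(ratio, phi) {
  phi * 0.9 * min(stats::sd(ratio), stats::mad(ratio)) *
    length(ratio)^(-1 / 5)
}

# argmax of the weighted Gaussian kernel density over a fine grid spanning
# the ratios +/- 3 bandwidths
kde_argmax <- function(ratio, w, h, grid_n) {
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, ratio, h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimate
#'
#' The mode of the inverse-variance-weighted Gaussian kernel density of the
#' per-SNP Wald ratios, consistent when the largest weight cluster of ratios
#' comes from valid instruments (plurality validity). Bandwidth follows the
#' modified Silverman rule `phi * 0.9 * min(sd, 1.4826 MAD) * n^(-1/5)`;
#' weights as in [mr_weighted_median()]. SE by parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier. Default 1.
#' @param grid_n Grid resolution for the density argmax. Default 512.
#' @return An `mr_estimate` (extra fields `bandwidth`, `phi`, `weighting`,
#'   `n_boot`, `seed`).
#' @export
mr_weighted_mode <- function(panel, phi = 1, weighting = c("delta2", "delta1"),
                             n_boot = 1000, seed = 1L, grid_n = 512) {
  weighting <- match.arg(weighting)
  s <- panel_stats(panel)
  if (s$n < 3) stop("weighted mode needs >= 3 instruments")
  ratio <- s$by / s$bx
  point <- function(ratio, w, h) {
    if (h <= 0) return(ratio[1])   # degenerate: all ratios coincide
    kde_argmax(ratio, w / sum(w), h, grid_n)
  }
  h <- mode_bandwidth(ratio, phi)
  if (max(ratio) - min(ratio) > 0) h <- max(h, 1e-8)
  b <- point(ratio, ratio_weights(s, weighting), h)
  d <- boot_draws(s, n_boot, seed)
  boots <- vapply(seq_len(n_boot), function(j) {
    sj <- list(bx = d$bx[, j], sx = s$sx, by = d$by[, j], sy = s$sy, n = s$n)
    rj <- sj$by / sj$bx
    point(rj, ratio_weights(sj, weighting), max(mode_bandwidth(rj, phi), 1e-8))
  }, numeric(1))
  se <- stats::sd(boots)
  new_mr_estimate("weighted_mode", b, se, s$n, sign_convention(panel),
                  extra = list(bandwidth = h, phi = phi, weighting = weighting,
                               n_boot = n_boot, seed = seed))
}

#' Run all five causal estimators
#'
#' Convenience wrapper returning the IVW, maximum-likelihood, Egger-slope,
#' weighted-median and weighted-mode estimates for one panel.
#'
#' @param panel An [instrument_panel()].
#' @param variance_model Passed to [mr_ivw()].
#' @param phi Passed to [mr_weighted_mode()].
#' @param weighting Passed to the median/mode estimators.
#' @param n_boot,seed Bootstrap settings for the median/mode SEs.
#' @return Named list of `mr_estimate` objects (`egger` holds the full
#'   `egger_fit`).
#' @export
mr_all <- function(panel, variance_model = "multiplicative_re", phi = 1,
                   weighting = "delta2", n_boot = 1000, seed = 1L) {
  list(ivw = mr_ivw(panel, variance_model = variance_model),
       maximum_likelihood = mr_maximum_likelihood(panel),
       egger = mr_egger(panel),
       weighted_median = mr_weighted_median(panel, weighting = weighting,
                                            n_boot = n_boot, seed = seed),
       weighted_mode = mr_weighted_mode(panel, phi = phi,
                                        weighting = weighting,
                                        n_boot = n_boot, seed = seed + 1L))
}
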