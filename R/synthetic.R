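#' Configure a synthetic two-sample MR panel
#'
#' Describes the generating model for [simulate_panel()]: per-SNP true
#' instrument effects `gamma_i` drawn uniformly from
#' `exposure_effect_range`, observed exposure betas normal about them with
#' SD `se_exposure_scale`, and outcome betas normal about
#' `beta_true * gamma_i + alpha_i` with SD `se_outcome_scale`, where
#' `alpha_i` is the horizontal-pleiotropy effect of invalid instruments
#' (zero for valid ones). Defaults mirror the magnitudes of the packaged
#' telomere-length instruments (exposure betas 0.02-0.15 SD, exposure SE
#' ~0.012, outcome SE ~0.003), so synthetic and fixture panels are
#' numerically comparable.
#'
#' @param n_snps Number of instruments.
#' @param beta_true True causal log-OR per SD of exposure.
#' @param exposure_effect_range Range (low, high) for the true `gamma_i`,
#'   drawn positive. Default c(0.02, 0.15).
#' @param se_exposure_scale,se_outcome_scale Per-SNP standard errors of the
#'   exposure and outcome betas. Defaults 0.012 and 0.003.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct effects),
#'   `"directional"` (mean `pleiotropy_mean`) or `"inside_violated"`
#'   (direct effects correlated with instrument strength, breaking the
#'   InSIDE assumption).
#' @param pleiotropy_sd SD of the direct effects of invalid instruments.
#'   Default 0.005.
#' @param pleiotropy_mean Mean direct effect (directional / InSIDE-violating
#'   modes). Default 0.
#' @param prop_invalid Proportion of instruments carrying a direct effect,
#'   in \[0, 1\]. Must be 0 when `pleiotropy_mode = "none"`.
#' @param seed Integer seed; the panel is fully reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snps, beta_true,
                       exposure_effect_range = c(0.02, 0.15),
                       se_exposure_scale = 0.012, se_outcome_scale = 0.003,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violated"),
                       pleiotropy_sd = 0.005, pleiotropy_mean = 0,
                       prop_invalid = 0, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, length(exposure_effect_range) == 2,
            exposure_effect_range[1] <= exposure_effect_range[2],
            se_exposure_scale > 0, se_outcome_scale > 0, pleiotropy_sd >= 0,
            prop_invalid >= 0, prop_invalid <= 1)
  if (pleiotropy_mode == "none" && prop_invalid > 0)
    stop("prop_invalid > 0 requires a pleiotropy mode other than 'none'")
  structure(list(n_snps = as.integer(n_snps), beta_true = beta_true,
                 exposure_effect_range = exposure_effect_range,
                 se_exposure_scale = se_exposure_scale,
                 se_outcome_scale = se_outcome_scale,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 prop_invalid = prop_invalid, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-sample summary-statistics panel with known truth
#'
#' Draws one instrument panel under the model described by [sim_config()]
#' and returns it together with the generating quantities (the truth the
#' robust estimators are meant to recover or resist).
#'
#' @param config A [sim_config()].
#' @return List with `panel` (an [instrument_panel()], per-SD-increase
#'   convention) and `truth` (list of class `synthetic_truth`: `beta_true`,
#'   per-SNP `gamma`, `alpha`, `invalid` flags, `seed`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snps
  gamma <- stats::runif(n, config$exposure_effect_range[1],
                        config$exposure_effect_range[2])
  sx <- rep(config$se_exposure_scale, n)
  sy <- rep(config$se_outcome_scale, n)
  n_invalid <- round(config$prop_invalid * n)
  invalid <- rep(FALSE, n)
  if (n_invalid > 0) invalid[sample.int(n, n_invalid)] <- TRUE
  alpha <- rep(0, n)
  if (n_invalid > 0) {
    alpha[invalid] <- switch(
      config$pleiotropy_mode,
      balanced = stats::rnorm(n_invalid, 0, config$pleiotropy_sd),
      directional = stats::rnorm(n_invalid, config$pleiotropy_mean,
                                 config$pleiotropy_sd),
      inside_violated = {
        # direct effects tied to instrument strength: InSIDE broken
        g <- gamma[invalid]
        z <- if (n_invalid > 1 && stats::sd(g) > 0)
          (g - mean(g)) / stats::sd(g) else rep(0, n_invalid)
        config$pleiotropy_mean + config$pleiotropy_sd * z
      },
      stop("invalid instruments under pleiotropy_mode 'none'"))
  }
  bx <- stats::rnorm(n, gamma, sx)
  by <- stats::rnorm(n, config$beta_true * gamma + alpha, sy)
  zero <- bx == 0
  if (any(zero)) bx[zero] <- .Machine$double.eps  # measure-zero guard
  panel <- instrument_panel(
    data.frame(snp_id = sprintf("snp%04d", seq_len(n)),
               beta_exposure = bx, se_exposure = sx,
               beta_outcome = by, se_outcome = sy,
               stringsAsFactors = FALSE),
    sign_convention = "per_sd_increase")
  truth <- structure(list(beta_true = config$beta_true, gamma = gamma,
                          alpha = alpha, invalid = invalid,
                          seed = config$seed, config = config),
                     class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

#' Build a block LD matrix
#'
#' Constructs the r-squared matrix in which two distinct SNPs share
#' `r2_within` when mapped to the same block and 0 otherwise — the LD
#' structure used to exercise clumping when only locus membership (not true
#' pairwise LD) is known.
#'
#' @param records Data frame of canonical GWAS records (only `snp_id` is
#'   required).
#' @param block_of Named character vector mapping every `snp_id` to a block
#'   label, e.g. from [locus_blocks()].
#' @param r2_within Within-block r-squared, in \[0, 1\]. Default 0.8.
#' @return An [ld_matrix()].
#' @export
simulate_ld_blocks <- function(records, block_of, r2_within = 0.8) {
  if (r2_within < 0 || r2_within > 1)
    stop("r2_within must lie in [0, 1]")
  ids <- records$snp_id
  unmapped <- setdiff(ids, names(block_of))
  if (length(unmapped) > 0)
    stop("SNP(s) missing from block mapping: ",
         paste(unmapped, collapse = ", "))
  blocks <- block_of[ids]
  m <- outer(blocks, blocks, "==") * r2_within
  diag(m) <- 1
  ld_matrix(m, ids)
}

#' Stream per-replicate seeds from one root seed
#'
#' Derives `n` reproducible sub-seeds for replicate simulations, so a whole
#' study is driven by a single integer.
#'
#' @param root_seed Integer root seed.
#' @param n Number of replicate seeds.
#' @return Integer vector of length `n`, each below 2^31.
#' @export
replicate_seeds <- function(root_seed, n) {
  set.seed(root_seed)
  sample.int(.Machine$integer.max, n)
}
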