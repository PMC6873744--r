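# Shared fixtures, all built in code.

# 10-instrument panel from the packaged case study: clump the 16 published
# SNPs with the locus-block LD matrix, then harmonize the survivors.
paper_panel <- local({
  cache <- new.env()
  function(sign_convention = "per_sd_decrease") {
    key <- sign_convention
    if (is.null(cache[[key]])) {
      paper <- load_paper_instruments()
      ld <- simulate_ld_blocks(paper$exposure, locus_blocks(paper$exposure))
      cl <- greedy_clump(paper$exposure, ld)
      keep_x <- paper$exposure$snp_id %in% cl$kept
      keep_y <- paper$outcome$snp_id %in% cl$kept
      cache[[key]] <- suppressWarnings(
        harmonize(paper$exposure[keep_x, ], paper$outcome[keep_y, ],
                  sign_convention = sign_convention))
    }
    cache[[key]]
  }
})

toy_panel <- function(bx, by, sx = rep(0.01, length(bx)),
                      sy = rep(0.01, length(bx)),
                      sign_convention = "per_sd_increase") {
  instrument_panel(
    data.frame(snp_id = sprintf("snp%02d", seq_along(bx)),
               beta_exposure = bx, se_exposure = sx,
               beta_outcome = by, se_outcome = sy,
               stringsAsFactors = FALSE),
    sign_convention = sign_convention)
}

gwas_record <- function(snp_id = "rs1", chromosome = "1", position = 1000,
                        effect_allele = "A", other_allele = "G", eaf = 0.3,
                        beta = 0.1, se = 0.01, p_value = 1e-9,
                        gene_label = NA_character_) {
  data.frame(snp_id = snp_id, chromosome = chromosome, position = position,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, p_value = p_value,
             gene_label = gene_label, stringsAsFactors = FALSE)
}

# Independent oracle for the interpolated weighted median: explicit
# bracketing of the 0.5 percentile rather than approx().
brute_weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(x[1])
  if (p[length(p)] <= 0.5) return(x[length(x)])
  k <- max(which(p < 0.5))
  x[k] + (x[k + 1] - x[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

random_ld <- function(ids, density = 0.3, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
    m[i, j] <- m[j, i] <- if (stats::runif(1) < density) stats::runif(1) else 0
  diag(m) <- 1
  ld_matrix(m, ids)
}
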