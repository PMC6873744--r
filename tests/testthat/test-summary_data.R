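test_that("delimited GWAS tables load through a column map with row-level validation", {
  paper <- load_paper_instruments()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  dialect <- data.frame(rsid = paper$exposure$snp_id,
                        CHR = paper$exposure$chromosome,
                        POS = paper$exposure$position,
                        a1 = tolower(paper$exposure$effect_allele),
                        a2 = tolower(paper$exposure$other_allele),
                        FRQ = paper$exposure$eaf, b = paper$exposure$beta,
                        SE = paper$exposure$se, P = paper$exposure$p_value)
  utils::write.table(dialect, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  map <- c(snp_id = "rsid", chromosome = "CHR", position = "POS",
           effect_allele = "a1", other_allele = "a2", eaf = "FRQ",
           beta = "b", se = "SE", p_value = "P")
  got <- read_gwas_table(tmp, column_map = map)
  expect_equal(nrow(got), 16)
  expect_equal(got$snp_id[1], "rs10936599")
  expect_equal(got$beta[1], 0.1)
  expect_equal(got$se[1], 0.011)
  expect_equal(got$effect_allele[1], "C")  # upper-cased

  # comma-delimited dialect auto-detects
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(dialect, csv, sep = ",", quote = FALSE,
                     row.names = FALSE)
  expect_equal(nrow(read_gwas_table(csv, column_map = map)), 16)

  # a zero-SE row is rejected with a row-indexed diagnostic
  bad <- dialect
  bad$SE[3] <- 0
  utils::write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(got <- read_gwas_table(tmp, column_map = map), "row 3")
  expect_equal(nrow(got), 15)
  expect_equal(attr(got, "rejected")$reason, "se must be > 0")

  # header only -> empty result plus warning
  writeLines(paste(names(dialect), collapse = "\t"), tmp)
  expect_warning(empty <- read_gwas_table(tmp, column_map = map),
                 "no data rows")
  expect_equal(nrow(empty), 0)

  # missing mapped column is a configuration error
  utils::write.table(dialect[, -7], tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_gwas_table(tmp, column_map = map), "missing column")
  expect_error(read_gwas_table(tmp, column_map = c(nonsense = "x")),
               "unknown field")
})

test_that("column maps load from YAML and JSON files", {
  paper <- load_paper_instruments()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- paper$exposure
  names(df)[names(df) == "snp_id"] <- "MarkerName"
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines("snp_id: MarkerName", yml)
  expect_equal(read_gwas_table(tmp, column_map = yml)$snp_id[1],
               "rs10936599")
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"snp_id": "MarkerName"}', js)
  expect_equal(read_gwas_table(tmp, column_map = js)$snp_id[2], "rs8105767")
})

test_that("the packaged instruments match the published summary table", {
  paper <- load_paper_instruments()
  expect_equal(nrow(paper$exposure), 16)
  expect_equal(nrow(paper$outcome), 16)
  expect_equal(paper$exposure$snp_id, paper$outcome$snp_id)
  expect_equal(length(unique(paper$exposure$gene_label)), 11)
  expect_true(all(paper$exposure$p_value < 5e-8))
  expect_true(all(paper$exposure$beta > 0))
  i <- match("rs4387287", paper$outcome$snp_id)
  expect_equal(paper$outcome$beta[i], -7.81e-3)
  expect_equal(paper$outcome$se[i], 2.69e-3)
  expect_equal(sort(paper$removed_by_clumping),
               sort(c("rs1317082", "rs412658", "rs12696304", "rs9419958",
                      "rs9420907", "rs10936601")))
})

test_that("harmonization aligns alleles, strand and orientation", {
  ex <- gwas_record(effect_allele = "A", other_allele = "G", eaf = 0.3,
                    beta = 0.1)
  # identical alleles, same order: untouched
  out <- gwas_record(effect_allele = "A", other_allele = "G", eaf = 0.3,
                     beta = 0.02, se = 0.005)
  h <- harmonize_pair(ex, out)
  expect_equal(h$action, "unchanged")
  expect_equal(h$beta_outcome, 0.02)

  # reversed allele order: sign and frequency flip
  out_rev <- gwas_record(effect_allele = "G", other_allele = "A", eaf = 0.3,
                         beta = 0.02, se = 0.005)
  h <- harmonize_pair(ex, out_rev, freq_warn_tol = 1)
  expect_equal(h$action, "allele-flipped")
  expect_equal(h$beta_outcome, -0.02)
  expect_equal(h$eaf_outcome, 0.7)

  # strand complement, same orientation (A/G vs T/C)
  out_str <- gwas_record(effect_allele = "T", other_allele = "C", eaf = 0.3,
                         beta = 0.02, se = 0.005)
  expect_equal(harmonize_pair(ex, out_str)$beta_outcome, 0.02)
  # strand complement and reversed (A/G vs C/T)
  out_both <- gwas_record(effect_allele = "C", other_allele = "T", eaf = 0.3,
                          beta = 0.02, se = 0.005)
  h <- harmonize_pair(ex, out_both, freq_warn_tol = 1)
  expect_equal(h$beta_outcome, -0.02)

  # irreconcilable allele sets never pass silently
  out_bad <- gwas_record(effect_allele = "A", other_allele = "C", eaf = 0.3,
                         beta = 0.02, se = 0.005)
  expect_equal(harmonize_pair(ex, out_bad)$action, "dropped")
  expect_equal(harmonize_pair(ex, out_bad)$reason, "incompatible")

  # negative exposure beta reorients both effects to the increasing allele
  ex_neg <- gwas_record(beta = -0.1, eaf = 0.3)
  h <- harmonize_pair(ex_neg, gwas_record(beta = 0.02, se = 0.005,
                                          eaf = 0.3))
  expect_gt(h$beta_exposure, 0)
  expect_equal(h$beta_outcome, -0.02)
  expect_equal(h$effect_allele, "G")
})

test_that("palindromic SNPs resolve by frequency below the MAF limit", {
  # the published T/A instrument: exposure frequency 0.87 (MAF 0.13) is
  # informative, so the SNP is retained untouched
  ex <- gwas_record(snp_id = "rs6772228", effect_allele = "T",
                    other_allele = "A", eaf = 0.87, beta = 0.041, se = 0.014)
  out <- gwas_record(snp_id = "rs6772228", effect_allele = "T",
                     other_allele = "A", eaf = 0.96, beta = 4.28e-3,
                     se = 5.34e-3)
  h <- harmonize_pair(ex, out)
  expect_equal(h$action, "unchanged")
  expect_equal(h$beta_outcome, 4.28e-3)

  # discordant frequencies imply the opposite strand: effect flips
  out_disc <- gwas_record(snp_id = "rs6772228", effect_allele = "T",
                          other_allele = "A", eaf = 0.10, beta = 4.28e-3,
                          se = 5.34e-3)
  h <- harmonize_pair(ex, out_disc, freq_warn_tol = 1)
  expect_equal(h$action, "allele-flipped")
  expect_equal(h$beta_outcome, -4.28e-3)

  # near 50% frequency the strand is unknowable: dropped as ambiguous
  ex_amb <- gwas_record(effect_allele = "C", other_allele = "G", eaf = 0.45)
  out_amb <- gwas_record(effect_allele = "C", other_allele = "G", eaf = 0.48,
                         beta = 0.01, se = 0.005)
  h <- harmonize_pair(ex_amb, out_amb)
  expect_equal(h$action, "dropped")
  expect_equal(h$reason, "ambiguous")
})

test_that("frequency discordance warns without dropping the SNP", {
  ex <- gwas_record(snp_id = "rs6028466", eaf = 0.17, beta = 0.058)
  out <- gwas_record(snp_id = "rs6028466", eaf = 0.06, beta = -5.65e-4,
                     se = 4.43e-3)
  expect_warning(h <- harmonize_pair(ex, out), "frequency differs")
  expect_equal(h$action, "unchanged")
})

test_that("harmonization is idempotent and ratio-preserving under relabeling", {
  set.seed(7)
  for (i in 1:25) {
    alleles <- sample(c("A", "C", "G", "T"), 2)
    ex <- gwas_record(effect_allele = alleles[1], other_allele = alleles[2],
                      eaf = stats::runif(1, 0.05, 0.95),
                      beta = stats::rnorm(1, 0, 0.1))
    out <- gwas_record(effect_allele = alleles[1], other_allele = alleles[2],
                       eaf = ex$eaf, beta = stats::rnorm(1, 0, 0.01),
                       se = 0.005)
    h1 <- suppressWarnings(harmonize_pair(ex, out))
    if (h1$action == "dropped") next
    # feed the harmonized pair back through: nothing changes
    ex2 <- gwas_record(effect_allele = h1$effect_allele,
                       other_allele = h1$other_allele, eaf = h1$eaf_exposure,
                       beta = h1$beta_exposure, se = h1$se_exposure)
    out2 <- gwas_record(effect_allele = h1$effect_allele,
                        other_allele = h1$other_allele, eaf = h1$eaf_outcome,
                        beta = h1$beta_outcome, se = h1$se_outcome)
    h2 <- suppressWarnings(harmonize_pair(ex2, out2))
    expect_equal(h2$beta_exposure, h1$beta_exposure)
    expect_equal(h2$beta_outcome, h1$beta_outcome)
    expect_equal(h2$action, "unchanged")

    # relabel which allele is "effect" in both raw inputs: a double flip
    # must leave the Wald ratio invariant
    flip <- function(r) {
      r2 <- r
      r2$effect_allele <- r$other_allele
      r2$other_allele <- r$effect_allele
      r2$eaf <- 1 - r$eaf
      r2$beta <- -r$beta
      r2
    }
    h3 <- suppressWarnings(harmonize_pair(flip(ex), flip(out)))
    expect_equal(h3$beta_outcome / h3$beta_exposure,
                 h1$beta_outcome / h1$beta_exposure, tolerance = 1e-12)
  }
})

test_that("panel construction enforces the instrument invariants", {
  df <- data.frame(snp_id = c("a", "a"), beta_exposure = c(0.1, 0.2),
                   se_exposure = 0.01, beta_outcome = 0, se_outcome = 0.01)
  expect_error(instrument_panel(df), "duplicate")
  df$snp_id <- c("a", "b")
  df$se_outcome <- c(0.01, -1)
  expect_error(instrument_panel(df), "positive")
  df$se_outcome <- 0.01
  df$beta_exposure <- c(0, 0.2)
  expect_error(instrument_panel(df), "nonzero")
  expect_error(instrument_panel(df[0, ]), ">= 1")
})

test_that("harmonize() assembles a panel and records drops", {
  paper <- load_paper_instruments()
  panel <- suppressWarnings(harmonize(paper$exposure, paper$outcome))
  expect_s3_class(panel, "instrument_panel")
  expect_equal(nrow(panel), 16)   # pre-aligned fixture: nothing dropped
  expect_true(all(panel$beta_exposure > 0))
  expect_equal(nrow(attr(panel, "dropped")), 0)
})
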