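#' @keywords internal
"_PACKAGE"

# Canonical column set for one GWAS association summary.
GWAS_FIELDS <- c("snp_id", "chromosome", "position", "effect_allele",
                 "other_allele", "eaf", "beta", "se", "p_value", "gene_label")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Validate GWAS summary records
#'
#' Checks each row of a summary-statistics table against the per-SNP
#' invariants (positive SE, p in (0, 1], allele frequency in \[0, 1\],
#' distinct single-base alleles, positive position) and splits the table
#' into valid and rejected rows.
#'
#' @param records Data frame with the canonical columns (`snp_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `p_value`, and optionally `gene_label`).
#' @return List with `valid` (the retained rows) and `rejected` (a data
#'   frame with `row`, `snp_id`, `reason`).
#' @export
validate_gwas_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (is.null(records$gene_label))
    records$gene_label <- rep(NA_character_, nrow(records))
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  n <- nrow(records)
  reasons <- character(n)
  flag <- function(bad, why) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- why
  }
  num_bad <- !is.finite(records$beta) | !is.finite(records$se) |
    !is.finite(records$p_value)
  flag(num_bad, "non-numeric beta/se/p")
  flag(records$se <= 0, "se must be > 0")
  flag(records$p_value <= 0 | records$p_value > 1, "p_value outside (0, 1]")
  flag(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1),
       "allele frequency outside [0, 1]")
  flag(!records$effect_allele %in% names(COMPLEMENT) |
         !records$other_allele %in% names(COMPLEMENT),
       "allele not a single base A/C/G/T")
  flag(records$effect_allele == records$other_allele, "identical alleles")
  flag(!is.finite(records$position) | records$position <= 0,
       "position must be > 0")
  bad <- nzchar(reasons)
  rejected <- data.frame(row = which(bad),
                         snp_id = records$snp_id[bad],
                         reason = reasons[bad],
                         stringsAsFactors = FALSE)
  list(valid = records[!bad, , drop = FALSE], rejected = rejected)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited text file with a header row and maps its
#' columns onto the canonical record fields. Rows violating the record
#' invariants are rejected with row-indexed diagnostics; alleles are
#' upper-cased.
#'
#' @param path Path to the delimited file.
#' @param column_map Named character vector (or list) mapping canonical field
#'   names to file column names, e.g. `c(snp_id = "SNP", beta = "b")`; or the
#'   path to a YAML/JSON file holding such a mapping. Fields not mentioned are
#'   looked up under their canonical names. `gene_label` is optional.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return Data frame of validated records, with a `rejected` attribute
#'   holding the diagnostics for any dropped rows.
#' @export
read_gwas_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  column_map <- resolve_column_map(column_map)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  required <- setdiff(GWAS_FIELDS, "gene_label")
  cols <- vapply(GWAS_FIELDS, function(f) {
    if (!is.null(column_map[[f]])) column_map[[f]] else f
  }, character(1))
  missing <- setdiff(cols[required], names(raw))
  if (length(missing) > 0)
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  out <- data.frame(snp_id = raw[[cols["snp_id"]]],
                    chromosome = raw[[cols["chromosome"]]],
                    position = suppressWarnings(as.numeric(raw[[cols["position"]]])),
                    effect_allele = raw[[cols["effect_allele"]]],
                    other_allele = raw[[cols["other_allele"]]],
                    eaf = suppressWarnings(as.numeric(raw[[cols["eaf"]]])),
                    beta = suppressWarnings(as.numeric(raw[[cols["beta"]]])),
                    se = suppressWarnings(as.numeric(raw[[cols["se"]]])),
                    p_value = suppressWarnings(as.numeric(raw[[cols["p_value"]]])),
                    stringsAsFactors = FALSE)
  out$gene_label <- if (cols["gene_label"] %in% names(raw))
    raw[[cols["gene_label"]]] else rep(NA_character_, nrow(out))
  if (nrow(out) == 0) {
    warning("no data rows in ", path)
    return(structure(out, rejected = out[0, c("snp_id", "p_value")]))
  }
  checked <- validate_gwas_records(out)
  if (nrow(checked$rejected) > 0)
    warning("rejected ", nrow(checked$rejected), " row(s) of ", path, ": ",
            paste(sprintf("row %d (%s): %s", checked$rejected$row,
                          checked$rejected$snp_id, checked$rejected$reason),
                  collapse = "; "))
  structure(checked$valid, rejected = checked$rejected)
}

resolve_column_map <- function(column_map) {
  if (is.null(column_map)) return(list())
  if (is.character(column_map) && length(column_map) == 1 &&
      is.null(names(column_map)) && file.exists(column_map)) {
    column_map <- if (grepl("\\.ya?ml$", column_map, ignore.case = TRUE))
      yaml::read_yaml(column_map)
    else jsonlite::read_json(column_map, simplifyVector = TRUE)
  }
  column_map <- as.list(column_map)
  unknown <- setdiff(names(column_map), GWAS_FIELDS)
  if (length(unknown) > 0)
    stop("unknown field(s) in column map: ", paste(unknown, collapse = ", "))
  column_map
}

#' Load the packaged telomere-length / Alzheimer's disease instruments
#'
#' Returns the 16 published genome-wide significant telomere-length SNPs
#' together with their Alzheimer's disease outcome associations, shipped
#' with the package as a tab-separated fixture. Exposure betas are in SD
#' units of telomere length per copy of the effect allele (the
#' telomere-lengthening allele, so all are positive); outcome betas are
#' log-odds of Alzheimer's disease for the same allele.
#'
#' @return List with data frames `exposure` and `outcome` (16 records each,
#'   canonical columns) and `removed_by_clumping`, the rsIDs the source
#'   analysis discarded during LD clumping (ground truth for
#'   [greedy_clump()]).
#' @export
load_paper_instruments <- function() {
  path <- system.file("extdata", "telomere_ad_instruments.tsv",
                      package = "telomr", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  shared <- data.frame(snp_id = raw$SNP, chromosome = as.character(raw$Chr),
                       position = raw$BP, effect_allele = raw$A1,
                       other_allele = raw$A2, gene_label = raw$Gene,
                       stringsAsFactors = FALSE)
  exposure <- cbind(shared, data.frame(eaf = raw$Freq_TL, beta = raw$Beta_TL,
                                       se = raw$SE_TL, p_value = raw$P_TL))
  outcome <- cbind(shared, data.frame(eaf = raw$Freq_AD, beta = raw$Beta_AD,
                                      se = raw$SE_AD, p_value = raw$P_AD))
  exposure <- exposure[, GWAS_FIELDS]
  outcome <- outcome[, GWAS_FIELDS]
  list(exposure = exposure, outcome = outcome,
       removed_by_clumping = raw$SNP[raw$Removed == "Yes"])
}

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize one exposure/outcome record pair
#'
#' Aligns the outcome association to the exposure's effect allele, resolving
#' reversed allele order and strand (complement) mismatches, then orients the
#' pair so the exposure beta is positive. Palindromic (A/T or C/G) SNPs are
#' kept when the exposure minor-allele frequency is below
#' `palindrome_maf_limit`, using allele-frequency concordance between the two
#' datasets to infer strand; otherwise they are dropped as ambiguous.
#'
#' @param exposure,outcome Single records (one-row data frames or lists) with
#'   the canonical fields, sharing `snp_id`.
#' @param palindrome_maf_limit Exposure MAF above which a palindromic SNP is
#'   considered strand-ambiguous and dropped. Default 0.42.
#' @param freq_warn_tol Warn when the harmonized effect-allele frequencies of
#'   the two datasets differ by more than this (the SNP is retained).
#' @return One-row data frame with `snp_id`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`, `action`
#'   (`"unchanged"`, `"allele-flipped"` or `"dropped"`) and `reason`.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_maf_limit = 0.42,
                           freq_warn_tol = 0.1) {
  exposure <- as.list(exposure)
  outcome <- as.list(outcome)
  if (!identical(exposure$snp_id, outcome$snp_id))
    stop("snp_id mismatch: ", exposure$snp_id, " vs ", outcome$snp_id)
  ea <- toupper(exposure$effect_allele); oa <- toupper(exposure$other_allele)
  yea <- toupper(outcome$effect_allele); yoa <- toupper(outcome$other_allele)
  b_out <- outcome$beta; f_out <- outcome$eaf
  action <- "unchanged"; reason <- NA_character_

  drop <- function(why) {
    data.frame(snp_id = exposure$snp_id, effect_allele = ea, other_allele = oa,
               beta_exposure = NA_real_, se_exposure = exposure$se,
               beta_outcome = NA_real_, se_outcome = outcome$se,
               eaf_exposure = NA_real_, eaf_outcome = NA_real_,
               action = "dropped", reason = why, stringsAsFactors = FALSE)
  }

  if (is_palindromic(ea, oa)) {
    maf <- min(exposure$eaf, 1 - exposure$eaf)
    if (is.na(maf) || maf >= palindrome_maf_limit)
      return(drop("ambiguous"))
    # Allele labels cannot resolve strand for palindromes; use frequency
    # concordance. Discordant minor alleles imply the outcome is reported on
    # the opposite strand/allele, so flip its effect.
    if (!is.na(f_out) && (exposure$eaf - 0.5) * (f_out - 0.5) < 0) {
      b_out <- -b_out; f_out <- 1 - f_out; action <- "allele-flipped"
    }
  } else if (yea == ea && yoa == oa) {
    # aligned as-is
  } else if (yea == oa && yoa == ea) {
    b_out <- -b_out; f_out <- 1 - f_out; action <- "allele-flipped"
  } else {
    cea <- unname(COMPLEMENT[yea]); coa <- unname(COMPLEMENT[yoa])
    if (identical(cea, ea) && identical(coa, oa)) {
      # other strand, same orientation
    } else if (identical(cea, oa) && identical(coa, ea)) {
      b_out <- -b_out; f_out <- 1 - f_out; action <- "allele-flipped"
    } else {
      return(drop("incompatible"))
    }
  }

  b_exp <- exposure$beta; f_exp <- exposure$eaf
  if (!is.na(b_exp) && b_exp < 0) {
    # orient to the exposure-increasing allele
    b_exp <- -b_exp; b_out <- -b_out
    f_exp <- 1 - f_exp; f_out <- 1 - f_out
    tmp <- ea; ea <- oa; oa <- tmp
    action <- if (action == "allele-flipped") "unchanged" else "allele-flipped"
  }
  if (!is.na(f_exp) && !is.na(f_out) && abs(f_exp - f_out) > freq_warn_tol)
    warning(exposure$snp_id, ": effect-allele frequency differs between ",
            "datasets (", signif(f_exp, 3), " vs ", signif(f_out, 3), ")")
  data.frame(snp_id = exposure$snp_id, effect_allele = ea, other_allele = oa,
             beta_exposure = b_exp, se_exposure = exposure$se,
             beta_outcome = b_out, se_outcome = outcome$se,
             eaf_exposure = f_exp, eaf_outcome = f_out,
             action = action, reason = reason, stringsAsFactors = FALSE)
}

#' Harmonize exposure and outcome summary tables into an instrument panel
#'
#' Applies [harmonize_pair()] to every SNP present in both tables (in
#' exposure order) and assembles the retained instruments into an
#' [instrument_panel()]. Dropped SNPs are reported with a warning and kept in
#' the panel's `dropped` attribute.
#'
#' @param exposure,outcome Data frames of canonical GWAS records.
#' @param sign_convention Reporting convention for downstream estimates, see
#'   [instrument_panel()].
#' @inheritParams harmonize_pair
#' @return An `instrument_panel`.
#' @export
harmonize <- function(exposure, outcome,
                      sign_convention = c("per_sd_increase", "per_sd_decrease"),
                      palindrome_maf_limit = 0.42, freq_warn_tol = 0.1) {
  sign_convention <- match.arg(sign_convention)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0) stop("no shared SNPs between exposure and outcome")
  rows <- lapply(shared, function(id) {
    harmonize_pair(exposure[match(id, exposure$snp_id), ],
                   outcome[match(id, outcome$snp_id), ],
                   palindrome_maf_limit = palindrome_maf_limit,
                   freq_warn_tol = freq_warn_tol)
  })
  all_rows <- do.call(rbind, rows)
  dropped <- all_rows[all_rows$action == "dropped", , drop = FALSE]
  if (nrow(dropped) > 0)
    warning("dropped ", nrow(dropped), " SNP(s) during harmonization: ",
            paste(sprintf("%s (%s)", dropped$snp_id, dropped$reason),
                  collapse = ", "))
  kept <- all_rows[all_rows$action != "dropped", , drop = FALSE]
  panel <- instrument_panel(kept, sign_convention = sign_convention)
  attr(panel, "dropped") <- dropped
  panel
}

#' Construct an instrument panel
#'
#' An instrument panel is the input of all causal estimators: an ordered,
#' de-duplicated set of harmonized instruments (per-SNP exposure and outcome
#' effects aligned to a common, exposure-increasing allele) plus the sign
#' convention under which pooled estimates are reported. Estimators always
#' work internally per SD *increase* of the exposure; under
#' `"per_sd_decrease"` the reporting layer negates the pooled log-OR (so an
#' odds ratio above 1 means higher outcome risk per SD decrease).
#'
#' @param instruments Data frame with columns `snp_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome` (extra columns are kept).
#' @param sign_convention `"per_sd_increase"` or `"per_sd_decrease"`.
#' @return Data frame of class `instrument_panel` with a `sign_convention`
#'   attribute.
#' @export
instrument_panel <- function(instruments,
                             sign_convention = c("per_sd_increase",
                                                 "per_sd_decrease")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(is.data.frame(instruments))
  needed <- c("snp_id", "beta_exposure", "se_exposure", "beta_outcome",
              "se_outcome")
  missing <- setdiff(needed, names(instruments))
  if (length(missing) > 0)
    stop("instrument panel lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(instruments) < 1) stop("instrument panel must hold >= 1 SNP")
  if (anyDuplicated(instruments$snp_id))
    stop("duplicate snp_id in instrument panel")
  if (any(instruments$se_exposure <= 0) || any(instruments$se_outcome <= 0))
    stop("standard errors must be positive")
  if (any(instruments$beta_exposure == 0))
    stop("beta_exposure must be nonzero")
  rownames(instruments) <- NULL
  structure(instruments, class = c("instrument_panel", "data.frame"),
            sign_convention = sign_convention)
}

#' @export
print.instrument_panel <- function(x, ...) {
  cat("Instrument panel:", nrow(x), "SNP(s), reported",
      gsub("_", " ", attr(x, "sign_convention")), "of exposure\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

sign_convention <- function(panel) {
  attr(panel, "sign_convention") %||% "per_sd_increase"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
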