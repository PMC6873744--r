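#' Construct an LD matrix
#'
#' A symmetric matrix of squared allelic correlations (r-squared) over a set
#' of SNP identifiers, as consumed by [greedy_clump()].
#'
#' @param r2 Square numeric matrix; entries in \[0, 1\], unit diagonal,
#'   symmetric to within 1e-12.
#' @param snp_ids Character vector of row/column labels; taken from
#'   `dimnames(r2)` when omitted.
#' @return Matrix of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = NULL) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) snp_ids <- rownames(r2)
  if (is.null(snp_ids)) stop("snp_ids required when r2 is unnamed")
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids))
    stop("r2 must be square with one row per snp_id")
  if (anyDuplicated(snp_ids)) stop("duplicate snp_ids in LD matrix")
  dimnames(r2) <- list(snp_ids, snp_ids)
  if (any(r2 < 0 | r2 > 1)) stop("r2 entries must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-12) stop("r2 matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-12)) stop("r2 diagonal must be 1")
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Read a square LD matrix from TSV
#'
#' Expects a tab-separated file whose header row and first column both carry
#' rsIDs.
#'
#' @param path File path.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  ld_matrix(m)
}

#' Read a sparse three-column LD table
#'
#' Reads `(id1, id2, r2)` rows (tab- or comma-separated, with header) and
#' expands them into a dense symmetric matrix over `snp_ids`; pairs not
#' listed get r-squared 0.
#'
#' @param path File path.
#' @param snp_ids Optional universe of SNP ids; defaults to the ids seen in
#'   the file.
#' @return An [ld_matrix()].
#' @export
read_ld_sparse <- function(path, snp_ids = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("sparse LD file needs columns id1, id2, r2")
  ids <- snp_ids %||% unique(c(d[[1]], d[[2]]))
  m <- diag(1, length(ids))
  dimnames(m) <- list(ids, ids)
  i <- match(d[[1]], ids); j <- match(d[[2]], ids)
  ok <- !is.na(i) & !is.na(j)
  m[cbind(i[ok], j[ok])] <- d[[3]][ok]
  m[cbind(j[ok], i[ok])] <- d[[3]][ok]
  diag(m) <- 1
  ld_matrix(m)
}

#' Write an LD matrix as square TSV
#'
#' @param ld An [ld_matrix()].
#' @param path Output path.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(SNP = rownames(ld), as.data.frame(unclass(ld),
                                                     check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy p-value-ordered LD clumping
#'
#' Selects independent index SNPs: candidates are visited in ascending
#' exposure p-value (ties broken lexicographically on rsID) and kept unless
#' an already-kept SNP on the same chromosome within `window_bp` has
#' r-squared above `r2_max` with them, in which case the removal is recorded
#' against that index SNP. Cross-chromosome pairs never clump.
#'
#' @param records Data frame of canonical GWAS records (needs `snp_id`,
#'   `chromosome`, `position`, `p_value`).
#' @param ld An [ld_matrix()] covering the records; pairs absent from it are
#'   treated as unlinked (r-squared 0) with a warning.
#' @param r2_max Exclusion threshold: a candidate is removed when linked to a
#'   kept SNP with r-squared strictly above this. Default 0.001.
#' @param window_bp Half-width of the clumping window around the index SNP in
#'   base pairs. Default 2 Mb.
#' @return List of class `clump_result`: `kept` (rsIDs in input order) and
#'   `removed` (data frame `snp_id`, `index_snp`, `r2`, `reason`).
#' @export
greedy_clump <- function(records, ld, r2_max = 0.001, window_bp = 2e6) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0)
    return(structure(list(kept = character(0),
                          removed = data.frame(snp_id = character(0),
                                               index_snp = character(0),
                                               r2 = numeric(0),
                                               reason = character(0))),
                     class = "clump_result"))
  if (anyDuplicated(records$snp_id)) stop("duplicate snp_ids in records")
  absent <- setdiff(records$snp_id, rownames(ld))
  if (length(absent) > 0)
    warning("SNP(s) absent from LD matrix treated as unlinked: ",
            paste(absent, collapse = ", "))
  r2_of <- function(a, b) {
    if (a %in% rownames(ld) && b %in% rownames(ld)) ld[a, b] else 0
  }
  ord <- order(records$p_value, records$snp_id)
  kept <- integer(0)
  removed <- list()
  for (i in ord) {
    hit <- NULL
    for (k in kept) {
      same_chr <- records$chromosome[k] == records$chromosome[i]
      near <- same_chr &&
        abs(records$position[k] - records$position[i]) <= window_bp
      r2 <- r2_of(records$snp_id[k], records$snp_id[i])
      if (near && r2 > r2_max) { hit <- list(k = k, r2 = r2); break }
    }
    if (is.null(hit)) {
      kept <- c(kept, i)
    } else {
      removed[[length(removed) + 1L]] <-
        data.frame(snp_id = records$snp_id[i],
                   index_snp = records$snp_id[hit$k], r2 = hit$r2,
                   reason = sprintf("r2 %.3g with %s within %d bp", hit$r2,
                                    records$snp_id[hit$k], as.integer(window_bp)),
                   stringsAsFactors = FALSE)
    }
  }
  removed <- if (length(removed) > 0) do.call(rbind, removed) else
    data.frame(snp_id = character(0), index_snp = character(0),
               r2 = numeric(0), reason = character(0))
  structure(list(kept = records$snp_id[sort(kept)], removed = removed),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("LD clumping:", length(x$kept), "kept,", nrow(x$removed), "removed\n")
  cat("kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$removed) > 0) print(x$removed)
  invisible(x)
}

#' Locus block labels from gene annotation and proximity
#'
#' Assigns each SNP a locus label such that SNPs sharing a gene annotation,
#' or lying within `merge_bp` of each other on the same chromosome, fall in
#' the same block (transitively merged). Used to build the block LD matrix
#' for the packaged instruments, whose true pairwise r-squared values are not
#' published but whose locus structure is.
#'
#' @param records Data frame of canonical GWAS records with `gene_label`.
#' @param merge_bp Same-chromosome distance below which two SNPs are merged
#'   into one locus. Default 200 kb.
#' @return Named character vector mapping `snp_id` to a block label.
#' @export
locus_blocks <- function(records, merge_bp = 2e5) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    same_gene <- !is.na(records$gene_label[i]) &&
      identical(records$gene_label[i], records$gene_label[j])
    near <- records$chromosome[i] == records$chromosome[j] &&
      abs(records$position[i] - records$position[j]) <= merge_bp
    if (same_gene || near) union_(i, j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(paste0("block", match(roots, unique(roots))),
                  records$snp_id)
}
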