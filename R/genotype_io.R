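#' SNP genotype matrix
#'
#' Container for a panel of biallelic SNP genotypes coded as counts of the
#' counted allele A1 (0, 1 or 2 copies; `NA` for missing).  Allele frequencies
#' refer to A1 throughout the package; the frequency of the alternative allele
#' is `1 - freq`.
#'
#' @param codes integer or numeric matrix, individuals in rows and SNPs in
#'   columns, with row names (individual IDs) and column names (SNP IDs).
#'   Non-missing entries must be 0, 1 or 2.
#' @param freq optional numeric vector of A1 allele frequencies, one per SNP.
#'   When `NULL` (the default) frequencies are computed from the sample:
#'   `freq[i] = sum(codes[, i]) / (2 * number of non-missing codes)`.
#'
#' @return An object of class `geno_matrix`: a list with elements `codes`,
#'   `freq`, `ids`, `snps` and a logical `monomorphic` flag per SNP.
#' @examples
#' X <- matrix(c(2L, 0L, 1L, 1L), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' G <- geno_matrix(X)
#' G$freq
#' @export
geno_matrix <- function(codes, freq = NULL) {
  if (!is.matrix(codes)) qgrm_stop("codes must be a matrix", "qgrm_value_error")
  if (is.null(rownames(codes)) || is.null(colnames(codes))) {
    qgrm_stop("codes must carry individual IDs (rownames) and SNP IDs (colnames)",
              "qgrm_id_error")
  }
  if (anyDuplicated(rownames(codes))) {
    qgrm_stop("duplicate individual IDs in genotype matrix", "qgrm_id_error")
  }
  if (anyDuplicated(colnames(codes))) {
    qgrm_stop("duplicate SNP IDs in genotype matrix", "qgrm_id_error")
  }
  vals <- codes[!is.na(codes)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    bad <- unique(vals[!vals %in% c(0, 1, 2)])
    qgrm_stop(sprintf("genotype codes must be 0/1/2/NA; found: %s",
                      paste(utils::head(bad, 5), collapse = ", ")),
              "qgrm_value_error")
  }
  storage.mode(codes) <- "integer"
  if (is.null(freq)) {
    nonmiss <- colSums(!is.na(codes))
    if (any(nonmiss == 0L)) {
      qgrm_stop("SNP with all genotypes missing; cannot compute allele frequency",
                "qgrm_value_error")
    }
    freq <- colSums(codes, na.rm = TRUE) / (2 * nonmiss)
  } else {
    if (length(freq) != ncol(codes)) {
      qgrm_stop("freq length must equal the number of SNPs", "qgrm_value_error")
    }
    if (any(!is.finite(freq)) || any(freq < 0) || any(freq > 1)) {
      qgrm_stop("allele frequencies must lie in [0, 1]", "qgrm_domain_error")
    }
  }
  freq <- as.numeric(freq)
  names(freq) <- colnames(codes)
  structure(list(codes = codes,
                 freq = freq,
                 ids = rownames(codes),
                 snps = colnames(codes),
                 monomorphic = freq <= 0 | freq >= 1),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs\n",
              length(x$ids), length(x$snps)))
  cat(sprintf("  A1 frequency range: [%.4g, %.4g]\n",
              min(x$freq), max(x$freq)))
  nm <- sum(is.na(x$codes))
  if (nm) cat(sprintf("  missing genotypes: %d\n", nm))
  if (any(x$monomorphic)) {
    cat(sprintf("  monomorphic SNPs (flagged): %d\n", sum(x$monomorphic)))
  }
  invisible(x)
}

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

parse_code_token <- function(tok, path, line_no) {
  out <- suppressWarnings(as.integer(
    ifelse(tok %in% c("NA", "na", ".", ""), NA, tok)))
  bad <- which(!is.na(tok) & !(tok %in% c("NA", "na", ".", "")) &
                 (is.na(out) | !(out %in% 0:2)))
  if (length(bad)) {
    qgrm_stop(sprintf("%s line %d: genotype token '%s' is not 0/1/2/NA",
                      path, line_no, tok[bad[1]]),
              "qgrm_value_error")
  }
  out
}

#' Read a SNP genotype file
#'
#' Reads genotypes in either of two plain-text layouts:
#' * `tsv012`: header row with an ID column followed by one column per SNP;
#'   each subsequent row is an individual ID and its 0/1/2/NA codes.
#' * `plink_raw`: the layout written by `plink --recode A`
#'   (`FID IID PAT MAT SEX PHENOTYPE` then one dosage column per SNP);
#'   the IID column supplies the individual ID.
#'
#' In both layouts the codes count copies of the counted allele A1.  Sample
#' allele frequencies are computed unless a two-column frequency file
#' (`snp_id`, `p`) is supplied, in which case those frequencies override the
#' sample values for listed SNPs.  Monomorphic SNPs are retained but flagged;
#' [apply_qc()] removes them.
#'
#' @param path file path.
#' @param format `"tsv012"` or `"plink_raw"`.
#' @param freq_file optional path to a headered two-column table
#'   (`snp_id`, `p`) of A1 frequencies to use instead of sample frequencies.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv012", "plink_raw"),
                           freq_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    qgrm_stop(sprintf("genotype file not found: %s", path), "qgrm_io_error")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    qgrm_stop(sprintf("%s: need a header row and at least one individual", path),
              "qgrm_parse_error")
  }
  header <- split_fields(lines[1])
  n_meta <- if (format == "plink_raw") 6L else 1L
  if (length(header) <= n_meta) {
    qgrm_stop(sprintf("%s: header has no SNP columns", path), "qgrm_parse_error")
  }
  snps <- header[-seq_len(n_meta)]
  m <- length(snps)
  body <- lines[-1]
  n <- length(body)
  codes <- matrix(NA_integer_, n, m)
  ids <- character(n)
  id_col <- if (format == "plink_raw") 2L else 1L
  for (r in seq_len(n)) {
    f <- split_fields(body[r])
    if (length(f) != n_meta + m) {
      qgrm_stop(sprintf("%s line %d: %d fields, expected %d",
                        path, r + 1L, length(f), n_meta + m),
                "qgrm_parse_error")
    }
    ids[r] <- f[id_col]
    codes[r, ] <- parse_code_token(f[-seq_len(n_meta)], path, r + 1L)
  }
  if (anyDuplicated(ids)) {
    qgrm_stop(sprintf("%s: duplicate individual ID '%s'",
                      path, ids[duplicated(ids)][1]), "qgrm_id_error")
  }
  dimnames(codes) <- list(ids, snps)
  freq <- NULL
  if (!is.null(freq_file)) {
    ft <- utils::read.table(freq_file, header = TRUE,
                            stringsAsFactors = FALSE)
    if (ncol(ft) < 2L) {
      qgrm_stop("frequency file must have columns (snp_id, p)", "qgrm_parse_error")
    }
    G0 <- geno_matrix(codes)
    freq <- G0$freq
    hit <- match(ft[[1]], snps)
    freq[hit[!is.na(hit)]] <- ft[[2]][!is.na(hit)]
  }
  geno_matrix(codes, freq = freq)
}

#' Write a genotype matrix as TSV
#'
#' Writes the `tsv012` layout read by [read_genotypes()]; re-reading
#' reproduces codes and sample allele frequencies exactly.
#'
#' @param G a [geno_matrix()].
#' @param path output path.
#' @param header optional character vector of comment lines (written with a
#'   leading `#`).
#' @export
write_genotypes <- function(G, path, header = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("id", G$snps), collapse = "\t"), con)
  body <- apply(G$codes, 1L, function(r) {
    paste(ifelse(is.na(r), "NA", as.character(r)), collapse = "\t")
  })
  writeLines(paste(G$ids, body, sep = "\t"), con)
  invisible(path)
}

#' Quality control for a genotype panel
#'
#' Removes SNPs whose minor-allele frequency falls below `min_maf` and all
#' monomorphic SNPs (for which the per-SNP heterozygosity `2pq` is zero and
#' the within-SNP standardized relationship definitions would divide by
#' zero).  Missing genotypes are either retained for mean imputation in the
#' model codings (additive coding 0 = the column mean; dominance coding 0 =
#' its HWE mean) or the SNP is dropped.
#'
#' The operation is idempotent: applying the same QC twice equals applying it
#' once.
#'
#' @param G a [geno_matrix()].
#' @param min_maf minimum minor-allele frequency in `[0, 0.5)`; SNPs with
#'   `min(p, 1-p) < min_maf` are removed.
#' @param missing_policy `"mean_impute"` (default) keeps SNPs with missing
#'   codes, to be imputed at their null means when codings are built, or
#'   `"drop_snp"` removes any SNP with a missing code.
#' @return A filtered [geno_matrix()] with a `qc` attribute recording the
#'   settings.
#' @export
apply_qc <- function(G, min_maf = 0,
                     missing_policy = c("mean_impute", "drop_snp")) {
  stopifnot(inherits(G, "geno_matrix"))
  missing_policy <- match.arg(missing_policy)
  if (!is.numeric(min_maf) || min_maf < 0 || min_maf >= 0.5) {
    qgrm_stop("min_maf must lie in [0, 0.5)", "qgrm_domain_error")
  }
  p <- G$freq
  keep <- pmin(p, 1 - p) >= min_maf & p > 0 & p < 1
  if (missing_policy == "drop_snp") {
    keep <- keep & colSums(is.na(G$codes)) == 0L
  }
  if (!any(keep)) {
    qgrm_stop("QC removed every SNP (empty panel)", "qgrm_contract_error")
  }
  out <- geno_matrix(G$codes[, keep, drop = FALSE],
                     freq = G$freq[keep])
  attr(out, "qc") <- list(min_maf = min_maf, missing_policy = missing_policy,
                          snps_removed = sum(!keep))
  out
}

#' Write a relationship or correlation matrix
#'
#' @param M a symmetric matrix with row/column names ([rel_matrix()],
#'   [genomic_correlation()] output, or a plain named matrix).
#' @param path output path.
#' @param format `"square_tsv"` writes the full matrix with an ID header
#'   column/row; `"long_tsv"` writes the lower triangle including the
#'   diagonal as rows `(id1, id2, value)`.  Values are printed with 17
#'   significant digits (full double precision) so that a write/read round
#'   trip reproduces the matrix exactly.
#' @param header optional character vector of comment lines.
#' @export
write_matrix <- function(M, path, format = c("square_tsv", "long_tsv"),
                         header = NULL) {
  format <- match.arg(format)
  V <- unclass(M)
  attributes(V) <- attributes(V)[c("dim", "dimnames")]
  check_symmetric(V, what = "matrix to write")
  if (is.null(rownames(V))) {
    qgrm_stop("matrix must carry individual IDs as dimnames", "qgrm_id_error")
  }
  ids <- rownames(V)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (format == "square_tsv") {
    writeLines(paste(c("id", ids), collapse = "\t"), con)
    for (i in seq_along(ids)) {
      writeLines(paste(c(ids[i], fmt_num(V[i, ])), collapse = "\t"), con)
    }
  } else {
    writeLines("id1\tid2\tvalue", con)
    for (i in seq_along(ids)) {
      for (j in seq_len(i)) {
        writeLines(paste(ids[i], ids[j], fmt_num(V[i, j]), sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path file path.
#' @param format `"square_tsv"` or `"long_tsv"`; `"auto"` (default) detects
#'   the layout from the header row.
#' @return A symmetric numeric matrix with ID dimnames.
#' @export
read_matrix <- function(path, format = c("auto", "square_tsv", "long_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    qgrm_stop(sprintf("matrix file not found: %s", path), "qgrm_io_error")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  header <- split_fields(lines[1])
  if (format == "auto") {
    format <- if (identical(header, c("id1", "id2", "value")))
      "long_tsv" else "square_tsv"
  }
  if (format == "long_tsv") {
    parts <- strsplit(trimws(lines[-1]), "[ \t]+")
    id1 <- vapply(parts, `[`, "", 1L)
    id2 <- vapply(parts, `[`, "", 2L)
    val <- as.numeric(vapply(parts, `[`, "", 3L))
    ids <- unique(id1)  # each id has a diagonal row, in original order
    V <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    V[cbind(id1, id2)] <- val
    V[cbind(id2, id1)] <- val
    V
  } else {
    ids <- header[-1]
    n <- length(lines) - 1L
    V <- matrix(NA_real_, n, length(ids))
    rn <- character(n)
    for (r in seq_len(n)) {
      f <- split_fields(lines[r + 1L])
      rn[r] <- f[1]
      V[r, ] <- as.numeric(f[-1])
    }
    dimnames(V) <- list(rn, ids)
    V
  }
}

#' Read a phenotype table
#'
#' Expects a headered TSV whose first column is the individual ID, second
#' column the trait value, and any remaining columns fixed covariates.
#' Phenotyped individuals absent from `geno_ids` (when given) are dropped
#' with a message.
#'
#' @param path file path.
#' @param geno_ids optional character vector of genotyped IDs to align to.
#' @return A `data.frame` with columns `id`, `y`, then covariates.
#' @export
read_phenotypes <- function(path, geno_ids = NULL) {
  if (!file.exists(path)) {
    qgrm_stop(sprintf("phenotype file not found: %s", path), "qgrm_io_error")
  }
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tb) < 2L) {
    qgrm_stop("phenotype table needs at least (id, y) columns", "qgrm_parse_error")
  }
  names(tb)[1:2] <- c("id", "y")
  tb$id <- as.character(tb$id)
  if (anyDuplicated(tb$id)) {
    qgrm_stop("duplicate individual IDs in phenotype table", "qgrm_id_error")
  }
  if (!is.null(geno_ids)) {
    drop <- !(tb$id %in% geno_ids)
    if (any(drop)) {
      message(sprintf("dropping %d phenotyped individual(s) without genotypes",
                      sum(drop)))
      tb <- tb[!drop, , drop = FALSE]
    }
  }
  tb
}
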