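#' Centered additive SNP coding
#'
#' Deviation of the 0/1/2 A1-allele count from its mean `2p`: genotypes
#' A1A1, A1A2, A2A2 code as `2q`, `q - p`, `-2p` (with `p` the A1 frequency,
#' `q = 1 - p`).  Under sample-computed frequencies every column sums to
#' exactly zero.  Missing genotypes are imputed at the column mean (coded 0).
#'
#' @param G a QC'd [geno_matrix()] (no monomorphic SNPs).
#' @return Numeric n x m matrix `W_alpha`.
#' @export
additive_coding <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  check_polymorphic(G$freq)
  W <- sweep(G$codes, 2L, 2 * G$freq, `-`)
  W[is.na(G$codes)] <- 0
  dimnames(W) <- dimnames(G$codes)
  W
}

#' Dominance-deviation SNP coding
#'
#' The classical quantitative-genetics dominance deviation scores: genotypes
#' A1A1, A1A2, A2A2 code as `-2q^2`, `2pq`, `-2p^2`.  Under exact HWE
#' genotype proportions the population mean of the coding is zero, and with
#' unit dominance effect its variance is `(2pq)^2`.  Missing genotypes are
#' imputed at the HWE mean (coded 0).
#'
#' @inheritParams additive_coding
#' @return Numeric n x m matrix `W_delta`.
#' @export
dominance_coding <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  p <- G$freq
  check_polymorphic(p)
  q <- 1 - p
  X <- G$codes
  miss <- is.na(X)
  X[miss] <- -1L
  W <- sweep((X == 1L) * 1, 2L, 2 * p * q, `*`) +
    sweep((X == 2L) * 1, 2L, -2 * q^2, `*`) +
    sweep((X == 0L) * 1, 2L, -2 * p^2, `*`)
  dimnames(W) <- dimnames(G$codes)
  W
}

check_polymorphic <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    qgrm_stop("monomorphic SNP present (p = 0 or 1); run apply_qc() first",
              "qgrm_contract_error")
  }
  invisible(TRUE)
}

#' Expected per-SNP additive and dominance variances
#'
#' With unit effect sizes the expected additive variance of a SNP under HWE
#' is `2pq` and the expected dominance variance is `(2pq)^2`.  The means over
#' the m SNPs feed the across-SNP standardized relationship definitions.
#'
#' @param freq numeric vector of A1 frequencies, each strictly inside (0, 1).
#' @return List with `exp_var_alpha`, `exp_var_delta` and their means
#'   `mean_exp_var_alpha`, `mean_exp_var_delta`.
#' @export
expected_snp_variances <- function(freq) {
  if (any(!is.finite(freq)) || any(freq <= 0 | freq >= 1)) {
    qgrm_stop("allele frequencies must lie strictly in (0, 1)",
              "qgrm_domain_error")
  }
  va <- 2 * freq * (1 - freq)
  vd <- va^2
  list(exp_var_alpha = va, exp_var_delta = vd,
       mean_exp_var_alpha = mean(va), mean_exp_var_delta = mean(vd))
}

#' Sample per-SNP additive and dominance variances
#'
#' Uncentered second moment with divisor `n`: `w_i' w_i / n` for column
#' `w_i` of the coding matrix.  Divisor `n` (not `n - 1`) makes the sum over
#' SNPs equal the trace of `W W'` over `n`, so the across-SNP sample-variance
#' denominator coincides exactly with the average diagonal element of `W W'`.
#' The codings have null means under HWE (exactly null for the additive
#' coding under sample frequencies), so no re-centering is applied.
#'
#' @param W_alpha,W_delta coding matrices from [additive_coding()] /
#'   [dominance_coding()].
#' @return List with `sam_var_alpha`, `sam_var_delta` and their means.
#' @export
sample_snp_variances <- function(W_alpha, W_delta) {
  n <- nrow(W_alpha)
  if (is.null(n) || n < 2L) {
    qgrm_stop("need at least 2 individuals for sample variances",
              "qgrm_domain_error")
  }
  sa <- colSums(W_alpha^2) / n
  sd_ <- colSums(W_delta^2) / n
  list(sam_var_alpha = sa, sam_var_delta = sd_,
       mean_sam_var_alpha = mean(sa), mean_sam_var_delta = mean(sd_))
}

#' Build the SNP model matrices and per-SNP variances
#'
#' Assembles everything the relationship definitions consume: the centered
#' additive coding `W_alpha`, the dominance-deviation coding `W_delta`, and
#' the expected (`2pq`, `(2pq)^2`) and sample (`w'w/n`) per-SNP variances
#' with their means.
#'
#' @param G a QC'd [geno_matrix()].
#' @return Object of class `model_matrices`.
#' @examples
#' G <- geno_matrix(matrix(c(2L, 0L, 1L, 1L), 2, 2,
#'                  dimnames = list(c("a", "b"), c("s1", "s2"))))
#' M <- model_matrices(G)
#' colSums(M$W_alpha)  # exactly zero under sample frequencies
#' @export
model_matrices <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  Wa <- additive_coding(G)
  Wd <- dominance_coding(G)
  ev <- expected_snp_variances(G$freq)
  sv <- sample_snp_variances(Wa, Wd)
  structure(c(list(W_alpha = Wa, W_delta = Wd, freq = G$freq,
                   ids = G$ids, snps = G$snps), ev, sv),
            class = "model_matrices")
}

#' @export
print.model_matrices <- function(x, ...) {
  cat(sprintf("model_matrices: %d individuals x %d SNPs\n",
              length(x$ids), length(x$snps)))
  cat(sprintf("  mean expected variances: additive %.4g, dominance %.4g\n",
              x$mean_exp_var_alpha, x$mean_exp_var_delta))
  cat(sprintf("  mean sample variances:   additive %.4g, dominance %.4g\n",
              x$mean_sam_var_alpha, x$mean_sam_var_delta))
  invisible(x)
}
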