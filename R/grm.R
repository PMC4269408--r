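#' Tag a symmetric matrix as a relationship matrix
#'
#' @param values symmetric numeric matrix with ID dimnames.
#' @param definition one of `"I"`, `"II"`, `"IV"`, `"V"`, `"IVb_diag"`,
#'   `"PED_A"`, `"PED_D"`.
#' @param role `"additive"` or `"dominance"`.
#' @return The matrix with class `rel_matrix` and attributes `definition`
#'   and `role`.
#' @export
rel_matrix <- function(values,
                       definition = c("I", "II", "IV", "V", "IVb_diag",
                                      "PED_A", "PED_D"),
                       role = c("additive", "dominance")) {
  definition <- match.arg(definition)
  role <- match.arg(role)
  check_symmetric(values, what = "relationship matrix")
  if (any(!is.finite(values))) {
    qgrm_stop("relationship matrix has non-finite entries", "qgrm_value_error")
  }
  structure(values, class = c("rel_matrix", class(values)),
            definition = definition, role = role)
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("rel_matrix (definition %s, %s): %d x %d, mean diagonal %.4f\n",
              attr(x, "definition"), attr(x, "role"),
              nrow(x), ncol(x), mean(diag(unclass(x)))))
  invisible(x)
}

# Generic weighted constructor behind all four definitions.
# across:  W W' / sum(snp_var)
# within:  (1/m) * W diag(1/snp_var) W'
.grm_general <- function(W, snp_var, scheme = c("across", "within")) {
  scheme <- match.arg(scheme)
  if (any(snp_var <= 0)) {
    qgrm_stop("non-positive per-SNP variance in denominator; run apply_qc() first",
              "qgrm_contract_error")
  }
  if (scheme == "across") {
    denom <- sum(snp_var)
    if (denom <= 0) qgrm_stop("zero denominator", "qgrm_contract_error")
    tcrossprod(W) / denom
  } else {
    m <- ncol(W)
    tcrossprod(sweep(W, 2L, sqrt(snp_var), `/`)) / m
  }
}

#' Genomic relationship matrices
#'
#' Constructs the genomic additive and dominance relationship matrices under
#' one of four definitions distinguished by the standardization of the SNP
#' codings:
#'
#' * **I** — across-SNP standardization with expected SNP variances
#'   (equal SNP effects): `A = W_a W_a' / sum(2 p q)`,
#'   `D = W_d W_d' / sum((2 p q)^2)` (VanRaden-style).
#' * **II** — across-SNP standardization with sample SNP variances:
#'   the denominator equals the average diagonal of `W W'`
#'   (Hayes-Goddard), so the mean diagonal is exactly 1.
#' * **IV** — within-SNP standardization with expected variances:
#'   `A[j,k] = mean_i( w_a[j,i] w_a[k,i] / (2 p_i q_i) )`, analogously for
#'   dominance with `(2 p_i q_i)^2`; additive off-diagonals match the
#'   allele-frequency-weighted GRM of Yang-type estimators.
#' * **V** — within-SNP standardization with sample variances; the mean
#'   diagonal is exactly 1.
#'
#' Definitions I and II share a numerator and differ by a positive scalar
#' only, so their genomic correlations (Definition III) are identical.
#'
#' @param M a [model_matrices()] object.
#' @param definition `"I"`, `"II"`, `"IV"` or `"V"`.
#' @return List with components `A` and `D`, each a [rel_matrix()].
#' @examples
#' G <- geno_matrix(matrix(c(2L, 0L, 1L, 1L), 2, 2,
#'                  dimnames = list(c("a", "b"), c("s1", "s2"))))
#' grm(model_matrices(G), "I")$A
#' @export
grm <- function(M, definition = c("I", "II", "IV", "V")) {
  stopifnot(inherits(M, "model_matrices"))
  definition <- match.arg(definition)
  va <- switch(definition,
               I = M$exp_var_alpha, II = M$sam_var_alpha,
               IV = M$exp_var_alpha, V = M$sam_var_alpha)
  vd <- switch(definition,
               I = M$exp_var_delta, II = M$sam_var_delta,
               IV = M$exp_var_delta, V = M$sam_var_delta)
  scheme <- if (definition %in% c("I", "II")) "across" else "within"
  A <- .grm_general(M$W_alpha, va, scheme)
  D <- .grm_general(M$W_delta, vd, scheme)
  dimnames(A) <- dimnames(D) <- list(M$ids, M$ids)
  list(A = rel_matrix(A, definition, "additive"),
       D = rel_matrix(D, definition, "dominance"))
}

#' Genomic correlation matrix (Definitions III and VI)
#'
#' The genomic version of Wright's coefficient of relationship:
#' `gamma[j,k] = M[j,k] / sqrt(M[j,j] * M[k,k])`.  Applied to a Definition
#' I/II matrix this is "Definition III"; applied to a Definition IV/V matrix
#' it is "Definition VI".  All diagonal elements are 1, and Definitions I and
#' II yield identical correlations because they differ by a positive scalar.
#'
#' @param R a genomic [rel_matrix()] (additive or dominance) with strictly
#'   positive diagonal.
#' @return A matrix of class `cor_matrix` with attributes
#'   `source_definition` (`"III"` or `"VI"`) and `role`.
#' @export
genomic_correlation <- function(R) {
  if (!inherits(R, "rel_matrix")) {
    qgrm_stop("input must be a rel_matrix", "qgrm_value_error")
  }
  def <- attr(R, "definition")
  if (!def %in% c("I", "II", "IV", "V")) {
    qgrm_stop("genomic correlations require a Definition I/II/IV/V matrix",
              "qgrm_contract_error")
  }
  V <- unclass(R)
  attributes(V) <- attributes(V)[c("dim", "dimnames")]
  d <- diag(V)
  if (any(d <= 0)) {
    bad <- rownames(V)[which(d <= 0)[1]] %||% as.character(which(d <= 0)[1])
    qgrm_stop(sprintf("non-positive diagonal for individual '%s'", bad),
              "qgrm_domain_error")
  }
  s <- sqrt(d)
  C <- V / tcrossprod(s)
  structure(C, class = c("cor_matrix", class(C)),
            source_definition = if (def %in% c("I", "II")) "III" else "VI",
            role = attr(R, "role"))
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("cor_matrix (Definition %s, %s): %d x %d\n",
              attr(x, "source_definition"), attr(x, "role"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Allele-frequency-weighted additive diagonal (Definition IVb)
#'
#' The per-SNP diagonal contribution is the reciprocal of the frequency of
#' the homozygote's own allele (`1/p` for A1A1, `1/q` for A2A2) and 0 for a
#' heterozygote; the individual's diagonal is the mean over SNPs.  Under HWE
#' the expectation is `p^2/p + q^2/q = 1`.  Algebraically this equals
#' `1 + F_hat` with `F_hat = (x^2 - (1 + 2p) x + 2 p^2) / (2pq)`, the
#' allele-frequency-weighted inbreeding estimator used for GRM diagonals
#' designed for inbreeding rather than prediction.  Off-diagonal elements of
#' the full "IVb" matrix are those of Definition IV; only the diagonal is
#' produced here.
#'
#' Missing genotypes are skipped (mean over non-missing SNPs).
#'
#' @param G a QC'd [geno_matrix()].
#' @return Named numeric vector of diagonal values, one per individual.
#' @export
yang_diagonal <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  p <- G$freq
  check_polymorphic(p)
  X <- G$codes
  miss <- is.na(X)
  Xz <- X
  Xz[miss] <- -1L
  contrib <- sweep((Xz == 2L) * 1, 2L, 1 / p, `*`) +
    sweep((Xz == 0L) * 1, 2L, 1 / (1 - p), `*`)
  contrib[miss] <- NA_real_
  out <- rowMeans(contrib, na.rm = TRUE)
  names(out) <- G$ids
  out
}
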