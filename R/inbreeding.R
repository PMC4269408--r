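#' Genomic inbreeding from the GRM diagonal
#'
#' `F = A[j, j] - 1` using the diagonal of a genomic additive relationship
#' matrix built from the SNP model matrix (Definition I, II, IV or V).
#'
#' @param A an additive [rel_matrix()] of Definition I/II/IV/V.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
f_from_diagonal <- function(A) {
  if (!inherits(A, "rel_matrix")) {
    qgrm_stop("input must be a rel_matrix", "qgrm_value_error")
  }
  if (!identical(attr(A, "role"), "additive")) {
    qgrm_stop("diagonal-based inbreeding requires an additive relationship matrix",
              "qgrm_role_error")
  }
  if (!attr(A, "definition") %in% c("I", "II", "IV", "V")) {
    qgrm_stop("diagonal-based inbreeding requires Definition I, II, IV or V",
              "qgrm_contract_error")
  }
  diag(unclass(A)) - 1
}

#' Genomic inbreeding from the allele-frequency-weighted diagonal
#'
#' `F = A_IVb[j, j] - 1`, where the diagonal is [yang_diagonal()].  An
#' individual heterozygous at every SNP has `F = -1`; under HWE the
#' expectation is 0.
#'
#' @param G a QC'd [geno_matrix()].
#' @return Named numeric vector.
#' @export
f_yang <- function(G) {
  yang_diagonal(G) - 1
}

parent_pairs <- function(P, ids, what) {
  stopifnot(inherits(P, "pedigree"))
  known <- !is.na(P$sire) & !is.na(P$dam)
  geno <- known & P$sire %in% ids & P$dam %in% ids
  skipped <- sum(known & !geno)
  if (skipped > 0) {
    message(sprintf("%s: skipping %d individual(s) without both parents genotyped",
                    what, skipped))
  }
  P[geno, , drop = FALSE]
}

#' Genomic inbreeding from parental genomic relationship
#'
#' The inbreeding coefficient of an individual equals the coancestry
#' coefficient of its parents; with genomic coancestry equal to half the
#' genomic additive relationship this gives `F_A = A[j, k] / 2` for parents
#' `j`, `k`.  Only individuals with both parents genotyped are evaluated;
#' others are skipped with a message.
#'
#' @param A an additive [rel_matrix()] of Definition I/II/IV/V whose
#'   dimnames are the genotyped IDs.
#' @param P a [pedigree()] identifying each individual's parents (used only
#'   to locate parent pairs; no pedigree values enter the estimate).
#' @return Named numeric vector over the individuals with genotyped parents.
#' @export
f_parental <- function(A, P) {
  if (!inherits(A, "rel_matrix") || !identical(attr(A, "role"), "additive")) {
    qgrm_stop("f_parental requires an additive relationship matrix",
              "qgrm_role_error")
  }
  ids <- rownames(unclass(A))
  Pg <- parent_pairs(P, ids, "f_parental")
  out <- 0.5 * unclass(A)[cbind(Pg$sire, Pg$dam)]
  names(out) <- Pg$id
  out
}

#' Genomic inbreeding from parental genomic correlation
#'
#' `F_gamma = gamma[j, k] / 2` where `gamma` is the parental genomic additive
#' correlation (Definition III or VI).  Definition III here uses Definition
#' II ingredients and Definition VI uses Definition V ingredients.
#'
#' @param C an additive `cor_matrix` from [genomic_correlation()].
#' @param P a [pedigree()] identifying parent pairs.
#' @return Named numeric vector over the individuals with genotyped parents.
#' @export
f_gamma <- function(C, P) {
  if (!inherits(C, "cor_matrix") || !identical(attr(C, "role"), "additive")) {
    qgrm_stop("f_gamma requires an additive genomic correlation matrix",
              "qgrm_role_error")
  }
  ids <- rownames(unclass(C))
  Pg <- parent_pairs(P, ids, "f_gamma")
  out <- 0.5 * unclass(C)[cbind(Pg$sire, Pg$dam)]
  names(out) <- Pg$id
  out
}

#' Summaries and correlations of inbreeding estimators
#'
#' Given a table of per-individual inbreeding estimates (one column per
#' estimator, `NA` where undefined), returns per-estimator summary
#' statistics (mean, SD with divisor `n - 1`, range) and the Pearson
#' correlation matrix over pairwise-complete observations.  A zero-variance
#' column yields `NA` correlations (undefined, not zero).
#'
#' @param estimates a data.frame or named list of numeric vectors; vectors
#'   are aligned by name when named, otherwise by position.
#' @return List with elements `summary` (data.frame) and `correlations`
#'   (matrix).
#' @export
compare_inbreeding <- function(estimates) {
  if (!is.data.frame(estimates)) {
    vecs <- estimates
    all_named <- all(vapply(vecs, function(v) !is.null(names(v)), logical(1)))
    if (all_named) {
      ids <- Reduce(union, lapply(vecs, names))
      estimates <- data.frame(lapply(vecs, function(v) v[match(ids, names(v))]),
                              row.names = ids, check.names = FALSE)
    } else {
      estimates <- as.data.frame(vecs, check.names = FALSE)
    }
  }
  if (ncol(estimates) < 1L) qgrm_stop("no estimators supplied", "qgrm_value_error")
  complete <- rowSums(is.na(estimates)) == 0L
  if (sum(complete) < 3L) {
    qgrm_stop("need at least 3 individuals with all estimators defined",
              "qgrm_contract_error")
  }
  sm <- data.frame(
    method = names(estimates),
    n = vapply(estimates, function(v) sum(!is.na(v)), integer(1)),
    mean = vapply(estimates, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(estimates, function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
    min = vapply(estimates, function(v) min(v, na.rm = TRUE), numeric(1)),
    max = vapply(estimates, function(v) max(v, na.rm = TRUE), numeric(1)),
    row.names = NULL, check.names = FALSE)
  cors <- suppressWarnings(
    stats::cor(as.matrix(estimates), use = "pairwise.complete.obs"))
  list(summary = sm, correlations = cors)
}

#' Full genomic inbreeding report
#'
#' Computes, for every genotyped individual, the diagonal-based estimators
#' `F = A[j,j] - 1` under the requested definitions, the
#' allele-frequency-weighted `F_IVb`, the parental-relationship estimators
#' `F_A` per definition, the parental-correlation estimators `F_gamma`
#' (Definition III from Definition II; Definition VI from Definition V) and,
#' optionally, the pedigree inbreeding coefficient, then summarizes and
#' correlates them.
#'
#' @param G a QC'd [geno_matrix()].
#' @param P a [pedigree()]; used to locate parent pairs (and for `F_ped`).
#' @param definitions subset of `c("I", "II", "IV", "V")`.
#' @param include_pedigree also compute the pedigree inbreeding coefficient.
#' @return Object of class `inbreeding_report`: list with `table`
#'   (per-individual estimates), `summary` and `correlations`.
#' @export
inbreeding_report <- function(G, P, definitions = c("I", "II", "IV", "V"),
                              include_pedigree = TRUE) {
  stopifnot(inherits(G, "geno_matrix"), inherits(P, "pedigree"))
  definitions <- match.arg(definitions, several.ok = TRUE)
  M <- model_matrices(G)
  grms <- lapply(stats::setNames(definitions, definitions),
                 function(d) grm(M, d))
  ids <- G$ids
  align <- function(v) v[match(ids, names(v))]
  tab <- list()
  for (d in definitions) {
    tab[[paste0("F_", d)]] <- align(f_from_diagonal(grms[[d]]$A))
  }
  tab[["F_IVb"]] <- align(f_yang(G))
  for (d in definitions) {
    tab[[paste0("FA_", d)]] <- align(f_parental(grms[[d]]$A, P))
  }
  if ("II" %in% definitions) {
    tab[["Fg_III"]] <- align(f_gamma(genomic_correlation(grms[["II"]]$A), P))
  }
  if ("V" %in% definitions) {
    tab[["Fg_VI"]] <- align(f_gamma(genomic_correlation(grms[["V"]]$A), P))
  }
  if (include_pedigree) {
    tab[["F_ped"]] <- align(pedigree_inbreeding(P))
  }
  table <- data.frame(tab, row.names = ids, check.names = FALSE)
  cmp <- compare_inbreeding(table)
  structure(list(table = table, summary = cmp$summary,
                 correlations = cmp$correlations),
            class = "inbreeding_report")
}

#' @export
print.inbreeding_report <- function(x, ...) {
  cat("Genomic inbreeding report\n")
  print(x$summary, digits = 4)
  cat("\nCorrelations:\n")
  print(round(x$correlations, 3))
  invisible(x)
}
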