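#' Construct a pedigree
#'
#' Builds a validated, topologically sorted pedigree.  Parents that appear
#' only in the sire/dam columns are auto-added as founders (with a message).
#' Unknown parents are `NA` (the text sentinel `0` is accepted by
#' [read_pedigree()]).  Self-parenthood and ancestry cycles are rejected.
#'
#' @param id,sire,dam character vectors of equal length; `NA` (or `"0"`)
#'   marks an unknown parent.
#' @return A `data.frame` of class `pedigree` with columns `id`, `sire`,
#'   `dam`, ordered parents-before-offspring.
#' @examples
#' pedigree(c("C"), c("A"), c("B"))  # A and B auto-added as founders
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  sire[sire %in% c("0", "NA", ".", "")] <- NA
  dam[dam %in% c("0", "NA", ".", "")] <- NA
  if (length(sire) != length(id) || length(dam) != length(id)) {
    qgrm_stop("id, sire, dam must have equal length", "qgrm_value_error")
  }
  if (anyDuplicated(id)) {
    qgrm_stop(sprintf("duplicate individual '%s' in pedigree",
                      id[duplicated(id)][1]), "qgrm_id_error")
  }
  self <- !is.na(sire) & sire == id | !is.na(dam) & dam == id
  if (any(self)) {
    qgrm_stop(sprintf("individual '%s' is recorded as its own parent",
                      id[self][1]), "qgrm_pedigree_error")
  }
  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents)) {
    message(sprintf("adding %d parent(s) as founder(s): %s",
                    length(parents),
                    paste(utils::head(parents, 10), collapse = ", ")))
    id <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  ord <- toposort_pedigree(id, sire, dam)
  out <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  attr(out, "sorted") <- TRUE
  out
}

# Kahn's algorithm; reports a cycle (as the unresolvable individuals) on
# failure.  Ties are broken by input order so founder-first files round-trip.
toposort_pedigree <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  si <- match(sire, id)
  di <- match(dam, id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- vapply(idx, function(k) {
      if (placed[k]) return(FALSE)
      ok_s <- is.na(si[k]) || placed[si[k]]
      ok_d <- is.na(di[k]) || placed[di[k]]
      ok_s && ok_d
    }, logical(1))
    if (!any(ready)) break
    ord <- c(ord, idx[ready])
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    qgrm_stop(sprintf("pedigree contains an ancestry cycle involving: %s",
                      paste(id[!placed], collapse = ", ")),
              "qgrm_pedigree_error")
  }
  ord
}

#' Read a 3-column pedigree file
#'
#' Whitespace- or tab-separated columns `individual sire dam`, with `0`
#' (or `NA`) for an unknown parent.  A header row is detected when the first
#' line's fields are non-numeric labels such as `id sire dam`.
#'
#' @param path file path.
#' @return A [pedigree()] in topological order.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) {
    qgrm_stop(sprintf("pedigree file not found: %s", path), "qgrm_io_error")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) qgrm_stop("empty pedigree file", "qgrm_parse_error")
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    qgrm_stop(sprintf("%s line %d: expected 3 columns, found %d",
                      path, bad[1], lengths(parts)[bad[1]]),
              "qgrm_parse_error")
  }
  tb <- do.call(rbind, parts)
  if (identical(tolower(tb[1, 1]), "id") ||
      identical(tolower(tb[1, 2]), "sire")) {
    tb <- tb[-1, , drop = FALSE]
  }
  pedigree(tb[, 1], tb[, 2], tb[, 3])
}

#' Write a pedigree as 3-column TSV
#' @param P a [pedigree()].
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_pedigree <- function(P, path, header = NULL) {
  stopifnot(inherits(P, "pedigree"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("id\tsire\tdam", con)
  writeLines(paste(P$id,
                   ifelse(is.na(P$sire), "0", P$sire),
                   ifelse(is.na(P$dam), "0", P$dam), sep = "\t"), con)
  invisible(path)
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' The numerator relationship matrix `A`, equal to twice the coancestry
#' (kinship) coefficient: for individual `k` with parents `s`, `d`,
#' `A[j, k] = (A[j, s] + A[j, d]) / 2` for earlier `j`, and
#' `A[k, k] = 1 + A[s, d] / 2`.  Unknown parents contribute 0 and are
#' treated as unique unrelated, non-inbred founders.
#'
#' @param P a [pedigree()] (topologically ordered; enforced).
#' @return A [rel_matrix()] with `definition = "PED_A"`, `role = "additive"`.
#' @export
tabular_additive <- function(P) {
  stopifnot(inherits(P, "pedigree"))
  if (!isTRUE(attr(P, "sorted"))) {
    qgrm_stop("pedigree must be topologically ordered (use pedigree())",
              "qgrm_contract_error")
  }
  n <- nrow(P)
  si <- match(P$sire, P$id)
  di <- match(P$dam, P$id)
  A <- matrix(0, n, n, dimnames = list(P$id, P$id))
  for (k in seq_len(n)) {
    s <- si[k]; d <- di[k]
    if (k > 1L) {
      js <- seq_len(k - 1L)
      as_ <- if (is.na(s)) 0 else A[js, s]
      ad_ <- if (is.na(d)) 0 else A[js, d]
      A[js, k] <- A[k, js] <- 0.5 * (as_ + ad_)
    }
    A[k, k] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  rel_matrix(A, definition = "PED_A", role = "additive")
}

#' Pedigree dominance relationship matrix
#'
#' Classical (no-inbreeding) dominance relationship:
#' `D[j, k] = (A[sj, sk] A[dj, dk] + A[sj, dk] A[dj, sk]) / 4` for `j != k`,
#' with any unknown-parent term contributing 0, and `D[k, k] = 1`.
#' Full sibs of unrelated non-inbred parents have `D = 0.25`;
#' parent-offspring and half-sib pairs have `D = 0`.
#'
#' @param P a [pedigree()].
#' @param A_ped optional precomputed [tabular_additive()] result.
#' @return A [rel_matrix()] with `definition = "PED_D"`, `role = "dominance"`.
#' @export
pedigree_dominance <- function(P, A_ped = NULL) {
  stopifnot(inherits(P, "pedigree"))
  A <- if (is.null(A_ped)) tabular_additive(P) else A_ped
  A <- unclass(A)
  n <- nrow(P)
  si <- match(P$sire, P$id)
  di <- match(P$dam, P$id)
  a <- function(i, j) {
    if (is.na(i) || is.na(j)) 0 else A[i, j]
  }
  D <- diag(n)
  if (n >= 2L) {
    for (k in 2:n) {
      for (j in seq_len(k - 1L)) {
        D[j, k] <- D[k, j] <- 0.25 *
          (a(si[j], si[k]) * a(di[j], di[k]) +
           a(si[j], di[k]) * a(di[j], si[k]))
      }
    }
  }
  dimnames(D) <- list(P$id, P$id)
  rel_matrix(D, definition = "PED_D", role = "dominance")
}

#' Pedigree inbreeding coefficients
#'
#' `F` of an individual is the coancestry coefficient of its parents, i.e.
#' half the parental additive relationship.  Founders and individuals with an
#' unknown parent get `F = 0`.  Equivalently `F = diag(A) - 1`.
#'
#' @param P a [pedigree()].
#' @param A_ped optional precomputed [tabular_additive()] result.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
pedigree_inbreeding <- function(P, A_ped = NULL) {
  stopifnot(inherits(P, "pedigree"))
  A <- if (is.null(A_ped)) tabular_additive(P) else A_ped
  A <- unclass(A)
  si <- match(P$sire, P$id)
  di <- match(P$dam, P$id)
  f <- ifelse(is.na(si) | is.na(di), 0, 0.5 * A[cbind(si, di)])
  names(f) <- P$id
  f
}
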