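# Shared fixtures and independent oracles.

# Quick genotype panel with auto IDs.
make_geno <- function(codes, freq = NULL) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes))) rownames(codes) <- paste0("i", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- paste0("s", seq_len(ncol(codes)))
  storage.mode(codes) <- "integer"
  geno_matrix(codes, freq = freq)
}

random_geno <- function(n, m, p = NULL, seed = 1, informative = FALSE) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.15, 0.85)
  X <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (informative) {
    # keep SNPs with >= 2 distinct codes so every definition (including the
    # sample-variance denominators) is well defined on tiny panels
    keep <- apply(X, 2, function(x) length(unique(x)) >= 2L)
    X <- X[, keep, drop = FALSE]
  }
  make_geno(X)
}

# Exact-HWE panel: for each frequency p = a/(a+b) with integer genotype
# counts scaled by n0, stacks n0*p^2 A1A1, 2*n0*p*q het, n0*q^2 A2A2.
# Sample frequency equals p exactly and genotype proportions are exact HWE.
hwe_exact_geno <- function(num, den, n0 = NULL) {
  # num/den: vectors of integer numerators/denominators of p per SNP
  stopifnot(length(num) == length(den))
  if (is.null(n0)) n0 <- prod(unique(den))^2
  counts <- lapply(seq_along(num), function(i) {
    p <- num[i] / den[i]
    c2 <- n0 * p^2; c1 <- 2 * n0 * p * (1 - p); c0 <- n0 * (1 - p)^2
    stopifnot(abs(c2 - round(c2)) < 1e-9, abs(c1 - round(c1)) < 1e-9)
    rep(c(2L, 1L, 0L), times = round(c(c2, c1, c0)))
  })
  make_geno(do.call(cbind, counts))
}

# Independent per-element GRM oracle: literal summation formulas, no matrix
# algebra shared with the implementation.
grm_bruteforce <- function(G, definition, role) {
  X <- G$codes
  p <- G$freq
  q <- 1 - p
  n <- nrow(X); m <- ncol(X)
  w <- function(j, i) {
    x <- X[j, i]
    if (is.na(x)) return(0)
    if (role == "additive") x - 2 * p[i]
    else c(-2 * p[i]^2, 2 * p[i] * q[i], -2 * q[i]^2)[x + 1]
  }
  ev <- if (role == "additive") 2 * p * q else (2 * p * q)^2
  sv <- vapply(seq_len(m), function(i) {
    mean(vapply(seq_len(n), function(j) w(j, i)^2, 0))
  }, 0)
  v <- switch(definition, I = ev, II = sv, IV = ev, V = sv)
  out <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (definition %in% c("I", "II")) {
        out[j, k] <- sum(vapply(seq_len(m), function(i) w(j, i) * w(k, i), 0)) /
          sum(v)
      } else {
        out[j, k] <- mean(vapply(seq_len(m), function(i)
          w(j, i) * w(k, i) / v[i], 0))
      }
    }
  }
  dimnames(out) <- list(G$ids, G$ids)
  out
}

# Independent coancestry oracle: memoized recursion on parent pairs
# (path-counting identity), distinct from the iterative tabular fill.
kinship_recursive <- function(P) {
  ids <- P$id
  si <- match(P$sire, ids)
  di <- match(P$dam, ids)
  pos <- seq_along(ids)
  memo <- new.env(hash = TRUE)
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(min(a, b), max(a, b))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == b) {
      0.5 * (1 + phi(si[a], di[a]))
    } else {
      # recurse on the later-born individual
      lt <- if (pos[a] > pos[b]) a else b
      ot <- if (lt == a) b else a
      0.5 * (phi(si[lt], ot) + phi(di[lt], ot))
    }
    memo[[key]] <- val
    val
  }
  out <- outer(pos, pos, Vectorize(function(a, b) 2 * phi(a, b)))
  diag(out) <- vapply(pos, function(a) 2 * phi(a, a), 0)
  dimnames(out) <- list(ids, ids)
  out
}

# Random valid pedigree: founders then offspring of random earlier pairs.
random_pedigree <- function(n_founders, n_offspring, seed = 1) {
  set.seed(seed)
  id <- paste0("p", seq_len(n_founders + n_offspring))
  sire <- dam <- rep(NA_character_, n_founders + n_offspring)
  for (k in n_founders + seq_len(n_offspring)) {
    par <- sample(k - 1L, 2L)  # may coincide only if k-1 < 2 guarded by caller
    sire[k] <- id[par[1]]
    dam[k] <- id[par[2]]
  }
  suppressMessages(pedigree(id, sire, dam))
}

mean_over_pairs <- function(R, pairs) {
  if (nrow(pairs) == 0) return(NA_real_)
  V <- unclass(R)
  mean(V[cbind(pairs[, 1], pairs[, 2])])
}
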