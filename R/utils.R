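# Internal helpers shared across modules.

# Signal a package-classed condition so the CLI can distinguish user errors
# (bad input, contract violations) from internal failures.
qgrm_stop <- function(msg, class = "qgrm_error") {
  classes <- unique(c(class, "qgrm_error", "error", "condition"))
  stop(structure(class = classes, list(message = msg, call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    qgrm_stop("seed must be a single finite number", "qgrm_domain_error")
  }
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

check_symmetric <- function(M, tol = 1e-12, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    qgrm_stop(sprintf("%s must be a square matrix", what), "qgrm_contract_error")
  }
  scale <- max(1, max(abs(M)))
  if (max(abs(M - t(M))) > tol * scale) {
    qgrm_stop(sprintf("%s is not symmetric (tolerance %g)", what, tol),
              "qgrm_contract_error")
  }
  invisible(TRUE)
}

# Moore-Penrose pseudo-inverse of a symmetric matrix via eigendecomposition.
# Returns the inverse with an attribute "rank" so callers can warn on
# rank deficiency.
pinv_sym <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  thresh <- tol * max(abs(e$values), .Machine$double.eps)
  keep <- e$values > thresh
  if (!any(keep)) {
    inv <- matrix(0, nrow(M), ncol(M))
  } else {
    U <- e$vectors[, keep, drop = FALSE]
    inv <- U %*% (t(U) / e$values[keep])
  }
  attr(inv, "rank") <- sum(keep)
  inv
}

# Population variance (divisor n) about the mean.
var_n <- function(x) {
  mean((x - mean(x))^2)
}

fmt_num <- function(x) sprintf("%.17g", x)
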