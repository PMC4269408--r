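#' Variance components and heritabilities
#'
#' @param sigma2_a additive genetic variance.
#' @param sigma2_d dominance genetic variance (0 for an additive-only model).
#' @param sigma2_e residual variance.
#' @param convergence optional list of fitting diagnostics (attached as-is).
#' @return Object of class `var_components` with narrow-sense additive
#'   heritability `h2_a = s2a / (s2a + s2d + s2e)`, dominance heritability
#'   `h2_d`, and total (broad-sense) heritability `h2_t = h2_a + h2_d`.
#' @export
var_components <- function(sigma2_a, sigma2_d = 0, sigma2_e,
                           convergence = NULL) {
  if (any(c(sigma2_a, sigma2_d, sigma2_e) < 0)) {
    qgrm_stop("variance components must be nonnegative", "qgrm_domain_error")
  }
  tot <- sigma2_a + sigma2_d + sigma2_e
  if (tot <= 0) qgrm_stop("total variance must be positive", "qgrm_domain_error")
  structure(list(sigma2_a = sigma2_a, sigma2_d = sigma2_d,
                 sigma2_e = sigma2_e,
                 h2_a = sigma2_a / tot, h2_d = sigma2_d / tot,
                 h2_t = (sigma2_a + sigma2_d) / tot,
                 convergence = convergence),
            class = "var_components")
}

#' @export
print.var_components <- function(x, ...) {
  cat(sprintf("sigma2_a = %.6g  sigma2_d = %.6g  sigma2_e = %.6g\n",
              x$sigma2_a, x$sigma2_d, x$sigma2_e))
  cat(sprintf("h2_a = %.4f  h2_d = %.4f  h2_t = %.4f\n",
              x$h2_a, x$h2_d, x$h2_t))
  if (!is.null(x$convergence)) {
    cat(sprintf("(%s, %d iterations, %s)\n",
                x$convergence$algorithm %||% "?",
                x$convergence$iterations %||% NA_integer_,
                if (isTRUE(x$convergence$converged)) "converged"
                else "NOT converged"))
  }
  invisible(x)
}

as_plain <- function(M) {
  V <- unclass(M)
  attributes(V) <- attributes(V)[c("dim", "dimnames")]
  V
}

#' GBLUP of breeding values and dominance deviations
#'
#' Best linear unbiased prediction for the individual-level model
#' `y = X b + a + d + e` with `Var(a) = A s2a`, `Var(d) = D s2d`,
#' `Var(e) = I s2e` and one record per individual.  The solution is computed
#' in its generalized-least-squares form — `b` from the GLS normal equations
#' on `V = A s2a + D s2d + I s2e`, then `a = s2a A V^-1 (y - X b)` and
#' `d = s2d D V^-1 (y - X b)` — which equals the solution of Henderson's
#' mixed-model equations and remains exact when a genomic relationship
#' matrix is singular (its rank is at most `n - 1` under sample-frequency
#' centering), since only the positive-definite `V` is factorized.
#' A variance component at (or below) zero drops the corresponding random
#' effect, returning a zero vector for it (the shrinkage limit).
#'
#' @param y numeric response, one record per individual, ordered as the rows
#'   of `A`.
#' @param A additive genomic or pedigree [rel_matrix()].
#' @param D optional dominance [rel_matrix()]; `NULL` for additive-only.
#' @param X fixed-effect design matrix; default a column of ones
#'   (intercept).
#' @param varcomp a [var_components()] object.
#' @return Object of class `gblup`: list with `b` (fixed effects), `a`
#'   (genomic breeding values), `d` (dominance deviations), `g = a + d`,
#'   `residuals`, and `mme_resid`, the relative residual of the normal
#'   equations (solution tolerance; warned about above 1e-8).
#' @export
gblup <- function(y, A, D = NULL, X = NULL, varcomp) {
  stopifnot(inherits(varcomp, "var_components"))
  n <- length(y)
  Av <- as_plain(A)
  if (nrow(Av) != n) {
    qgrm_stop("length(y) must equal nrow(A)", "qgrm_contract_error")
  }
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  s2a <- varcomp$sigma2_a; s2d <- varcomp$sigma2_d; s2e <- varcomp$sigma2_e
  if (s2e <= 0) qgrm_stop("residual variance must be positive", "qgrm_domain_error")
  use_a <- s2a > 0
  use_d <- !is.null(D) && s2d > 0
  V <- diag(s2e, n)
  if (use_a) V <- V + s2a * Av
  if (use_d) V <- V + s2d * as_plain(D)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    qgrm_stop(sprintf("phenotypic covariance V not positive definite (rcond = %.3g)",
                      rcond(V)), "qgrm_numerical_error")
  }
  Vinv <- chol2inv(ch)
  T_ <- Vinv %*% X
  Mxx <- crossprod(X, T_)
  b <- tryCatch(solve(Mxx, crossprod(T_, y)), error = function(e) {
    qgrm_stop(sprintf("singular fixed-effect equations (rcond = %.3g)",
                      rcond(Mxx)), "qgrm_numerical_error")
  })
  mme_resid <- sqrt(sum((Mxx %*% b - crossprod(T_, y))^2)) /
    max(sqrt(sum(crossprod(T_, y)^2)), .Machine$double.eps)
  if (mme_resid > 1e-8) {
    warning(sprintf("normal-equation residual %.3g exceeds 1e-8", mme_resid))
  }
  r <- Vinv %*% (y - X %*% b)
  ids <- rownames(Av) %||% as.character(seq_len(n))
  a <- if (use_a) as.numeric(s2a * Av %*% r) else numeric(n)
  d <- if (use_d) as.numeric(s2d * as_plain(D) %*% r) else numeric(n)
  b <- as.numeric(b)
  names(b) <- colnames(X)
  names(a) <- names(d) <- ids
  structure(list(b = b, a = a, d = d, g = a + d,
                 residuals = as.numeric(y - X %*% b - a - d),
                 varcomp = varcomp, mme_resid = mme_resid),
            class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("gblup fit: %d individuals, %d fixed effect(s)\n",
              length(x$a), length(x$b)))
  cat(sprintf("  var(a-hat) = %.4g, var(d-hat) = %.4g, MME residual %.2g\n",
              stats::var(x$a), stats::var(x$d), x$mme_resid))
  invisible(x)
}

#' SNP-BLUP: the marker-effect form of the genomic mixed model
#'
#' Fits `y = X b + W_a alpha + W_d delta + e` with i.i.d. SNP effect priors
#' `Var(alpha_i) = s2a / sum(2 p q)` and `Var(delta_i) = s2d / sum((2pq)^2)`.
#' With these priors the implied covariance of `a = W_a alpha` is exactly
#' the Definition I additive relationship times `s2a`, so the transformed
#' predictions equal individual-level GBLUP under Definition I: the two
#' parameterizations are the same model.
#'
#' @param y numeric response.
#' @param M a [model_matrices()] object.
#' @param X fixed-effect design matrix (default intercept).
#' @param varcomp a [var_components()] object; `sigma2_d = 0` fits the
#'   additive-only model.
#' @return List with `b`, `alpha_hat`, `delta_hat`, and the individual-level
#'   `a = W_a alpha_hat`, `d = W_d delta_hat`.
#' @export
snp_blup <- function(y, M, X = NULL, varcomp) {
  stopifnot(inherits(M, "model_matrices"), inherits(varcomp, "var_components"))
  n <- length(y)
  if (n != nrow(M$W_alpha)) {
    qgrm_stop("length(y) must match the genotype panel", "qgrm_contract_error")
  }
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  s2e <- varcomp$sigma2_e
  use_a <- varcomp$sigma2_a > 0
  use_d <- varcomp$sigma2_d > 0
  W <- cbind(if (use_a) M$W_alpha, if (use_d) M$W_delta)
  if (is.null(W)) qgrm_stop("no genetic variance to fit", "qgrm_domain_error")
  m <- length(M$snps)
  lam <- c(if (use_a) rep(s2e / (varcomp$sigma2_a / sum(M$exp_var_alpha)), m),
           if (use_d) rep(s2e / (varcomp$sigma2_d / sum(M$exp_var_delta)), m))
  T_ <- cbind(X, W)
  C <- crossprod(T_)
  diag(C)[-seq_len(ncol(X))] <- diag(C)[-seq_len(ncol(X))] + lam
  sol <- solve(C, crossprod(T_, y))
  b <- sol[seq_len(ncol(X))]
  eff <- sol[-seq_len(ncol(X))]
  alpha_hat <- if (use_a) eff[seq_len(m)] else numeric(m)
  delta_hat <- if (use_d) eff[(if (use_a) m else 0L) + seq_len(m)] else numeric(m)
  names(alpha_hat) <- names(delta_hat) <- M$snps
  list(b = stats::setNames(b, colnames(X)),
       alpha_hat = alpha_hat, delta_hat = delta_hat,
       a = as.numeric(M$W_alpha %*% alpha_hat),
       d = as.numeric(M$W_delta %*% delta_hat))
}

#' Back-solve SNP effects from GBLUP predictions
#'
#' Conditional-expectation back-solve: with the definition's scaled coding
#' `W` and implied per-SNP prior scale `K` (identity for Definitions I-II;
#' `diag(1/(2pq))` for IV and `diag(1/sample variance)` for V, and the
#' dominance analogues), `alpha_hat = K W' (W K W')^- a_hat`.  When the
#' relationship matrix is full rank the reconstruction `W alpha_hat`
#' reproduces `a_hat`; under rank deficiency a pseudo-inverse is used and a
#' message is logged.
#'
#' @param M a [model_matrices()] object.
#' @param definition `"I"`, `"II"`, `"IV"` or `"V"` — must match the
#'   definition used to build the GBLUP relationship matrices.
#' @param fit a [gblup()] result.
#' @return List with `alpha_hat` and `delta_hat` (the latter zero when no
#'   dominance component was fitted).
#' @export
snp_effects <- function(M, definition = c("I", "II", "IV", "V"), fit) {
  stopifnot(inherits(M, "model_matrices"), inherits(fit, "gblup"))
  definition <- match.arg(definition)
  backsolve_one <- function(W, snp_var, u) {
    if (all(u == 0)) return(stats::setNames(numeric(ncol(W)), colnames(W)))
    k <- switch(definition,
                I = , II = rep(1, ncol(W)),
                IV = , V = 1 / snp_var)
    B <- tcrossprod(sweep(W, 2L, k, `*`), W)  # W K W'
    Binv <- pinv_sym(B)
    if (attr(Binv, "rank") < nrow(B)) {
      message(sprintf("rank-deficient relationship structure (rank %d < %d); using pseudo-inverse",
                      attr(Binv, "rank"), nrow(B)))
    }
    stats::setNames(as.numeric(k * crossprod(W, Binv %*% u)), colnames(W))
  }
  va <- if (definition %in% c("I", "IV")) M$exp_var_alpha else M$sam_var_alpha
  vd <- if (definition %in% c("I", "IV")) M$exp_var_delta else M$sam_var_delta
  list(alpha_hat = backsolve_one(M$W_alpha, va, fit$a),
       delta_hat = backsolve_one(M$W_delta, vd, fit$d))
}

#' REML estimation of additive and dominance variance components
#'
#' Restricted maximum likelihood for `y = X b + a + d + e` with
#' `Var(a) = A s2a`, `Var(d) = D s2d`, `Var(e) = I s2e`.  Two algorithms are
#' available: `"em"` (expectation-maximization; monotone in the restricted
#' likelihood, the default) and `"ai"` (average information with an EM
#' fallback step whenever an AI update would leave the parameter space or
#' decrease the likelihood).  Components are floored at
#' `floor_frac * var(y)`; convergence is declared when the largest relative
#' component change falls below `tol`.
#'
#' @param y numeric response.
#' @param A additive [rel_matrix()] (or plain symmetric matrix).
#' @param D optional dominance matrix; `NULL` fits the additive-only model.
#' @param X fixed-effect design (default intercept).
#' @param init optional [var_components()] starting values; default splits
#'   `var(y)` equally among the fitted components.
#' @param max_iter,tol iteration cap and relative-change tolerance.
#' @param algorithm `"em"` or `"ai"`.
#' @param floor_frac component floor as a fraction of `var(y)`.
#' @param verbose print per-iteration progress.
#' @return A [var_components()] whose `convergence` element records the
#'   algorithm, iteration count, per-iteration restricted log-likelihood
#'   trace (`loglik`), final relative change, convergence flag and any
#'   clamping/fallback notes.
#' @export
greml <- function(y, A, D = NULL, X = NULL, init = NULL,
                  max_iter = 1000L, tol = 1e-6,
                  algorithm = c("em", "ai"), floor_frac = 1e-8,
                  verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  Vs <- list(as_plain(A))
  if (!is.null(D)) Vs <- c(Vs, list(as_plain(D)))
  for (V in Vs) {
    if (nrow(V) != n) qgrm_stop("relationship matrix size must match length(y)",
                                "qgrm_contract_error")
  }
  nk <- length(Vs) + 1L  # + residual
  vy <- stats::var(y)
  floor_ <- floor_frac * vy
  sig <- if (is.null(init)) rep(vy / nk, nk) else {
    stopifnot(inherits(init, "var_components"))
    c(init$sigma2_a, if (!is.null(D)) init$sigma2_d, init$sigma2_e)
  }
  sig <- pmax(sig, floor_)
  notes <- character(0)
  ll_trace <- numeric(0)
  converged <- FALSE
  rel_change <- NA_real_
  iter_done <- 0L

  # One evaluation of P-quantities at the current components.  All trace
  # terms use tr(P V_k) = tr(Vinv V_k) - tr((X'Vinv X)^-1 (Vinv X)' V_k
  # (Vinv X)), so the only O(n^3) step per iteration is the Cholesky of V.
  eval_point <- function(sig) {
    V <- diag(sig[nk], n)
    for (k in seq_along(Vs)) V <- V + sig[k] * Vs[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) qgrm_stop("V not positive definite during REML",
                               "qgrm_numerical_error")
    Vinv <- chol2inv(ch)
    T_ <- Vinv %*% X
    Mxx <- crossprod(X, T_)
    Mi <- solve(Mxx)
    Py <- Vinv %*% y - T_ %*% (Mi %*% crossprod(T_, y))
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    determinant(Mxx, logarithm = TRUE)$modulus[1] +
                    sum(y * Py))
    Pz <- function(z) Vinv %*% z - T_ %*% (Mi %*% crossprod(T_, z))
    trPV <- numeric(nk)
    ypvpy <- numeric(nk)
    u <- vector("list", nk)
    for (k in seq_len(nk)) {
      if (k < nk) {
        Vk <- Vs[[k]]
        trPV[k] <- sum(Vinv * Vk) -
          sum(Mi * crossprod(T_, Vk %*% T_))
        u[[k]] <- Vk %*% Py
      } else {
        trPV[k] <- sum(diag(Vinv)) - sum(Mi * crossprod(T_))
        u[[k]] <- Py
      }
      ypvpy[k] <- sum(Py * u[[k]])
    }
    list(ll = ll, trPV = trPV, ypvpy = ypvpy, u = u, Pz = Pz)
  }

  ep <- eval_point(sig)
  for (it in seq_len(max_iter)) {
    iter_done <- it
    ll_trace <- c(ll_trace, ep$ll)
    em_step <- sig + sig^2 * (ep$ypvpy - ep$trPV) / n
    new_sig <- NULL
    if (algorithm == "ai") {
      score <- -0.5 * (ep$trPV - ep$ypvpy)
      AI <- matrix(0, nk, nk)
      Pu <- lapply(ep$u, ep$Pz)
      for (k in seq_len(nk)) {
        for (l in k:nk) {
          AI[k, l] <- AI[l, k] <- 0.5 * sum(ep$u[[k]] * Pu[[l]])
        }
      }
      cand <- tryCatch(sig + solve(AI, score), error = function(e) NULL)
      if (!is.null(cand) && all(is.finite(cand)) && all(cand > 0)) {
        new_sig <- cand
      } else {
        notes <- c(notes, sprintf("iteration %d: AI step rejected, EM fallback", it))
      }
    }
    if (is.null(new_sig)) new_sig <- em_step
    clamped <- new_sig < floor_
    if (any(clamped)) {
      notes <- c(notes, sprintf("iteration %d: component(s) %s clamped to floor",
                                it, paste(which(clamped), collapse = ",")))
      new_sig <- pmax(new_sig, floor_)
    }
    ep_new <- eval_point(new_sig)
    if (algorithm == "ai" && ep_new$ll < ep$ll - 1e-8 * abs(ep$ll)) {
      # AI overshoot: retreat to the monotone EM update
      new_sig <- pmax(em_step, floor_)
      ep_new <- eval_point(new_sig)
      notes <- c(notes, sprintf("iteration %d: AI decreased logLik, EM fallback", it))
    }
    rel_change <- max(abs(new_sig - sig) / pmax(abs(sig), floor_))
    if (verbose) {
      cat(sprintf("iter %3d  logLik %.6f  sigma: %s\n", it, ep_new$ll,
                  paste(sprintf("%.5g", new_sig), collapse = " ")))
    }
    sig <- new_sig
    ep <- ep_new
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  ll_trace <- c(ll_trace, ep$ll)
  if (!converged) {
    warning(sprintf("REML did not converge in %d iterations (last relative change %.3g)",
                    iter_done, rel_change))
  }
  var_components(sigma2_a = sig[1],
                 sigma2_d = if (!is.null(D)) sig[2] else 0,
                 sigma2_e = sig[nk],
                 convergence = list(algorithm = algorithm,
                                    iterations = iter_done,
                                    converged = converged,
                                    rel_change = rel_change,
                                    loglik = ll_trace,
                                    notes = notes))
}
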