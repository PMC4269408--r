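test_that("variance components validate and derive heritabilities that sum to one", {
  vc <- var_components(0.3, 0.1, 0.6)
  expect_equal(vc$h2_a, 0.3)
  expect_equal(vc$h2_d, 0.1)
  expect_equal(vc$h2_t, 0.4)
  expect_equal(vc$h2_a + vc$h2_d + vc$sigma2_e / 1, 1)
  expect_error(var_components(-1, 0, 1), class = "qgrm_domain_error")
})

test_that("gblup with identity A equals the closed-form ridge shrinkage", {
  set.seed(21)
  n <- 15
  y <- rnorm(n)
  V <- diag(n); dimnames(V) <- list(paste0("i", 1:n), paste0("i", 1:n))
  A <- rel_matrix(V, "I", "additive")
  vc <- var_components(2, 0, 1)
  fit <- gblup(y, A = A, varcomp = vc)
  # closed form: b = GLS mean, a = (s2a/(s2a+s2e)) (y - b)
  w <- 2 / 3
  b <- mean(y)
  expect_equal(unname(fit$b), b, tolerance = 1e-10)
  expect_equal(unname(fit$a), w * (y - b), tolerance = 1e-10)
})

test_that("gblup solves a 3-individual system identically to a dense solve", {
  set.seed(4)
  V0 <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3)
  dimnames(V0) <- list(letters[1:3], letters[1:3])
  A <- rel_matrix(V0, "I", "additive")
  y <- c(1.2, -0.4, 0.9)
  vc <- var_components(0.7, 0, 0.5)
  fit <- gblup(y, A = A, varcomp = vc)
  V <- 0.7 * V0 + 0.5 * diag(3)
  X <- matrix(1, 3, 1)
  b <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  a <- 0.7 * V0 %*% solve(V, y - X %*% b)
  expect_equal(unname(fit$b), as.numeric(b), tolerance = 1e-12)
  expect_equal(unname(fit$a), as.numeric(a), tolerance = 1e-12)
})

test_that("breeding values vanish in the zero-additive-variance limit", {
  G <- random_geno(25, 40, seed = 30)
  M <- model_matrices(G)
  g <- grm(M, "I")
  y <- rnorm(25)
  fit <- gblup(y, A = g$A, D = g$D, varcomp = var_components(0, 0.4, 0.6))
  expect_equal(unname(fit$a), rep(0, 25))
  expect_gt(stats::var(fit$d), 0)
})

test_that("SNP-BLUP and GBLUP under Definition I are the same model", {
  set.seed(12)
  n <- 60; m <- 120
  G <- random_geno(n, m, seed = 12)
  M <- model_matrices(G)
  y <- rnorm(n)
  vc <- var_components(0.5, 0.2, 0.5)
  sb <- snp_blup(y, M, varcomp = vc)
  fit <- gblup(y, A = grm(M, "I")$A, D = grm(M, "I")$D, varcomp = vc)
  expect_equal(sb$b, fit$b, tolerance = 1e-10)
  scale <- max(abs(fit$a))
  expect_lt(max(abs(sb$a - fit$a)) / scale, 1e-10)
  expect_lt(max(abs(sb$d - fit$d)) / max(abs(fit$d)), 1e-10)
})

test_that("back-solved SNP effects reconstruct the breeding values", {
  G <- random_geno(20, 50, seed = 44)
  M <- model_matrices(G)
  y <- rnorm(20)
  for (d in c("I", "V")) {
    g <- grm(M, d)
    fit <- gblup(y, A = g$A, D = g$D, varcomp = var_components(0.4, 0.2, 0.4))
    eff <- suppressMessages(snp_effects(M, d, fit))
    expect_lt(max(abs(M$W_alpha %*% eff$alpha_hat - fit$a)), 1e-6)
    expect_lt(max(abs(M$W_delta %*% eff$delta_hat - fit$d)), 1e-6)
  }
})

test_that("single-SNP back-solve equals the coding ratio and zero a gives zero effects", {
  G <- make_geno(cbind(c(2L, 1L, 0L, 1L)))
  M <- model_matrices(G)
  y <- c(1, 0.5, -1, 0.2)
  fit <- gblup(y, A = grm(M, "I")$A, varcomp = var_components(1, 0, 1))
  eff <- snp_effects(M, "I", fit)
  # with one SNP, a = W alpha exactly determines alpha
  expect_equal(unname(eff$alpha_hat[1]),
               sum(M$W_alpha[, 1] * fit$a) / sum(M$W_alpha[, 1]^2),
               tolerance = 1e-10)
  fit0 <- gblup(y, A = grm(M, "I")$A, varcomp = var_components(0, 0, 1))
  eff0 <- snp_effects(M, "I", fit0)
  expect_equal(unname(eff0$alpha_hat), 0)
})

test_that("EM-REML likelihood is monotone and recovers a null additive model", {
  # family structure sharpens the h2 resolution; noise-only phenotypes
  cfg <- sim_config(m = 400, seed = 79, n_fullsib_families = 50,
                    fullsib_size = 3)
  sim <- simulate_panel(cfg)
  g <- grm(sim$M, "I")
  set.seed(77)
  h2 <- replicate(5, {
    y <- rnorm(length(sim$M$ids))  # pure noise: h2 = 0
    vc <- suppressWarnings(greml(y, A = g$A, algorithm = "em",
                                 max_iter = 200, tol = 1e-5))
    ll <- vc$convergence$loglik
    expect_true(all(diff(ll) > -1e-8 * pmax(1, abs(ll[-length(ll)]))))
    vc$h2_a
  })
  expect_lt(mean(h2), 0.1)
})

test_that("EM and AI REML converge to the same optimum", {
  cfg <- sim_config(m = 300, seed = 31, n_founders = 150, h2_a = 0.5)
  sim <- simulate_panel(cfg)
  g <- grm(sim$M, "I")
  em <- greml(sim$pheno$y, A = g$A, algorithm = "em", tol = 1e-8,
              max_iter = 3000)
  ai <- greml(sim$pheno$y, A = g$A, algorithm = "ai", tol = 1e-8)
  expect_equal(em$sigma2_a, ai$sigma2_a, tolerance = 1e-3)
  expect_equal(em$sigma2_e, ai$sigma2_e, tolerance = 1e-3)
  expect_lt(ai$convergence$iterations, em$convergence$iterations)
})

test_that("non-convergence is flagged rather than silent", {
  cfg <- sim_config(m = 200, seed = 32, n_founders = 80, h2_a = 0.4)
  sim <- simulate_panel(cfg)
  g <- grm(sim$M, "I")
  expect_warning(vc <- greml(sim$pheno$y, A = g$A, algorithm = "em",
                             max_iter = 3, tol = 1e-12),
                 "did not converge")
  expect_false(vc$convergence$converged)
})
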