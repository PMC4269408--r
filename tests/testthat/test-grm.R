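test_that("every definition matches the per-element brute-force oracle", {
  for (seed in 1:5) {
    G <- random_geno(4, 3, seed = seed, informative = TRUE)
    expect_gte(ncol(G$codes), 1L)
    G <- apply_qc(G)
    M <- model_matrices(G)
    for (d in c("I", "II", "IV", "V")) {
      g <- grm(M, d)
      expect_equal(unclass(g$A), grm_bruteforce(G, d, "additive"),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(unclass(g$D), grm_bruteforce(G, d, "dominance"),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("Definition I reproduces hand-computed single-SNP values", {
  # two A1A1 individuals at one p = 0.5 SNP: A_12 = 1 / 0.5 = 2
  G <- make_geno(cbind(c(2L, 2L)), freq = 0.5)
  A <- grm(model_matrices(G), "I")$A
  expect_equal(A[1, 2], 2)
  expect_true(all(diag(unclass(A)) >= 0))
})

test_that("Definition II normalizes the mean diagonal to exactly 1 and is a scalar multiple of I", {
  G <- random_geno(30, 12, seed = 3)
  M <- model_matrices(G)
  g1 <- grm(M, "I"); g2 <- grm(M, "II")
  expect_equal(mean(diag(unclass(g2$A))), 1, tolerance = 1e-13)
  expect_equal(mean(diag(unclass(g2$D))), 1, tolerance = 1e-13)
  ratio <- unclass(g1$A) / unclass(g2$A)
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("Definition IV matches hand-computed within-SNP values", {
  # p = 0.2, individuals A1A1 and A2A2: (1.6 * -0.4) / 0.32 = -2
  G <- make_geno(cbind(c(2L, 0L)), freq = 0.2)
  A4 <- grm(model_matrices(G), "IV")$A
  expect_equal(A4[1, 2], -2)
  # heterozygotes contribute zero additive coding at p = 0.5
  G <- make_geno(cbind(c(1L, 1L)), freq = 0.5)
  expect_equal(grm(model_matrices(G), "IV")$A[1, 2], 0)
  # m identical SNPs average to the single-SNP value
  G <- make_geno(cbind(c(2L, 0L), c(2L, 0L), c(2L, 0L)), freq = rep(0.2, 3))
  expect_equal(grm(model_matrices(G), "IV")$A[1, 2], -2)
})

test_that("Definition V mean diagonal is 1 and V equals IV on exact-HWE panels", {
  G <- random_geno(40, 15, seed = 6)
  M <- model_matrices(G)
  g5 <- grm(M, "V")
  expect_equal(mean(diag(unclass(g5$A))), 1, tolerance = 1e-12)
  expect_equal(mean(diag(unclass(g5$D))), 1, tolerance = 1e-12)

  Gh <- hwe_exact_geno(num = c(1, 2), den = c(4, 5), n0 = 400)
  Mh <- model_matrices(Gh)
  expect_equal(unclass(grm(Mh, "V")$A), unclass(grm(Mh, "IV")$A),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(grm(Mh, "V")$D), unclass(grm(Mh, "IV")$D),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("genomic correlations have unit diagonal and collapse I/II to one Definition III", {
  G <- random_geno(20, 30, seed = 2)
  M <- model_matrices(G)
  C1 <- genomic_correlation(grm(M, "I")$A)
  C2 <- genomic_correlation(grm(M, "II")$A)
  expect_lt(max(abs(diag(unclass(C1)) - 1)), 1e-14)
  expect_lt(max(abs(unclass(C1) - unclass(C2))), 1e-14)
  expect_identical(attr(C1, "source_definition"), "III")
  expect_identical(attr(genomic_correlation(grm(M, "V")$D),
                        "source_definition"), "VI")
  expect_true(all(abs(unclass(C1)) <= 1 + 1e-12))
})

test_that("identical genotypes give genomic correlation 1", {
  codes <- rbind(c(2L, 1L, 0L, 1L), c(2L, 1L, 0L, 1L), c(0L, 2L, 2L, 0L))
  G <- make_geno(codes)
  C <- genomic_correlation(grm(model_matrices(G), "II")$A)
  expect_equal(C[1, 2], 1)
})

test_that("correlation transform rejects nonpositive diagonals, naming the individual", {
  V <- diag(c(1, 0))
  dimnames(V) <- list(c("a", "bad"), c("a", "bad"))
  R <- rel_matrix(V, "I", "additive")
  expect_error(genomic_correlation(R), "bad", class = "qgrm_domain_error")
})

test_that("IVb diagonal: heterozygotes 0, homozygotes 1/own-allele frequency, HWE mean 1", {
  G <- make_geno(rbind(c(1L, 1L), c(2L, 0L)), freq = c(0.5, 0.2))
  d <- yang_diagonal(G)
  expect_equal(unname(d[1]), 0)              # heterozygous at both
  expect_equal(unname(d[2]), mean(c(1 / 0.5, 1 / 0.8)))

  Gh <- hwe_exact_geno(num = c(1, 1, 3), den = c(2, 4, 10), n0 = 400)
  expect_equal(mean(yang_diagonal(Gh)), 1, tolerance = 1e-12)
})

test_that("IVb diagonal equals 1 + the allele-frequency-weighted inbreeding estimator", {
  G <- random_geno(15, 8, seed = 13)
  p <- G$freq
  X <- G$codes
  fhat <- sapply(seq_len(ncol(X)), function(i) {
    (X[, i]^2 - (1 + 2 * p[i]) * X[, i] + 2 * p[i]^2) / (2 * p[i] * (1 - p[i]))
  })
  expect_equal(unname(yang_diagonal(G)), unname(rowMeans(fhat) + 1),
               tolerance = 1e-12)
})
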