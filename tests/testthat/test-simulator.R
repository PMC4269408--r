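test_that("pedigree simulation instantiates the requested family classes", {
  cfg <- sim_config(m = 10, seed = 1, n_fullsib_families = 1, fullsib_size = 2)
  P <- simulate_pedigree(cfg)
  expect_equal(nrow(P), 4)
  cls <- attr(P, "classes")
  expect_equal(nrow(cls$fullsib), 1)
  expect_equal(nrow(cls$parent_offspring), 4)

  cfg0 <- sim_config(m = 10, seed = 1, n_founders = 5)
  P0 <- simulate_pedigree(cfg0)
  expect_true(all(is.na(P0$sire)))

  cfgi <- sim_config(m = 10, seed = 1, n_inbred_matings = 2)
  Pi <- simulate_pedigree(cfgi)
  F_ <- pedigree_inbreeding(Pi)
  expect_equal(unname(F_[attr(Pi, "classes")$inbred_offspring]), c(0.25, 0.25))
})

test_that("half-sib groups yield correct pedigree expectations", {
  cfg <- sim_config(m = 10, seed = 1, n_halfsib_groups = 2,
                    dams_per_sire = 2, offspring_per_dam = 2)
  P <- simulate_pedigree(cfg)
  cls <- attr(P, "classes")
  A <- tabular_additive(P)
  expect_equal(unname(mean_over_pairs(A, cls$halfsib)), 0.25)
  expect_equal(unname(mean_over_pairs(A, cls$fullsib)), 0.5)
  expect_equal(unname(mean_over_pairs(A, cls$parent_offspring)), 0.5)
})

test_that("gene dropping respects fixation and Mendelian transmission", {
  cfg <- sim_config(m = 5, seed = 2, n_fullsib_families = 3, freq = 0.5)
  P <- simulate_pedigree(cfg)
  cfg_fix <- sim_config(m = 5, seed = 2, n_fullsib_families = 3,
                        freq = rep(1 - 1e-12, 5))
  # p effectively 1: all founders homozygous A1A1, all offspring code 2
  Gfix <- gene_drop(P, cfg_fix, seed = 3)
  expect_true(all(Gfix$codes == 2L))

  G <- gene_drop(P, cfg, seed = 4)
  po <- attr(P, "classes")$parent_offspring
  for (r in seq_len(nrow(po))) {
    xp <- G$codes[po[r, 1], ]
    xo <- G$codes[po[r, 2], ]
    # parent and offspring always share at least one allele by state
    shared <- !(xp == 2 & xo == 0) & !(xp == 0 & xo == 2)
    expect_true(all(shared))
  }
})

test_that("founder allele frequencies concentrate around the target", {
  cfg <- sim_config(m = 50, seed = 5, n_founders = 2000, freq = 0.5)
  P <- simulate_pedigree(cfg)
  G <- gene_drop(P, cfg, seed = 6)
  expect_lt(max(abs(G$freq - 0.5)), 0.05)
})

test_that("founder genotypes pass a HWE chi-square screen at alpha = 0.001", {
  cfg <- sim_config(m = 200, seed = 7, n_founders = 500)
  sim_G <- gene_drop(simulate_pedigree(cfg), cfg, seed = 8)
  pvals <- apply(sim_G$codes, 2, function(x) {
    p <- mean(x) / 2
    if (p <= 0 || p >= 1) return(NA_real_)
    obs <- c(sum(x == 2), sum(x == 1), sum(x == 0))
    expd <- length(x) * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stats::pchisq(sum((obs - expd)^2 / expd), df = 1, lower.tail = FALSE)
  })
  expect_gte(mean(pvals > 0.001, na.rm = TRUE), 0.99)
})

test_that("identical seeds reproduce the full simulation bit for bit", {
  cfg <- sim_config(m = 100, seed = 11, n_fullsib_families = 10,
                    h2_a = 0.3, h2_d = 0.1)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$G$codes, s2$G$codes)
  expect_identical(s1$pheno$y, s2$pheno$y)
  expect_identical(s1$ped, s2$ped)
})

test_that("phenotype variance shares hit their targets exactly", {
  cfg <- sim_config(m = 500, seed = 12, n_founders = 150,
                    h2_a = 0.3, h2_d = 0.1)
  sim <- simulate_panel(cfg)
  ph <- sim$pheno
  vn <- function(x) mean((x - mean(x))^2)
  expect_equal(vn(ph$y), 1, tolerance = 1e-10)
  expect_equal(vn(ph$g_a) / vn(ph$y), 0.3, tolerance = 1e-6)
  expect_equal(vn(ph$g_d) / vn(ph$y), 0.1, tolerance = 1e-6)
  # truth is internally consistent
  expect_equal(as.numeric(sim$M$W_alpha %*% ph$alpha), ph$g_a,
               tolerance = 1e-10)
  expect_equal(as.numeric(sim$M$W_delta %*% ph$delta), ph$g_d,
               tolerance = 1e-10)
})

test_that("pure-noise and noise-free limits behave", {
  cfg <- sim_config(m = 100, seed = 13, n_founders = 60, h2_a = 0, h2_d = 0)
  sim <- simulate_panel(cfg)
  expect_equal(sim$pheno$g_a, rep(0, 60))
  expect_equal(sim$pheno$g_d, rep(0, 60))

  cfg2 <- sim_config(m = 100, seed = 14, n_founders = 60, h2_a = 0.999)
  sim2 <- simulate_panel(cfg2)
  vn <- function(x) mean((x - mean(x))^2)
  expect_lt(vn(sim2$pheno$e), 0.0011)
})

test_that("simulation configs are validated", {
  expect_error(sim_config(m = 10, seed = 1, h2_a = 0.6, h2_d = 0.5),
               class = "qgrm_domain_error")
  expect_error(sim_config(m = 10, seed = 1, freq = 1.2),
               class = "qgrm_domain_error")
  expect_error(sim_config(m = 10), "seed", class = "qgrm_domain_error")
})
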