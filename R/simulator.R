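#' Simulation configuration
#'
#' Describes a gene-dropping study: a pedigree of founder families, the SNP
#' panel drawn in founders at HWE, and a phenotype generated from per-SNP
#' additive and dominance effects plus Gaussian noise.
#'
#' Family designs are expressed as counts of groups:
#' * `n_fullsib_families` families of two new unrelated founders with
#'   `fullsib_size` offspring each (every offspring is also a
#'   parent-offspring pair with each parent);
#' * `n_halfsib_groups` groups of one sire mated to `dams_per_sire` dams
#'   with `offspring_per_dam` offspring each — offspring of the same dam are
#'   full sibs, offspring of different dams half sibs;
#' * `n_inbred_matings` matings of a full-sib pair (each from two new
#'   founders), producing one offspring with pedigree inbreeding 0.25;
#' * `n_founders` additional unrelated stand-alone founders.
#'
#' @param m number of unlinked biallelic SNPs.
#' @param seed RNG seed (mandatory: every replicate must be reproducible).
#' @param n_founders count of extra stand-alone founders.
#' @param n_fullsib_families,fullsib_size full-sib family design.
#' @param n_halfsib_groups,dams_per_sire,offspring_per_dam half-sib design.
#' @param n_inbred_matings count of full-sib matings.
#' @param freq founder A1 allele-frequency law: a single value in (0, 1), a
#'   length-2 range for per-SNP Uniform draws (default `c(0.05, 0.95)`), or
#'   a length-`m` vector.
#' @param h2_a,h2_d target additive and dominance heritabilities
#'   (`h2_a + h2_d < 1`).
#' @param mu phenotype intercept.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(m, seed,
                       n_founders = 0L,
                       n_fullsib_families = 0L, fullsib_size = 2L,
                       n_halfsib_groups = 0L, dams_per_sire = 2L,
                       offspring_per_dam = 1L,
                       n_inbred_matings = 0L,
                       freq = c(0.05, 0.95),
                       h2_a = 0, h2_d = 0, mu = 0) {
  if (missing(seed)) qgrm_stop("seed is mandatory", "qgrm_domain_error")
  if (m < 1L) qgrm_stop("m must be at least 1", "qgrm_domain_error")
  if (!length(freq) %in% c(1L, 2L, m)) {
    qgrm_stop("freq must be a value, a range, or one value per SNP",
              "qgrm_domain_error")
  }
  if (any(freq <= 0 | freq >= 1)) {
    qgrm_stop("founder allele frequencies must lie strictly in (0, 1)",
              "qgrm_domain_error")
  }
  if (h2_a < 0 || h2_d < 0 || h2_a + h2_d >= 1) {
    qgrm_stop("need h2_a >= 0, h2_d >= 0 and h2_a + h2_d < 1",
              "qgrm_domain_error")
  }
  structure(list(m = as.integer(m), seed = seed,
                 n_founders = as.integer(n_founders),
                 n_fullsib_families = as.integer(n_fullsib_families),
                 fullsib_size = as.integer(fullsib_size),
                 n_halfsib_groups = as.integer(n_halfsib_groups),
                 dams_per_sire = as.integer(dams_per_sire),
                 offspring_per_dam = as.integer(offspring_per_dam),
                 n_inbred_matings = as.integer(n_inbred_matings),
                 freq = freq, h2_a = h2_a, h2_d = h2_d, mu = mu),
            class = "sim_config")
}

#' Simulate a pedigree from a family design
#'
#' Founders are unrelated and non-inbred.  The returned pedigree carries a
#' `classes` attribute listing the identifiable relative pairs —
#' `fullsib`, `halfsib` and `parent_offspring` two-column ID matrices and
#' the `inbred_offspring` IDs — for downstream evaluation of relationship
#' expectations.
#'
#' @param cfg a [sim_config()].
#' @return A [pedigree()] with attribute `classes`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  id <- character(0); sire <- character(0); dam <- character(0)
  fs <- hs <- po <- matrix(character(0), 0, 2)
  inbred <- character(0)
  add <- function(i, s, d) {
    id <<- c(id, i); sire <<- c(sire, s); dam <<- c(dam, d)
  }
  pairs_of <- function(v) if (length(v) < 2L) matrix(character(0), 0, 2) else
    t(utils::combn(v, 2L))
  if (cfg$n_founders > 0L) {
    for (i in seq_len(cfg$n_founders)) add(sprintf("U%d", i), NA, NA)
  }
  for (f in seq_len(cfg$n_fullsib_families)) {
    s <- sprintf("FS%d.s", f); d <- sprintf("FS%d.d", f)
    add(s, NA, NA); add(d, NA, NA)
    kids <- sprintf("FS%d.o%d", f, seq_len(cfg$fullsib_size))
    for (k in kids) add(k, s, d)
    fs <- rbind(fs, pairs_of(kids))
    po <- rbind(po, cbind(rep(c(s, d), each = length(kids)), rep(kids, 2L)))
  }
  for (g in seq_len(cfg$n_halfsib_groups)) {
    s <- sprintf("HS%d.s", g)
    add(s, NA, NA)
    kids_by_dam <- vector("list", cfg$dams_per_sire)
    for (dm in seq_len(cfg$dams_per_sire)) {
      d <- sprintf("HS%d.d%d", g, dm)
      add(d, NA, NA)
      kids <- sprintf("HS%d.d%d.o%d", g, dm, seq_len(cfg$offspring_per_dam))
      for (k in kids) add(k, s, d)
      kids_by_dam[[dm]] <- kids
      fs <- rbind(fs, pairs_of(kids))
      po <- rbind(po, cbind(rep(c(s, d), each = length(kids)), rep(kids, 2L)))
    }
    if (cfg$dams_per_sire >= 2L) {
      dd <- utils::combn(cfg$dams_per_sire, 2L)
      for (c_ in seq_len(ncol(dd))) {
        hs <- rbind(hs, as.matrix(expand.grid(
          kids_by_dam[[dd[1, c_]]], kids_by_dam[[dd[2, c_]]],
          stringsAsFactors = FALSE)))
      }
    }
  }
  for (b in seq_len(cfg$n_inbred_matings)) {
    s <- sprintf("IB%d.s", b); d <- sprintf("IB%d.d", b)
    add(s, NA, NA); add(d, NA, NA)
    b1 <- sprintf("IB%d.b1", b); b2 <- sprintf("IB%d.b2", b)
    add(b1, s, d); add(b2, s, d)
    fs <- rbind(fs, c(b1, b2))
    kid <- sprintf("IB%d.x", b)
    add(kid, b1, b2)
    inbred <- c(inbred, kid)
  }
  if (!length(id)) qgrm_stop("empty simulation design", "qgrm_domain_error")
  P <- pedigree(id, sire, dam)
  attr(P, "classes") <- list(fullsib = fs, halfsib = hs,
                             parent_offspring = po,
                             inbred_offspring = inbred)
  P
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders are drawn per locus as Binomial(2, p) (HWE); each non-founder
#' inherits, independently at every locus, one allele from each parent with
#' transmission probability equal to half the parent's allele count (loci
#' unlinked, Mendelian segregation, no mutation).
#'
#' @param P a [pedigree()].
#' @param cfg a [sim_config()] supplying `m` and the founder frequency law.
#' @param seed optional seed (RNG state restored afterwards); when `NULL`
#'   the current RNG stream is used, as in [simulate_panel()].
#' @return A [geno_matrix()] with sample-computed frequencies and attribute
#'   `founder_freq` (the generating frequencies).
#' @export
gene_drop <- function(P, cfg, seed = NULL) {
  stopifnot(inherits(P, "pedigree"), inherits(cfg, "sim_config"))
  with_seed(seed, {
    m <- cfg$m
    p <- switch(as.character(length(cfg$freq)),
                "1" = rep(cfg$freq, m),
                "2" = stats::runif(m, cfg$freq[1], cfg$freq[2]),
                cfg$freq)
    n <- nrow(P)
    si <- match(P$sire, P$id)
    di <- match(P$dam, P$id)
    codes <- matrix(0L, n, m,
                    dimnames = list(P$id, sprintf("snp%d", seq_len(m))))
    for (k in seq_len(n)) {
      if (is.na(si[k]) && is.na(di[k])) {
        codes[k, ] <- stats::rbinom(m, 2L, p)
      } else {
        # unknown single parents segregate from the founder population
        from_s <- if (is.na(si[k])) stats::rbinom(m, 1L, p) else
          stats::rbinom(m, 1L, codes[si[k], ] / 2)
        from_d <- if (is.na(di[k])) stats::rbinom(m, 1L, p) else
          stats::rbinom(m, 1L, codes[di[k], ] / 2)
        codes[k, ] <- from_s + from_d
      }
    }
    G <- geno_matrix(codes)
    attr(G, "founder_freq") <- p
    G
  })
}

#' Simulate phenotypes from SNP additive and dominance effects
#'
#' Per-SNP effects are drawn i.i.d. normal and rescaled so the realized
#' variance shares are exact: `var(W_a alpha) / var(y) = h2_a` and
#' `var(W_d delta) / var(y) = h2_d` (population variances, divisor n), with
#' `var(y) = 1`.  Exactness is achieved by (i) deflecting `delta` within the
#' dominance coding space so the realized dominance values are uncorrelated
#' with the realized breeding values, and (ii) residualizing the noise on
#' both genetic components, so the three variance contributions add with no
#' cross terms.  The recorded truth (`alpha`, `delta`, variance components)
#' is therefore exactly consistent with the generated `y`.
#'
#' @param M a [model_matrices()] object from gene-dropped genotypes.
#' @param cfg a [sim_config()] supplying `h2_a`, `h2_d`, `mu`.
#' @param seed optional seed (RNG state restored afterwards).
#' @return List with `y` (named), `alpha`, `delta`, `g_a`, `g_d`, `e`, and
#'   `varcomp` (the true [var_components()]).
#' @export
simulate_phenotypes <- function(M, cfg, seed = NULL) {
  stopifnot(inherits(M, "model_matrices"), inherits(cfg, "sim_config"))
  with_seed(seed, {
    n <- length(M$ids); m <- length(M$snps)
    h2a <- cfg$h2_a; h2d <- cfg$h2_d
    if (n < 3L) qgrm_stop("need at least 3 individuals for phenotypes",
                          "qgrm_domain_error")
    alpha <- numeric(m); delta <- numeric(m)
    g_a <- numeric(n); g_d <- numeric(n)
    if (h2a > 0) {
      alpha <- stats::rnorm(m)
      g_a <- as.numeric(M$W_alpha %*% alpha)
      sc <- sqrt(h2a / var_n(g_a))
      alpha <- alpha * sc
      g_a <- g_a * sc
    }
    if (h2d > 0) {
      delta <- stats::rnorm(m)
      g_d <- as.numeric(M$W_delta %*% delta)
      if (h2a > 0) {
        # make realized dominance orthogonal to realized breeding values,
        # staying inside the span of W_delta so `delta` remains the truth
        v <- as.numeric(crossprod(M$W_delta, g_a))
        denom <- sum(v^2)  # = g_a' W_d W_d' g_a
        if (denom > 0) {
          t_ <- sum(g_a * g_d) / denom
          delta <- delta - t_ * v
          g_d <- as.numeric(M$W_delta %*% delta)
        }
      }
      vgd <- var_n(g_d)
      if (vgd <= 0) qgrm_stop("degenerate dominance values in simulation",
                              "qgrm_numerical_error")
      sc <- sqrt(h2d / vgd)
      delta <- delta * sc
      g_d <- g_d * sc
    }
    h2e <- 1 - h2a - h2d
    e <- stats::rnorm(n)
    # strip any sample correlation with the genetic values and the mean
    Q <- cbind(rep(1, n), if (h2a > 0) g_a, if (h2d > 0) g_d)
    e <- as.numeric(stats::lm.fit(Q, e)$residuals)
    e <- e * sqrt(h2e / var_n(e))
    y <- cfg$mu + g_a + g_d + e
    names(y) <- M$ids
    list(y = y, alpha = stats::setNames(alpha, M$snps),
         delta = stats::setNames(delta, M$snps),
         g_a = g_a, g_d = g_d, e = e,
         varcomp = var_components(h2a, h2d, h2e))
  })
}

#' Run a full simulation: pedigree, genotypes, phenotypes
#'
#' Seeds the RNG once from `cfg$seed`, then simulates the pedigree,
#' gene-drops the genotype panel and generates phenotypes.  The same
#' configuration always yields bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return List with `ped`, `G` ([geno_matrix()]), `M` ([model_matrices()])
#'   and `pheno` (see [simulate_phenotypes()]).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    ped <- simulate_pedigree(cfg)
    G <- gene_drop(ped, cfg)
    M <- model_matrices(apply_qc(G, min_maf = 0))
    pheno <- simulate_phenotypes(M, cfg)
    list(ped = ped, G = G, M = M, pheno = pheno)
  })
}
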