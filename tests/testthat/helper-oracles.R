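# Independent brute-force oracles used to check the exact-test machinery.
# These deliberately avoid the code paths (and the stats functions) the
# package uses: p-values by full hypergeometric enumeration, odds ratios by
# likelihood-grid scan, rank-sum p by permutation enumeration, BH by the
# direct step-up formula.

# Two-sided Fisher p: sum of hypergeometric probabilities of all tables with
# the observed margins that are no more probable than the observed one.
oracle_fisher_p <- function(tab) {
  m1 <- sum(tab[1, ])
  m2 <- sum(tab[2, ])
  k <- sum(tab[, 1])
  if (m1 == 0 || m2 == 0 || k == 0 || k == m1 + m2) {
    return(1)
  }
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(m1 + m2, k)
  probs <- exp(logp)
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Conditional log-likelihood of log-odds-ratio g for all x in the support,
# shared across tables with the same margins. Returns argmax per x by a
# coarse grid scan plus local refinement.
oracle_or_cmle <- function(tab) {
  m1 <- sum(tab[1, ])
  m2 <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x <- tab[1, 1]
  if (m1 == 0 || m2 == 0 || k == 0 || k == m1 + m2) {
    return(NaN)
  }
  lo <- max(0, k - m2)
  hi <- min(k, m1)
  if (x == hi) {
    return(Inf)
  }
  if (x == lo) {
    return(0)
  }
  u <- lo:hi
  lc <- lchoose(m1, u) + lchoose(m2, k - u)
  loglik <- function(g) {
    M <- lc + outer(u, g)
    mx <- apply(M, 2, max)
    x * g - (mx + log(colSums(exp(sweep(M, 2, mx, "-")))))
  }
  g <- seq(-15, 15, by = 0.05)
  g0 <- g[which.max(loglik(g))]
  g2 <- seq(g0 - 0.05, g0 + 0.05, by = 5e-4)
  exp(g2[which.max(loglik(g2))])
}

# Exact two-sided rank-sum p: enumerate every assignment of the pooled ranks
# to group 1; p = 2 * min tail, capped at 1.
oracle_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  sums <- combn(r, n1, sum)
  min(1, 2 * min(mean(sums <= obs + 1e-9), mean(sums >= obs - 1e-9)))
}

# Benjamini-Hochberg by the direct step-up formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# Random valid variant catalog for property tests.
random_catalog <- function(n, seed) {
  withr::with_seed(seed, {
    loc <- sample(c("exon", "intron"), n, replace = TRUE, prob = c(0.9, 0.1))
    tibble::tibble(
      hgvs_c = sprintf("c.%dA>G", sample(1e5, n)),
      hgvs_p = NA_character_,
      location_kind = loc,
      exon_number = ifelse(loc == "exon", sample(1:10, n, replace = TRUE), NA_integer_),
      domain = sample(c("transmembrane", "non_transmembrane", "unassigned"), n, replace = TRUE),
      mutation_type = sample(
        c("missense", "frameshift", "nonsense", "splicing", "inframe_indel", "start_loss"),
        n,
        replace = TRUE
      ),
      acmg_class = sample(c("P", "LP", "VUS", "LB", "B"), n, replace = TRUE)
    )
  })
}

# Patient cohort with configurable genotype mix and per-group phenotype rates.
random_patients <- function(n, seed, p_pheno_hom = 0.2, p_pheno_chet = 0.2,
                            phenotype = "cardiomyopathy", frac_hom = 0.4) {
  withr::with_seed(seed, {
    hom <- runif(n) < frac_hom
    sites <- c("c.760C>T", "c.1400C>G", "c.844C>T", "c.51C>G")
    types <- c("c.760C>T" = "nonsense", "c.1400C>G" = "missense",
      "c.844C>T" = "nonsense", "c.51C>G" = "missense")
    a1 <- sample(sites, n, replace = TRUE)
    a2 <- ifelse(hom, a1, sample(sites, n, replace = TRUE))
    # force compound hets to differ
    clash <- !hom & a1 == a2
    a2[clash] <- sites[(match(a1[clash], sites)) %% length(sites) + 1]
    has <- runif(n) < ifelse(hom, p_pheno_hom, p_pheno_chet)
    tibble::tibble(
      id = sprintf("R%04d", seq_len(n)),
      age_group = sample(c("infant_child", "adult"), n, replace = TRUE, prob = c(0.7, 0.3)),
      allele1_hgvs = a1, allele1_type = unname(types[a1]),
      allele2_hgvs = a2, allele2_type = unname(types[a2]),
      phenotypes = ifelse(has, phenotype, "")
    )
  })
}
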