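obsRow <- function(snp, hyb, dens = "HPD", alt = 5, tot = 10)
  data.frame(snp_id = snp, hybrid_id = hyb, density = dens,
             replicate = 1L, alt_count = alt, total_count = tot,
             stringsAsFactors = FALSE)

test_that("ASE filters apply inclusive bounds per SNP and observation", {
  nine <- do.call(rbind, lapply(sprintf("H%02d", 1:9), function(h)
    obsRow("snpA", h)))
  ten <- do.call(rbind, lapply(sprintf("H%02d", 1:10), function(h)
    obsRow("snpB", h)))
  shallow <- obsRow("snpB", "H11", tot = 9)
  out <- filterASEObservations(rbind(nine, ten, shallow))
  expect_setequal(unique(out$snp_id), "snpB")   # 9 hybrids is too few
  expect_true(all(out$total_count >= 10))       # exactly 10 reads is kept
  expect_identical(nrow(out), 10L)
  expect_warning(filterASEObservations(obsRow("x", "H1")[0, ]), "empty")
})

test_that("the null ratio is the dataset median", {
  obs <- obsRow(c("a", "b", "c"), "H1", alt = c(4, 5, 6), tot = 10)
  expect_equal(computeNullRatio(obs), 0.5)
  sym <- obsRow(sprintf("s%d", 1:10), "H1", alt = c(1:5, 9:5), tot = 10)
  expect_equal(computeNullRatio(sym), 0.5)
  expect_error(computeNullRatio(obs[0, ]), "empty")
})

test_that("BH adjustment reproduces the hand-computed step-up rule", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFDR(0.2), 0.2)
  expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
  expect_error(bhFDR(c(0.1, NA)), "NA")
  # independent step-up oracle on random inputs
  stepUp <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(4)
  for (k in 1:5) {
    p <- runif(25)
    expect_equal(bhFDR(p), stepUp(p))
  }
})

test_that("a SNP generated at the null is not called significant", {
  set.seed(8)
  hy <- sprintf("H%02d", 1:20)
  obs <- do.call(rbind, lapply(hy, function(h)
    rbind(obsRow("s", h, "HPD", rbinom(1, 1e4, 0.5), 1e4),
          obsRow("s", h, "LPD", rbinom(1, 1e4, 0.5), 1e4))))
  fit <- fitASEGLMM(obs, null = 0.5, spec = quickSpec(3))
  expect_gt(fit$post_p, 0.2)
  expect_true(fit$ratio > 0.45 && fit$ratio < 0.55)
})

test_that("a strongly imbalanced SNP is recovered and agrees with a
          maximum-likelihood logit oracle", {
  set.seed(9)
  hy <- sprintf("H%02d", 1:20)
  obs <- do.call(rbind, lapply(hy, function(h)
    rbind(obsRow("s", h, "HPD", rbinom(1, 100, 0.2), 100),
          obsRow("s", h, "LPD", rbinom(1, 100, 0.2), 100))))
  fit <- fitASEGLMM(obs, null = 0.5, spec = aseModelSpec(seed = 2))
  expect_lt(abs(fit$ratio - 0.2), 0.05)
  expect_lt(fit$post_p, 0.05)
  # fixed-effect logit fit ignoring random effects as a sanity oracle
  glmFit <- glm(cbind(alt_count, total_count - alt_count) ~ 1,
                family = binomial, data = obs)
  expect_lt(abs(fit$ratio - plogis(coef(glmFit))), 0.05)
})

test_that("the genotype random effect absorbs a single extreme hybrid", {
  set.seed(10)
  hy <- sprintf("H%02d", 1:15)
  obs <- do.call(rbind, lapply(hy, function(h)
    obsRow("s", h, "HPD", rbinom(1, 200, 0.5), 200)))
  # one deeply covered hybrid with extreme imbalance dominates the pooled
  # estimate; the per-hybrid random effect caps its influence on beta0
  obs$alt_count[1] <- 4875
  obs$total_count[1] <- 5000
  fit <- fitASEGLMM(obs, null = 0.5, spec = aseModelSpec(seed = 4))
  pooledRatio <- sum(obs$alt_count) / sum(obs$total_count)
  expect_lt(abs(fit$ratio - 0.5), abs(pooledRatio - 0.5))
})

test_that("population scan output is reproducible and self-consistent", {
  st <- smallStudy()
  res1 <- fitASEPopulation(st$alleleCounts, minHybrids = 4, minTotal = 10,
                           spec = quickSpec(11))
  res2 <- fitASEPopulation(st$alleleCounts, minHybrids = 4, minTotal = 10,
                           spec = quickSpec(11))
  expect_identical(res1$fits, res2$fits)
  f <- res1$fits
  expect_true(all(f$ratio > 0 & f$ratio < 1))
  expect_true(all(f$ci_low <= f$ratio & f$ratio <= f$ci_high))
  expect_identical(f$significant, !is.na(f$fdr) & f$fdr < 0.05)
})

test_that("summary percentages and MAF stratification are exact", {
  fits <- data.frame(snp_id = sprintf("s%05d", 1:14345),
                     ratio = 0.5,
                     significant = c(rep(TRUE, 2857), rep(FALSE, 11488)),
                     stringsAsFactors = FALSE)
  genes <- sprintf("g%04d", 1:5699)
  sigGene <- c(rep(genes[1:1654], length.out = 2857),
               rep(genes[1655:5699], length.out = 11488))
  snpGene <- data.frame(snp_id = fits$snp_id, gene_id = sigGene)
  s <- summarizeASE(fits, snpGene)
  expect_equal(round(s$pctSignificant, 1), 19.9)
  expect_equal(round(s$pctGenesSignificant, 1), 29.0)
  # low-MAF enrichment fold
  af <- setNames(rep(c(0.05, 0.3), c(1000, 13345)), fits$snp_id)
  fits2 <- fits
  fits2$significant <- FALSE
  fits2$significant[1:632] <- TRUE                 # 63.2% of rare SNPs
  fits2$significant[1001:(1000 + 2334)] <- TRUE    # 17.5% of common SNPs
  s2 <- summarizeASE(fits2, altFreq = af)
  expect_equal(round(s2$pctSignificantLowMAF, 1), 63.2)
  expect_equal(round(s2$mafFoldRatio, 1), 3.6)
  # no significant SNPs: zero percentages, empty gene set
  fits$significant <- FALSE
  s0 <- summarizeASE(fits, snpGene)
  expect_equal(s0$pctSignificant, 0)
  expect_identical(s0$nGenesSignificant, 0L)
})

test_that("posterior intervals widen with the genotype effect SD", {
  widths <- sapply(seq_along(c(0.05, 0.4, 1.0)), function(k) {
    sdv <- c(0.05, 0.4, 1.0)[k]
    cfg <- simulationConfig(nHybrids = 12, nSnps = 12, seed = 40 + k,
                            aseMeanRatio = 0.5, beta0Sd = 0,
                            aseEffectSd = sdv, densityEffectSd = 0)
    ac <- simulateAlleleCounts(informativeTrios(12, 12), cfg)
    fits <- do.call(rbind, lapply(split(ac$counts, ac$counts$snp_id),
                                  function(o) {
      set.seed(k); fitASEGLMM(o, 0.5, quickSpec(k))
    }))
    mean(fits$ci_high - fits$ci_low)
  })
  expect_true(all(diff(widths) > 0))
})
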