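# Shared small simulated study, built once per test run.
.cache <- new.env(parent = emptyenv())

smallStudy <- function() {
  if (is.null(.cache$study)) {
    cfg <- simulationConfig(nHybrids = 5, nSnps = 150, nGenes = 250,
                            seed = 101)
    .cache$study <- simulateStudy(cfg)
  }
  .cache$study
}

quickSpec <- function(seed = 1)
  aseModelSpec(chains = 2, iter = 400, warmup = 300, seed = seed)

# NB counts around a mean matrix (genes x replicates)
nbMat <- function(mu, reps, dispersion = 0.01) {
  matrix(rnbinom(length(mu) * reps, mu = rep(mu, reps),
                 size = 1 / dispersion),
         nrow = length(mu), ncol = reps)
}

# Replicate counts for genes planted across the five inheritance modes,
# with gene-specific parental folds in random directions, on a background
# of non-DE genes that anchor the normalisation as in real transcriptomes.
# `planted` labels only the five-mode genes; `idx` locates them.
plantedInheritance <- function(nPer = 40, seed = 22, meanCount = 200,
                               reps = 3, dispersion = 0.01,
                               nNull = 5 * nPer) {
  set.seed(seed)
  modes <- c("MP", "HP", "LP", "AHP", "BLP")
  planted <- rep(modes, each = nPer)
  n <- length(planted) + nNull
  base <- exp(rnorm(n, log(meanCount), 0.4))
  l2 <- c(runif(length(planted), 1.5, 2.5) *
            sample(c(-1, 1), length(planted), replace = TRUE),
          rnorm(nNull, 0, 0.1))
  p1 <- base * 2^(l2 / 2)
  p2 <- base * 2^(-l2 / 2)
  mid <- (p1 + p2) / 2
  hi <- pmax(p1, p2)
  lo <- pmin(p1, p2)
  lbl <- c(planted, rep("MP", nNull))
  f1 <- ifelse(lbl == "MP", mid,
        ifelse(lbl == "HP", hi,
        ifelse(lbl == "LP", lo,
        ifelse(lbl == "AHP", mid + 2 * (hi - mid),
               pmax(1, mid - 2 * (hi - mid))))))
  m1 <- nbMat(p1, reps, dispersion)
  m2 <- nbMat(p2, reps, dispersion)
  mF <- nbMat(f1, reps, dispersion)
  rownames(m1) <- rownames(m2) <- rownames(mF) <- sprintf("g%04d", 1:n)
  list(m1 = m1, m2 = m2, mF = mF, planted = planted,
       idx = seq_along(planted))
}
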