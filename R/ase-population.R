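## Population-level allele-specific expression: a Bayesian binomial mixed
## model per SNP, logit(p_gt) = beta0 + alpha_g + gamma_t, with genotype and
## planting-density random effects, tested against the dataset-median null.

#' Sampler and prior settings for the ASE binomial mixed model
#'
#' Weakly-informative defaults: Normal(0, 2.5^2) on the logit-scale
#' intercept, HalfNormal(1) on both random-effect SDs, 4 chains of 1000
#' post-warmup draws after 500 warmup iterations of the adaptive
#' Metropolis-within-Gibbs sampler.
#'
#' @param chains,iter,warmup MCMC geometry (iter counts post-warmup draws)
#' @param priorInterceptSd prior SD of the intercept (logit scale)
#' @param priorSigmaSd HalfNormal scale of the random-effect SD priors
#' @param seed integer seed used to derive one reproducible stream per SNP
#' @param rhatMax convergence gate on the split-Rhat of the intercept
#' @return a list of class \code{ASEModelSpec}
#' @export
aseModelSpec <- function(chains = 4, iter = 1000, warmup = 500,
                         priorInterceptSd = 2.5, priorSigmaSd = 1,
                         seed = 1, rhatMax = 1.05) {
  stopifnot(chains >= 1, iter >= 10, warmup >= 0,
            priorInterceptSd > 0, priorSigmaSd > 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup),
                 priorInterceptSd = priorInterceptSd,
                 priorSigmaSd = priorSigmaSd, seed = as.integer(seed),
                 rhatMax = rhatMax),
            class = "ASEModelSpec")
}

#' Filter ASE observations
#'
#' Keeps SNPs heterozygous (observed) in at least \code{minHybrids} hybrids
#' and observations with at least \code{minTotal} total reads (both bounds
#' inclusive). The heterozygosity count is taken before the depth filter:
#' how many hybrids carry the SNP does not depend on sequencing depth.
#'
#' @param obs data.frame with snp_id, hybrid_id, density, alt_count,
#'   total_count
#' @param minHybrids minimum number of distinct heterozygous hybrids per SNP
#' @param minTotal minimum total read count per observation
#' @return the filtered data.frame (possibly empty, with a warning)
#' @export
filterASEObservations <- function(obs, minHybrids = 10, minTotal = 10) {
  stopifnot(all(c("snp_id", "hybrid_id", "alt_count", "total_count") %in%
                  names(obs)))
  if (!nrow(obs)) {
    warning("empty observation table")
    return(obs)
  }
  hetCount <- tapply(obs$hybrid_id, obs$snp_id,
                     function(h) length(unique(h)))
  keepSnp <- names(hetCount)[hetCount >= minHybrids]
  out <- obs[obs$snp_id %in% keepSnp & obs$total_count >= minTotal, ,
             drop = FALSE]
  if (!nrow(out)) warning("no observations pass the ASE filters")
  rownames(out) <- NULL
  out
}

#' Median ASE ratio of the filtered dataset (the null hypothesis)
#'
#' @param obs filtered observation table
#' @return the median of alt_count / total_count over all observations with
#'   positive totals
#' @export
computeNullRatio <- function(obs) {
  if (!nrow(obs)) stop("cannot compute the null ratio of an empty table")
  ok <- obs$total_count > 0
  if (!any(ok)) stop("all observations have zero total count")
  median(obs$alt_count[ok] / obs$total_count[ok])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values in [0, 1]; NaN/NA rejected
#' @return BH step-up adjusted p-values
#' @export
bhFDR <- function(p) {
  if (any(is.na(p))) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

.splitRhat <- function(draws) {
  # draws: iter x chains; split each chain in half
  iter <- nrow(draws)
  half <- iter %/% 2
  if (half < 2) return(NA_real_)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(iter - half + 1):iter, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu <- colMeans(sub)
  W <- mean(apply(sub, 2, var))
  B <- nn * var(mu)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

.poolReplicates <- function(obs) {
  key <- paste(obs$hybrid_id, obs$density, sep = "\r")
  alt <- tapply(obs$alt_count, key, sum)
  tot <- tapply(obs$total_count, key, sum)
  parts <- do.call(rbind, strsplit(names(alt), "\r", fixed = TRUE))
  data.frame(hybrid_id = parts[, 1], density = parts[, 2],
             alt_count = as.integer(alt), total_count = as.integer(tot),
             stringsAsFactors = FALSE)
}

#' Fit the Bayesian binomial mixed model for one SNP
#'
#' Replicates within a (hybrid, density) cell are summed (under the model
#' their reads are exchangeable Bernoulli trials), then the adaptive
#' Metropolis-within-Gibbs sampler draws from the posterior of
#' \code{logit(p_gt) = beta0 + alpha_g + gamma_t}. The SNP-level ASE ratio is
#' the inverse logit of the intercept; its posterior p-value against the
#' null ratio \code{m} is the two-sided posterior tail probability
#' \code{2 * min(Pr(ratio < m), Pr(ratio > m))}, capped at 1.
#'
#' @param obs observations of a single SNP (hybrid_id, density, alt_count,
#'   total_count)
#' @param null the null ASE ratio (see \code{\link{computeNullRatio}})
#' @param spec an \code{\link{aseModelSpec}}
#' @return one-row data.frame: posterior mean ratio, 97.5\% credible
#'   interval, posterior p, split-Rhat of the intercept and a convergence
#'   flag
#' @export
fitASEGLMM <- function(obs, null = 0.5, spec = aseModelSpec()) {
  pooled <- .poolReplicates(obs[obs$total_count > 0, , drop = FALSE])
  if (!nrow(pooled)) stop("no observations with positive totals")
  hy <- factor(pooled$hybrid_id)
  de <- factor(pooled$density)
  init <- qlogis((sum(pooled$alt_count) + 0.5) /
                   (sum(pooled$total_count) + 1))
  fit <- .aseGlmmSampler(as.numeric(pooled$alt_count),
                         as.numeric(pooled$total_count),
                         as.integer(hy) - 1L, as.integer(de) - 1L,
                         nlevels(hy), nlevels(de),
                         spec$chains, spec$warmup, spec$iter,
                         spec$priorInterceptSd, spec$priorSigmaSd, init)
  ratio <- plogis(as.numeric(fit$beta0))
  pm <- mean(ratio)
  ci <- unname(quantile(ratio, c(0.0125, 0.9875)))
  postP <- min(1, 2 * min(mean(ratio < null), mean(ratio > null)))
  rhat <- .splitRhat(fit$beta0)
  data.frame(n_hybrids = nlevels(hy), ratio = pm,
             ci_low = ci[1], ci_high = ci[2], post_p = postP,
             rhat = rhat,
             converged = is.na(rhat) || rhat <= spec$rhatMax,
             sigma_g = mean(fit$sigma_g), sigma_t = mean(fit$sigma_t),
             stringsAsFactors = FALSE)
}

#' Population-level ASE scan
#'
#' Filters the observation table, sets the null to the dataset median ASE
#' ratio, fits the binomial mixed model per SNP (one reproducible RNG stream
#' per SNP derived from the spec seed), excludes non-converged SNPs from the
#' multiple-testing family, and controls the FDR by Benjamini-Hochberg.
#'
#' @param obs observation table (snp_id, hybrid_id, density, alt_count,
#'   total_count)
#' @param minHybrids,minTotal filters, see
#'   \code{\link{filterASEObservations}}
#' @param spec an \code{\link{aseModelSpec}}
#' @param fdrLevel significance level on the BH-adjusted posterior p
#' @param null optional fixed null ratio; default is the dataset median
#' @return list with \code{fits} (per-SNP table with fdr and significant
#'   flag), \code{null} and \code{nNonConverged}
#' @export
fitASEPopulation <- function(obs, minHybrids = 10, minTotal = 10,
                             spec = aseModelSpec(), fdrLevel = 0.05,
                             null = NULL) {
  filt <- filterASEObservations(obs, minHybrids, minTotal)
  if (!nrow(filt))
    return(list(fits = data.frame(), null = NA_real_, nNonConverged = 0L))
  m <- if (is.null(null)) computeNullRatio(filt) else null
  snps <- unique(filt$snp_id)
  byS <- split(filt, filt$snp_id)[snps]
  fits <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    set.seed(as.integer((as.double(spec$seed) + i * 7919) %% 2147483647))
    fits[[i]] <- fitASEGLMM(byS[[i]], null = m, spec = spec)
  }
  fits <- do.call(rbind, fits)
  fits <- cbind(data.frame(snp_id = snps, stringsAsFactors = FALSE), fits)
  fits$fdr <- NA_real_
  conv <- fits$converged
  if (any(conv)) fits$fdr[conv] <- bhFDR(fits$post_p[conv])
  fits$significant <- !is.na(fits$fdr) & fits$fdr < fdrLevel
  rownames(fits) <- NULL
  list(fits = fits, null = m, nNonConverged = sum(!conv))
}

#' Summarize a population ASE scan
#'
#' Reports significant-SNP and significant-gene counts and percentages and,
#' when allele frequencies are supplied, the MAF-stratified proportions of
#' significant SNPs with their fold ratio and the correlation between ASE
#' ratio and alternative-allele frequency computed separately for the
#' significant and non-significant sets.
#'
#' @param fits per-SNP fit table with snp_id and significant columns
#' @param snpGene optional data.frame (snp_id, gene_id) mapping SNPs to genes
#' @param altFreq optional named numeric vector of alternative-allele
#'   frequencies per SNP
#' @param mafCutoff minor-allele-frequency boundary between rare and common
#'   variants
#' @return list of counts, percentages, fold ratio and correlations
#' @export
summarizeASE <- function(fits, snpGene = NULL, altFreq = NULL,
                         mafCutoff = 0.1) {
  nSnps <- nrow(fits)
  nSig <- sum(fits$significant)
  out <- list(nSnps = nSnps, nSignificant = nSig,
              pctSignificant = if (nSnps) 100 * nSig / nSnps else 0)
  if (!is.null(snpGene)) {
    gene <- snpGene$gene_id[match(fits$snp_id, snpGene$snp_id)]
    covered <- unique(gene[!is.na(gene)])
    sigGenes <- unique(gene[fits$significant & !is.na(gene)])
    out$nGenesCovered <- length(covered)
    out$nGenesSignificant <- length(sigGenes)
    out$pctGenesSignificant <- if (length(covered))
      100 * length(sigGenes) / length(covered) else 0
  }
  if (!is.null(altFreq)) {
    af <- altFreq[fits$snp_id]
    maf <- pmin(af, 1 - af)
    low <- maf < mafCutoff
    pLow <- 100 * mean(fits$significant[low])
    pHigh <- 100 * mean(fits$significant[!low])
    out$pctSignificantLowMAF <- pLow
    out$pctSignificantHighMAF <- pHigh
    out$mafFoldRatio <- pLow / pHigh
    sig <- fits$significant
    safeCor <- function(x, y)
      if (length(x) >= 3 && sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_
    out$corSig <- safeCor(fits$ratio[sig], af[sig])
    out$corNonSig <- safeCor(fits$ratio[!sig], af[!sig])
  }
  out
}
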