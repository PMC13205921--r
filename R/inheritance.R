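## Differential expression, SPE/CE calling, the dominance/additivity ratio
## and BIC-based inheritance-mode classification.

.checkFullRank <- function(mm, factors) {
  if (qr(mm)$rank < ncol(mm))
    stop("design matrix is rank deficient; confounded factors among: ",
         paste(factors, collapse = ", "))
}

#' Population-level multifactor differential expression
#'
#' Fits, per gene, a negative-binomial GLM with log link and library-size
#' offsets for the design
#' \code{~ stage + class + density + class:density}, where class contrasts
#' hybrids against inbred parents, using DESeq2 (Wald tests per coefficient,
#' BH-adjusted). A gene is differentially expressed for a factor when its
#' adjusted p-value is below \code{fdrLevel} and |log2 fold change| exceeds
#' \code{lfcThreshold}.
#'
#' @param se SummarizedExperiment with a \code{counts} assay and colData
#'   columns role, stage, density
#' @param fdrLevel,lfcThreshold DE thresholds (defaults 0.01 and 1)
#' @return named list of per-factor data.frames (gene_id, log2fc, p, fdr,
#'   de) for the hybrid/inbred, density and interaction terms plus each
#'   stage contrast
#' @export
fitMultifactorDE <- function(se, fdrLevel = 0.01, lfcThreshold = 1) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  cls <- factor(ifelse(cd$role == "hybrid", "hybrid", "inbred"),
                levels = c("inbred", "hybrid"))
  df <- data.frame(stage = factor(cd$stage),
                   class = cls,
                   density = factor(cd$density, levels =
                                      rev(sort(unique(cd$density)))))
  mm <- model.matrix(~ stage + class + density + class:density, df)
  .checkFullRank(mm, c("stage", "class", "density"))
  cnt <- SummarizedExperiment::assay(se, "counts")
  mode(cnt) <- "integer"
  dds <- DESeq2::DESeqDataSetFromMatrix(cnt, S4Vectors::DataFrame(df),
                                        ~ stage + class + density +
                                          class:density)
  dds <- DESeq2::DESeq(dds, quiet = TRUE, fitType = "local",
                       minReplicatesForReplace = Inf)
  grab <- function(name) {
    r <- DESeq2::results(dds, name = name)
    data.frame(gene_id = rownames(r), log2fc = r$log2FoldChange,
               p = r$pvalue, fdr = r$padj,
               de = !is.na(r$padj) & r$padj < fdrLevel &
                 abs(r$log2FoldChange) > lfcThreshold,
               stringsAsFactors = FALSE)
  }
  rn <- DESeq2::resultsNames(dds)
  out <- list()
  out$hybrid_vs_inbred <- grab(grep("^class_", rn, value = TRUE)[1])
  out$density <- grab(grep("^density_", rn, value = TRUE)[1])
  inter <- grep(":|\\.", setdiff(rn, "Intercept"), value = TRUE)
  inter <- setdiff(inter, grep("^(stage|class|density)_", rn, value = TRUE))
  if (length(inter)) out$interaction <- grab(inter[1])
  for (s in grep("^stage_", rn, value = TRUE))
    out[[s]] <- grab(s)
  out
}

#' Pairwise parental differential expression with fold-change tiers
#'
#' DESeq2 Wald test of female vs male parent (log2 fold changes oriented
#' female over male). Genes with FDR below \code{fdrLevel} are DE and tiered
#' by |log2FC|: at least 1 is two-fold (DE_2), at least 2 four-fold (DE_4),
#' at least 3 eight-fold (DE_8); a gene carries the highest tier reached.
#'
#' @param se SummarizedExperiment with counts and colData genotype_id,
#'   stage, density
#' @param femaleId,maleId parental genotype ids
#' @param fdrLevel parental DE threshold on the FDR (no fold-change gate)
#' @return data.frame gene_id, log2fc, p, fdr, de, tier
#' @export
callParentalDE <- function(se, femaleId, maleId, fdrLevel = 0.01) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  sel <- cd$genotype_id %in% c(femaleId, maleId)
  if (!any(cd$genotype_id == femaleId) || !any(cd$genotype_id == maleId))
    stop("both parents must be present in the expression data")
  cd <- cd[sel, , drop = FALSE]
  cnt <- SummarizedExperiment::assay(se, "counts")[, sel, drop = FALSE]
  mode(cnt) <- "integer"
  df <- data.frame(genotype = factor(cd$genotype_id,
                                     levels = c(maleId, femaleId)))
  form <- ~ genotype
  if (length(unique(cd$stage)) > 1) {
    df$stage <- factor(cd$stage)
    form <- update(form, ~ stage + .)
  }
  if (length(unique(cd$density)) > 1) {
    df$density <- factor(cd$density)
    form <- update(form, ~ density + .)
  }
  dds <- DESeq2::DESeqDataSetFromMatrix(cnt, S4Vectors::DataFrame(df), form)
  dds <- DESeq2::DESeq(dds, quiet = TRUE, fitType = "local",
                       minReplicatesForReplace = Inf)
  r <- DESeq2::results(dds, contrast = c("genotype", femaleId, maleId))
  de <- !is.na(r$padj) & r$padj < fdrLevel
  al <- abs(r$log2FoldChange)
  tier <- rep("none", nrow(r))
  tier[de & al >= 1] <- "DE_2"
  tier[de & al >= 2] <- "DE_4"
  tier[de & al >= 3] <- "DE_8"
  data.frame(gene_id = rownames(r), log2fc = r$log2FoldChange,
             p = r$pvalue, fdr = r$padj, de = de, tier = tier,
             stringsAsFactors = FALSE)
}

#' Replicate-mean FPKM triples for a trio
#'
#' @param se SummarizedExperiment with an \code{fpkm} assay
#' @param hybridId,femaleId,maleId genotype ids of the trio
#' @param by optional metadata columns (e.g. c("stage", "density")) to
#'   average within; default averages over all samples of each genotype
#' @return data.frame gene_id (and the \code{by} columns), fpkm_p1 (female),
#'   fpkm_p2 (male), fpkm_f1
#' @export
expressionTriples <- function(se, hybridId, femaleId, maleId, by = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  fp <- SummarizedExperiment::assay(se, "fpkm")
  grpMean <- function(id) {
    sel <- cd$genotype_id == id
    if (!any(sel)) stop("genotype absent from expression data: ", id)
    if (is.null(by)) {
      data.frame(gene_id = rownames(fp),
                 value = rowMeans(fp[, sel, drop = FALSE]),
                 stringsAsFactors = FALSE)
    } else {
      key <- interaction(cd[sel, by, drop = FALSE], drop = TRUE)
      vals <- sapply(levels(key), function(l)
        rowMeans(fp[, sel, drop = FALSE][, key == l, drop = FALSE]))
      lv <- do.call(rbind, strsplit(levels(key), ".", fixed = TRUE))
      out <- data.frame(gene_id = rep(rownames(fp), ncol(vals)),
                        value = as.numeric(vals), stringsAsFactors = FALSE)
      for (j in seq_along(by))
        out[[by[j]]] <- rep(lv[, j], each = nrow(fp))
      out
    }
  }
  f <- grpMean(femaleId); m <- grpMean(maleId); h <- grpMean(hybridId)
  keyCols <- c("gene_id", by)
  out <- f
  names(out)[names(out) == "value"] <- "fpkm_p1"
  out$fpkm_p2 <- m$value[match(do.call(paste, out[keyCols]),
                               do.call(paste, m[keyCols]))]
  out$fpkm_f1 <- h$value[match(do.call(paste, out[keyCols]),
                               do.call(paste, h[keyCols]))]
  out
}

#' Call single-parent expression (SPE) and hybrid complementary expression
#'
#' A gene is SPE when one parent is silent (FPKM below
#' \code{silentThreshold}) and the other expressed (FPKM above
#' \code{exprThreshold}); an SPE gene is complementarily expressed (CE) when
#' the hybrid also exceeds \code{exprThreshold}. Parental expression classes
#' are reported alongside: expressed (both parents above the threshold),
#' silent (both below the silent threshold), genotype-dependent otherwise.
#'
#' @param triples output of \code{\link{expressionTriples}}
#' @param exprThreshold,silentThreshold FPKM cutoffs (1 and 0.1)
#' @return the input with spe, spe_silent_parent, ce and parent_class
#' @export
callSpeCe <- function(triples, exprThreshold = 1, silentThreshold = 0.1) {
  p1 <- triples$fpkm_p1; p2 <- triples$fpkm_p2; f1 <- triples$fpkm_f1
  spe1 <- p1 < silentThreshold & p2 > exprThreshold  # female silent
  spe2 <- p2 < silentThreshold & p1 > exprThreshold  # male silent
  out <- triples
  out$spe <- spe1 | spe2
  out$spe_silent_parent <- ifelse(spe1, "female", ifelse(spe2, "male",
                                                         NA_character_))
  out$ce <- out$spe & f1 > exprThreshold
  out$parent_class <- ifelse(p1 > exprThreshold & p2 > exprThreshold,
                             "expressed",
                             ifelse(p1 < silentThreshold &
                                      p2 < silentThreshold, "silent",
                                    "genotype_dependent"))
  out
}

#' Per-hybrid SPE/CE summary
#'
#' @param spece per-gene, per-hybrid table with hybrid_id, spe and ce
#'   columns (e.g. stacked \code{\link{callSpeCe}} outputs)
#' @return list with the per-hybrid counts and the means of SPE and CE
#'   counts plus the CE percentage of SPE genes
#' @export
summarizeSpeCe <- function(spece) {
  spe <- tapply(spece$spe, spece$hybrid_id, sum)
  ce <- tapply(spece$ce, spece$hybrid_id, sum)
  perHybrid <- data.frame(hybrid_id = names(spe),
                          n_spe = as.integer(spe), n_ce = as.integer(ce),
                          stringsAsFactors = FALSE)
  list(perHybrid = perHybrid, meanSpe = mean(spe), meanCe = mean(ce),
       pctCe = 100 * mean(ce) / mean(spe))
}

#' Dominance/additivity ratio of hybrid expression
#'
#' \code{D/A = (F1 - mean(P1, P2)) / (max(P1, P2) - mean(P1, P2))}: 0 is
#' mid-parent additivity, +1/-1 high/low-parent dominance, beyond that
#' overdominance. Undefined (NA) when the parents are equal. Invariant to
#' relabelling P1 and P2.
#'
#' @param p1,p2,f1 replicate-mean expression of the two parents and the
#'   hybrid (vectors recycle)
#' @return numeric D/A values, NA where p1 == p2
#' @export
computeDA <- function(p1, p2, f1) {
  mid <- (p1 + p2) / 2
  hi <- pmax(p1, p2)
  ifelse(hi == mid, NA_real_, (f1 - mid) / (hi - mid))
}

.nbLL <- function(y, mu, phi) {
  sum(dnbinom(y, mu = pmax(mu, 1e-8), size = 1 / phi, log = TRUE))
}

.inheritPhi <- function(y1, y2, yF, s1, s2, sF) {
  mFree <- pmax(c(sum(y1) / sum(s1), sum(y2) / sum(s2),
                  sum(yF) / sum(sF)), 1e-6)
  y <- c(y1, y2, yF)
  mu <- c(s1 * mFree[1], s2 * mFree[2], sF * mFree[3])
  nObs <- length(y)
  phi <- exp(optimize(function(lp) -.nbLL(y, mu, exp(lp)),
                      c(log(1e-4), log(10)))$minimum)
  # first-order df correction: three means are estimated from nObs counts,
  # so the plug-in ML dispersion is biased low by about (nObs - 3)/nObs
  min(10, phi * nObs / max(1, nObs - 3))
}

.inheritOne <- function(y1, y2, yF, s1, s2, sF, phi, daBands, bicMargin) {
  mFree <- c(sum(y1) / sum(s1), sum(y2) / sum(s2), sum(yF) / sum(sF))
  mFree <- pmax(mFree, 1e-6)
  y <- c(y1, y2, yF); s <- c(s1, s2, sF)
  nObs <- length(y)
  muOf <- function(m) c(s1 * m[1], s2 * m[2], sF * m[3])
  llFree <- .nbLL(y, muOf(mFree), phi)
  # additive: F1 mean constrained to the mid-parent value
  oadd <- optim(log(mFree[1:2]), function(lm) {
    m <- exp(lm)
    -.nbLL(y, muOf(c(m[1], m[2], (m[1] + m[2]) / 2)), phi)
  }, method = "Nelder-Mead")
  llAdd <- -oadd$value
  # dominant: F1 mean tied to one parent
  m1s <- (sum(y1) + sum(yF)) / (sum(s1) + sum(sF))
  llDomF <- .nbLL(y, muOf(c(m1s, mFree[2], m1s)), phi)
  m2s <- (sum(y2) + sum(yF)) / (sum(s2) + sum(sF))
  llDomM <- .nbLL(y, muOf(c(mFree[1], m2s, m2s)), phi)
  bic <- c(additive = -2 * llAdd + 2 * log(nObs),
           dominantF = -2 * llDomF + 2 * log(nObs),
           dominantM = -2 * llDomM + 2 * log(nObs),
           free = -2 * llFree + 3 * log(nObs))
  da <- computeDA(mFree[1], mFree[2], mFree[3])
  # BIC first separates additive from the non-additive family (a gap inside
  # the margin falls back to MP, conservatively). Within the family the
  # best model decides: a dominant winner is a point hypothesis and maps
  # straight to HP/LP, a free winner is refined by the D/A bands.
  cand <- bic[c("dominantF", "dominantM", "free")]
  bestNonAdd <- min(cand)
  tie <- abs(bic[["additive"]] - bestNonAdd) < bicMargin
  hiParent <- if (mFree[1] >= mFree[2]) "F" else "M"
  mode <- if (bic[["additive"]] - bestNonAdd < bicMargin || is.na(da)) "MP"
  else {
    win <- names(cand)[which.min(cand)]
    # parsimony margin within the family too: the free model must beat the
    # best dominant point hypothesis decisively
    bestDom <- min(cand[c("dominantF", "dominantM")])
    if (win == "free" && bestDom - cand[["free"]] < bicMargin)
      win <- names(cand)[which.min(cand[c("dominantF", "dominantM")])]
    if (win == "dominantF") { if (hiParent == "F") "HP" else "LP" }
    else if (win == "dominantM") { if (hiParent == "M") "HP" else "LP" }
    else if (da > daBands[3]) "AHP"
    else if (da < -daBands[3]) "BLP"
    else if (abs(da) >= daBands[2]) { if (da > 0) "HP" else "LP" }
    else if (abs(da) > daBands[1]) { if (da > 0) "PD_H" else "PD_L" }
    else "MP"
  }
  list(mode = mode, da = da, bic = bic, tie = tie, phi = phi)
}

#' Classify gene expression inheritance by BIC model comparison
#'
#' For each (parental DE) gene, replicate counts of the two parents and the
#' hybrid in one stage x density condition are fit, after median-of-ratios
#' normalisation, to candidate negative-binomial models of the hybrid mean:
#' constrained to the mid-parent value (additive), to either parent
#' (dominant), or free (overdominant / partial dominance), with a gene-wise
#' maximum-likelihood dispersion floored at 1e-4 and shared across models.
#' BIC separates additive from the non-additive model family; a non-additive
#' winner is refined by D/A bands (|D/A| <= 0.25 mid-parent, < 0.75 partial
#' dominance, <= 1.25 dominance, beyond overdominance). An
#' additive/non-additive BIC gap below \code{bicMargin} falls back to MP,
#' conservatively, and is flagged.
#'
#' @param countsP1,countsP2,countsF1 gene x replicate count matrices (same
#'   genes, one condition) for female parent, male parent and hybrid
#' @param sizeFactors optional length-(total replicates) size factors;
#'   median-of-ratios estimates by default
#' @param daBands D/A band edges (mid-parent, partial, dominant)
#' @param bicMargin minimum BIC gap for a non-MP call
#' @return data.frame gene_id, mode (MP, HP, LP, PD_H, PD_L, AHP, BLP), da,
#'   per-model BICs, dispersion and tie flag
#' @importFrom stats dnbinom optimize optim model.matrix update
#' @export
classifyInheritance <- function(countsP1, countsP2, countsF1,
                                sizeFactors = NULL,
                                daBands = c(0.25, 0.75, 1.25),
                                bicMargin = 2) {
  stopifnot(nrow(countsP1) == nrow(countsP2),
            nrow(countsP1) == nrow(countsF1))
  Y <- cbind(countsP1, countsP2, countsF1)
  if (is.null(sizeFactors))
    sizeFactors <- DESeq2::estimateSizeFactorsForMatrix(Y)
  i1 <- seq_len(ncol(countsP1))
  i2 <- ncol(countsP1) + seq_len(ncol(countsP2))
  iF <- ncol(countsP1) + ncol(countsP2) + seq_len(ncol(countsF1))
  genes <- rownames(countsP1)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(countsP1)))
  # gene-wise ML dispersions, then empirical-Bayes shrinkage toward the
  # median log-dispersion: at a handful of replicates the raw MLE is too
  # unstable for calibrated likelihood-ratio comparisons
  rawPhi <- vapply(seq_len(nrow(Y)), function(g)
    .inheritPhi(Y[g, i1], Y[g, i2], Y[g, iF],
                sizeFactors[i1], sizeFactors[i2], sizeFactors[iF]),
    numeric(1))
  nObs <- ncol(Y)
  mleVar <- 2 / max(1, nObs - 3)     # approximate var of log phi-hat
  priorVar <- 0.1
  w <- priorVar / (priorVar + mleVar)
  phiUse <- pmax(1e-4, exp(w * log(rawPhi) +
                             (1 - w) * median(log(rawPhi))))
  res <- lapply(seq_len(nrow(Y)), function(g)
    .inheritOne(Y[g, i1], Y[g, i2], Y[g, iF],
                sizeFactors[i1], sizeFactors[i2], sizeFactors[iF],
                phiUse[g], daBands, bicMargin))
  data.frame(gene_id = genes,
             mode = vapply(res, `[[`, character(1), "mode"),
             da = vapply(res, `[[`, numeric(1), "da"),
             bic_additive = vapply(res, function(r) r$bic[["additive"]],
                                   numeric(1)),
             bic_dominant_female = vapply(res, function(r)
               r$bic[["dominantF"]], numeric(1)),
             bic_dominant_male = vapply(res, function(r)
               r$bic[["dominantM"]], numeric(1)),
             bic_free = vapply(res, function(r) r$bic[["free"]],
                               numeric(1)),
             dispersion = vapply(res, `[[`, numeric(1), "phi"),
             bic_tie = vapply(res, `[[`, logical(1), "tie"),
             stringsAsFactors = FALSE)
}
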