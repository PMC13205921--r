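## Per-hybrid haplotype allele-specific expression: gene-level maternal and
## paternal counts from phased SNPs, exact binomial imbalance tests,
## cis/trans regulatory-pattern assignment by BIC, ASE consistency across
## planting densities and the allele-specific density response.

#' Aggregate phased per-SNP allele counts to gene-level haplotype counts
#'
#' Alternative-allele counts at phased SNPs are oriented by the phase
#' (\code{0|1}: the alternative allele is paternal; \code{1|0}: maternal) and
#' summed over the SNPs of a gene. Counting is per-SNP summation: the input
#' is expected to be free of reads double-counted across overlapping SNPs,
#' as the synthetic generator guarantees. SNPs mapping to more than one gene
#' are assigned to none (with a warning); genes without phased SNPs are
#' absent from the output.
#'
#' @param counts allele-count table (snp_id, hybrid_id, density, replicate,
#'   alt_count, total_count)
#' @param phased a phased \linkS4class{TrioGenotypes}
#' @param snpGene data.frame (snp_id, gene_id)
#' @return data.frame with gene_id, hybrid_id, density, replicate,
#'   maternal_count, paternal_count
#' @export
aggregateHaplotypeCounts <- function(counts, phased, snpGene) {
  rec <- as.data.frame(trioRecords(phased))
  kept <- rec[!is.na(rec$filter_reason) & rec$filter_reason == "kept",
              c("snp_id", "hybrid_id", "phased_gt")]
  dupSnp <- unique(snpGene$snp_id[duplicated(snpGene$snp_id)])
  if (length(dupSnp)) {
    warning(length(dupSnp), " SNP(s) mapped to multiple genes were excluded")
    snpGene <- snpGene[!snpGene$snp_id %in% dupSnp, , drop = FALSE]
  }
  snpGene <- snpGene[!is.na(snpGene$gene_id), , drop = FALSE]
  x <- merge(counts, kept, by = c("snp_id", "hybrid_id"))
  x$gene_id <- snpGene$gene_id[match(x$snp_id, snpGene$snp_id)]
  x <- x[!is.na(x$gene_id), , drop = FALSE]
  if (!nrow(x))
    return(data.frame(gene_id = character(), hybrid_id = character(),
                      density = character(), replicate = integer(),
                      maternal_count = integer(), paternal_count = integer(),
                      stringsAsFactors = FALSE))
  # phase 0|1: maternal (female) haplotype carries the reference allele
  mat <- ifelse(x$phased_gt == "0|1", x$total_count - x$alt_count,
                x$alt_count)
  pat <- x$total_count - mat
  key <- paste(x$gene_id, x$hybrid_id, x$density, x$replicate, sep = "\r")
  ms <- tapply(mat, key, sum)
  ps <- tapply(pat, key, sum)
  parts <- do.call(rbind, strsplit(names(ms), "\r", fixed = TRUE))
  out <- data.frame(gene_id = parts[, 1], hybrid_id = parts[, 2],
                    density = parts[, 3], replicate = as.integer(parts[, 4]),
                    maternal_count = as.integer(ms),
                    paternal_count = as.integer(ps),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$hybrid_id, out$density, out$replicate), ]
  rownames(out) <- NULL
  out
}

.poolHaplotype <- function(hap, by = c("gene_id", "hybrid_id", "density")) {
  key <- do.call(paste, c(hap[by], sep = "\r"))
  ms <- tapply(hap$maternal_count, key, sum)
  ps <- tapply(hap$paternal_count, key, sum)
  parts <- do.call(rbind, strsplit(names(ms), "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- by
  out$maternal_count <- as.integer(ms)
  out$paternal_count <- as.integer(ps)
  out
}

#' Test allelic imbalance of gene-level haplotype expression
#'
#' Replicates are pooled per gene x hybrid x density, imbalance is tested
#' with the exact two-sided binomial test against 0.5, and the FDR is
#' controlled by Benjamini-Hochberg within each hybrid x density family.
#' Genes with fewer than \code{minTotal} haplotype-assigned reads are
#' excluded; zero-total genes are skipped.
#'
#' @param hap haplotype count table from
#'   \code{\link{aggregateHaplotypeCounts}}
#' @param minTotal minimum pooled maternal + paternal reads per gene
#' @param fdrLevel ASE significance level on the adjusted p-value
#' @return data.frame with pooled counts, \code{ase_log2_ratio}
#'   (log2 maternal/paternal, 0.5 pseudocount when a zero occurs),
#'   binomial p, fdr and the ase flag
#' @importFrom stats binom.test p.adjust var
#' @export
testAllelicImbalance <- function(hap, minTotal = 20, fdrLevel = 0.05) {
  pooled <- .poolHaplotype(hap)
  tot <- pooled$maternal_count + pooled$paternal_count
  pooled <- pooled[tot >= pmax(1, minTotal), , drop = FALSE]
  if (!nrow(pooled)) return(pooled)
  m <- pooled$maternal_count; p <- pooled$paternal_count
  zero <- m == 0 | p == 0
  pooled$ase_log2_ratio <- ifelse(zero, log2((m + 0.5) / (p + 0.5)),
                                  log2(m / p))
  n <- m + p
  # exact two-sided binomial p (sum of outcome probabilities <= P(observed))
  pooled$p_value <- vapply(seq_len(nrow(pooled)), function(i)
    binom.test(m[i], n[i], 0.5)$p.value, numeric(1))
  fam <- paste(pooled$hybrid_id, pooled$density)
  pooled$fdr <- ave(pooled$p_value, fam, FUN = function(z)
    p.adjust(z, method = "BH"))
  pooled$ase <- pooled$fdr < fdrLevel
  rownames(pooled) <- NULL
  pooled
}

.binomLL <- function(k, n, p) {
  p <- min(max(p, 1e-12), 1 - 1e-12)
  k * log(p) + (n - k) * log1p(-p)
}

#' Classify the regulatory pattern behind hybrid ASE and parental DE
#'
#' For each parental DE gene the pooled hybrid haplotype counts are fit to
#' three binomial models of the maternal read fraction: trans-only (equal
#' allelic expression, log2 ratio 0), cis-only (allelic ratio equal to the
#' parental log2 fold change) and cis + trans (free ratio). The model with
#' the lowest BIC wins; a BIC gap below \code{bicMargin} yields
#' \code{ambiguous}. A winning free model is split by the sign and magnitude
#' of its ratio against the parental fold change: same sign and smaller
#' magnitude is cis + trans (same direction), same sign and larger magnitude
#' cis + trans (opposite direction), and an allelic ratio opposite in sign
#' to the parental DE is \code{unexpected}.
#'
#' @param aseTab pooled per-gene table (gene_id, hybrid_id,
#'   maternal_count, paternal_count), e.g. from
#'   \code{\link{testAllelicImbalance}} pooled over densities or per density
#' @param parentalDE data.frame (gene_id, log2fc, de) with log2fc oriented
#'   female/maternal over male/paternal
#' @param bicMargin minimum BIC gap for an unambiguous call
#' @return the input with \code{pattern} and per-model BIC columns
#' @export
classifyRegulatoryPattern <- function(aseTab, parentalDE, bicMargin = 2) {
  idx <- match(aseTab$gene_id, parentalDE$gene_id)
  L <- parentalDE$log2fc[idx]
  de <- parentalDE$de[idx]
  n <- aseTab$maternal_count + aseTab$paternal_count
  k <- aseTab$maternal_count
  pattern <- rep("ambiguous", nrow(aseTab))
  bicT <- bicC <- bicF <- rep(NA_real_, nrow(aseTab))
  for (i in seq_len(nrow(aseTab))) {
    if (is.na(de[i]) || !de[i] || is.na(L[i]) || n[i] == 0) next
    pCis <- 2^L[i] / (1 + 2^L[i])
    pHat <- (k[i] + 0.5) / (n[i] + 1)
    llT <- .binomLL(k[i], n[i], 0.5)
    llC <- .binomLL(k[i], n[i], pCis)
    llF <- .binomLL(k[i], n[i], pHat)
    bic <- c(trans = -2 * llT, cis = -2 * llC,
             free = -2 * llF + log(n[i]))
    bicT[i] <- bic["trans"]; bicC[i] <- bic["cis"]; bicF[i] <- bic["free"]
    o <- order(bic)
    if (bic[o[2]] - bic[o[1]] < bicMargin) {
      pattern[i] <- "ambiguous"
      next
    }
    win <- names(bic)[o[1]]
    if (win == "trans") pattern[i] <- "trans_only"
    else if (win == "cis") pattern[i] <- "cis_only"
    else {
      r <- log2(pHat / (1 - pHat))
      if (sign(r) != sign(L[i])) pattern[i] <- "unexpected"
      else if (abs(r) < abs(L[i])) pattern[i] <- "cis_plus_trans_same"
      else pattern[i] <- "cis_plus_trans_opposite"
    }
  }
  pattern[is.na(de) | (!is.na(de) & !de)] <- "ambiguous"
  out <- aseTab
  out$parental_log2fc <- L
  out$pattern <- pattern
  out$bic_trans <- bicT; out$bic_cis <- bicC; out$bic_free <- bicF
  out
}

#' Classify ASE consistency across planting densities
#'
#' @param aseRes output of \code{\link{testAllelicImbalance}} containing both
#'   densities
#' @param densities the two density labels (first treated as HPD)
#' @return per gene x hybrid: density_consistency in consistent,
#'   direction_shift, HPD_only, LPD_only, none; genes tested in a single
#'   density are classified from it alone and flagged
#' @export
classifyDensityConsistency <- function(aseRes, densities = c("HPD", "LPD")) {
  key <- paste(aseRes$gene_id, aseRes$hybrid_id, sep = "\r")
  out <- lapply(split(aseRes, key), function(d) {
    hp <- d[d$density == densities[1], , drop = FALSE]
    lp <- d[d$density == densities[2], , drop = FALSE]
    single <- nrow(hp) == 0 || nrow(lp) == 0
    aseH <- nrow(hp) == 1 && hp$ase
    aseL <- nrow(lp) == 1 && lp$ase
    dirH <- if (nrow(hp)) sign(hp$ase_log2_ratio) else NA
    dirL <- if (nrow(lp)) sign(lp$ase_log2_ratio) else NA
    cls <- if (aseH && aseL) {
      if (!is.na(dirH) && !is.na(dirL) && dirH == dirL) "consistent"
      else "direction_shift"
    } else if (aseH) paste0(densities[1], "_only")
    else if (aseL) paste0(densities[2], "_only")
    else "none"
    data.frame(gene_id = d$gene_id[1], hybrid_id = d$hybrid_id[1],
               density_consistency = cls, single_density = single,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.nbDensityDE <- function(mat, density, densities = c("HPD", "LPD")) {
  cd <- S4Vectors::DataFrame(density = factor(density, levels =
                                                rev(densities)))
  mode(mat) <- "integer"
  dds <- DESeq2::DESeqDataSetFromMatrix(mat, colData = cd,
                                        design = ~ density)
  dds <- DESeq2::DESeq(dds, quiet = TRUE, fitType = "mean",
                       minReplicatesForReplace = Inf)
  res <- DESeq2::results(dds, contrast = c("density", densities[1],
                                           densities[2]),
                         independentFiltering = FALSE,
                         cooksCutoff = FALSE)
  data.frame(gene_id = rownames(res), log2fc = res$log2FoldChange,
             padj = res$padj, stringsAsFactors = FALSE)
}

#' Classify the allele-specific response to planting density
#'
#' For one hybrid, each parental allele's gene-level counts are tested for
#' differential expression between the two densities with a
#' negative-binomial GLM (Wald test); an allele is responsive when its
#' |log2 fold change| exceeds \code{lfcThreshold} at FDR below
#' \code{fdrLevel}. Genes are then assigned: both alleles responsive with
#' equal signs is \code{same_direction}, with opposite signs
#' \code{opposite_direction}, a single responsive allele is
#' \code{female_specific} or \code{male_specific}, otherwise \code{none}.
#'
#' @param hap haplotype counts of one hybrid (replicate level)
#' @param fdrLevel response FDR threshold (0.01 by default; the looser 0.05
#'   variant can be requested)
#' @param lfcThreshold absolute log2 fold-change threshold
#' @param densities the two density labels (fold changes reported first vs
#'   second)
#' @return per-gene data.frame with allele log2 fold changes, FDRs and
#'   \code{allelic_response}; with fewer than two replicates per condition
#'   all genes are \code{none} and flagged
#' @export
classifyAllelicResponse <- function(hap, fdrLevel = 0.01, lfcThreshold = 1,
                                    densities = c("HPD", "LPD")) {
  stopifnot(length(unique(hap$hybrid_id)) == 1)
  smp <- unique(hap[, c("density", "replicate")])
  enough <- all(vapply(densities, function(d)
    sum(smp$density == d) >= 2, logical(1)))
  genes <- sort(unique(hap$gene_id))
  if (!enough) {
    return(data.frame(gene_id = genes, hybrid_id = hap$hybrid_id[1],
                      maternal_log2fc = NA_real_, paternal_log2fc = NA_real_,
                      maternal_fdr = NA_real_, paternal_fdr = NA_real_,
                      allelic_response = "none", insufficient_replicates = TRUE,
                      stringsAsFactors = FALSE))
  }
  smp <- smp[order(smp$density, smp$replicate), ]
  cn <- paste(smp$density, smp$replicate, sep = "_")
  build <- function(col) {
    m <- matrix(0L, length(genes), nrow(smp),
                dimnames = list(genes, cn))
    m[cbind(hap$gene_id,
            paste(hap$density, hap$replicate, sep = "_"))] <- hap[[col]]
    m
  }
  resM <- .nbDensityDE(build("maternal_count"), smp$density, densities)
  resP <- .nbDensityDE(build("paternal_count"), smp$density, densities)
  respond <- function(res)
    !is.na(res$padj) & res$padj < fdrLevel & abs(res$log2fc) > lfcThreshold
  rM <- respond(resM); rP <- respond(resP)
  cls <- rep("none", length(genes))
  both <- rM & rP
  cls[both & sign(resM$log2fc) == sign(resP$log2fc)] <- "same_direction"
  cls[both & sign(resM$log2fc) != sign(resP$log2fc)] <- "opposite_direction"
  cls[rM & !rP] <- "female_specific"
  cls[!rM & rP] <- "male_specific"
  data.frame(gene_id = genes, hybrid_id = hap$hybrid_id[1],
             maternal_log2fc = resM$log2fc, paternal_log2fc = resP$log2fc,
             maternal_fdr = resM$padj, paternal_fdr = resP$padj,
             allelic_response = cls, insufficient_replicates = FALSE,
             stringsAsFactors = FALSE)
}
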