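## Transcriptomic plasticity as Shannon entropy of a genotype's averaged
## gene expression-frequency distribution across its stage x density
## samples, and the hybrid-parent entropy reduction.

#' Gene expression frequencies of a set of samples
#'
#' Each sample's FPKM vector is normalised to sum to one (the within-sample
#' expression frequencies p_ij), and the per-gene average frequency
#' p_i = mean_j(p_ij) is taken over samples. All-zero samples are excluded
#' with a warning. Frequencies are scale invariant: rescaling any sample's
#' FPKM leaves them unchanged.
#'
#' @param fpkm genes x samples matrix of FPKM values
#' @return list with \code{perSample} (frequency matrix) and \code{mean}
#'   (the averaged frequency vector, summing to 1)
#' @export
expressionFrequencies <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (!ncol(fpkm)) stop("at least one sample is required")
  tot <- colSums(fpkm)
  if (any(tot <= 0)) {
    warning(sum(tot <= 0), " all-zero sample(s) excluded")
    fpkm <- fpkm[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
    if (!ncol(fpkm)) stop("all samples are empty")
  }
  perSample <- sweep(fpkm, 2, tot, "/")
  list(perSample = perSample, mean = rowMeans(perSample))
}

#' Shannon entropy of an expression-frequency vector, in bits
#'
#' \code{H = -sum(p_i * log2(p_i))} with 0 log 0 taken as 0. H lies in
#' [0, log2(g)] with the maximum attained exactly at the uniform
#' distribution.
#'
#' @param p frequency vector (non-negative, summing to 1)
#' @param tol tolerance on the normalisation check
#' @return entropy in bits
#' @export
shannonEntropy <- function(p, tol = 1e-6) {
  if (any(p < 0)) stop("frequencies must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("frequencies must sum to 1 (got ", format(sum(p)), ")")
  q <- p[p > 0]
  -sum(q * log2(q))
}

#' Entropy profile of one genotype
#'
#' @param se SummarizedExperiment with an \code{fpkm} assay and colData
#'   genotype_id
#' @param genotypeId the genotype whose samples are profiled
#' @param genes optional gene universe (character vector of rownames)
#' @return list with genotype_id, the averaged frequency vector \code{p},
#'   \code{entropy} (bits), \code{nSamples} and the gene universe
#' @export
entropyProfile <- function(se, genotypeId, genes = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  sel <- cd$genotype_id == genotypeId
  if (!any(sel)) stop("no samples for genotype ", genotypeId)
  fp <- SummarizedExperiment::assay(se, "fpkm")[, sel, drop = FALSE]
  if (!is.null(genes)) fp <- fp[genes, , drop = FALSE]
  fr <- expressionFrequencies(fp)
  list(genotype_id = genotypeId, p = fr$mean,
       entropy = shannonEntropy(fr$mean), nSamples = ncol(fr$perSample),
       genes = rownames(fp))
}

#' Entropy reduction of a hybrid relative to its parents
#'
#' \code{dH = mean(H_female, H_male) - H_hybrid}: positive when the hybrid's
#' transcriptome is more structured (lower entropy) than its parents'. The
#' three profiles must share one gene universe.
#'
#' @param hybrid,female,male profiles from \code{\link{entropyProfile}}
#' @return one-row data.frame with the three entropies and \code{dH}
#' @export
entropyReduction <- function(hybrid, female, male) {
  if (!identical(hybrid$genes, female$genes) ||
      !identical(hybrid$genes, male$genes))
    stop("gene universes differ; intersect the profiles and rerun")
  data.frame(hybrid_id = hybrid$genotype_id,
             H_hybrid = hybrid$entropy, H_female = female$entropy,
             H_male = male$entropy,
             dH = (female$entropy + male$entropy) / 2 - hybrid$entropy,
             stringsAsFactors = FALSE)
}

#' Entropy reduction for every trio of a study
#'
#' Applies, per trio, a common gene universe (genes whose mean FPKM over the
#' trio's samples is at least \code{minMeanFpkm}) and computes the three
#' entropy profiles and the reduction.
#'
#' @param se SummarizedExperiment with fpkm and colData genotype_id
#' @param manifest trio manifest (hybrid_id, female_id, male_id)
#' @param minMeanFpkm expression filter defining each trio's gene universe
#' @return data.frame with one row per hybrid
#' @export
trioEntropy <- function(se, manifest, minMeanFpkm = 1) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  fp <- SummarizedExperiment::assay(se, "fpkm")
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    ids <- unlist(manifest[i, c("hybrid_id", "female_id", "male_id")])
    sel <- cd$genotype_id %in% ids
    universe <- rownames(fp)[rowMeans(fp[, sel, drop = FALSE]) >=
                               minMeanFpkm]
    entropyReduction(entropyProfile(se, ids[[1]], universe),
                     entropyProfile(se, ids[[2]], universe),
                     entropyProfile(se, ids[[3]], universe))
  })
  do.call(rbind, out)
}

#' Association between entropy reduction and heterosis
#'
#' Pearson correlation (with its t-distribution two-sided p) of per-hybrid
#' entropy reduction against heterosis, per trait.
#'
#' @param entropies data.frame with hybrid_id and dH (see
#'   \code{\link{trioEntropy}})
#' @param heterosis data.frame with hybrid_id, trait and a heterosis value
#'   column
#' @param value name of the heterosis column used
#' @return data.frame per trait: n, r, r2, p
#' @export
entropyHeterosisAssociation <- function(entropies, heterosis,
                                        value = "absolute_heterosis") {
  out <- lapply(split(heterosis, heterosis$trait), function(h) {
    v <- tapply(h[[value]], h$hybrid_id, mean)
    dH <- entropies$dH[match(names(v), entropies$hybrid_id)]
    ok <- is.finite(v) & is.finite(dH)
    if (sum(ok) < 3)
      stop("association requires at least 3 hybrids with both values")
    ct <- correlateTraits(dH[ok], v[ok])
    data.frame(trait = h$trait[1], n = sum(ok), r = ct$r, r2 = ct$r2,
               p = ct$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
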