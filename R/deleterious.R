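## Deleterious-allele load: gene-level identification of high-effect
## alleles, complementary (single-parent) pairs in hybrids, transcriptional
## suppression of the deleterious allele, and GERP-based region trends.

.HIGH_EFFECTS <- c("frameshift", "stop_gained", "splice_acceptor",
                   "splice_donor", "gene_fusion", "exon_loss", "start_lost",
                   "stop_lost", "transcript_ablation")

.deleteriousGeneSets <- function(annotations, carriers, region = "CDS") {
  if (anyNA(annotations$impact)) {
    n <- sum(is.na(annotations$impact))
    message(n, " unannotated variant(s) treated as modifier impact")
    annotations$impact[is.na(annotations$impact)] <- "modifier"
  }
  del <- annotations[annotations$effect %in% .HIGH_EFFECTS &
                       (is.null(region) | annotations$region %in% region), ,
                     drop = FALSE]
  x <- merge(carriers, del[, c("variant_id", "gene_id")], by = "variant_id")
  # gene-level set semantics: several variants in one gene count once
  unique(x[, c("line_id", "gene_id")])
}

#' Per-line deleterious gene counts and per-hybrid mid-parent values
#'
#' A line's deleterious count is the number of genes on which it carries at
#' least one high-effect (frameshift, stop gained/lost, splice
#' acceptor/donor, gene fusion, exon loss, start lost, transcript ablation)
#' coding variant; duplicate variants within a gene never double-count. The
#' mid-parent value of a hybrid is the average of its two parents' counts.
#'
#' @param annotations variant table (variant_id, gene_id, effect, impact,
#'   gerp_rs, region)
#' @param carriers long table (variant_id, line_id) of carried variants
#' @param manifest trio manifest (hybrid_id, female_id, male_id)
#' @param region region label(s) counted (coding by default)
#' @return list with \code{perLine} (line_id, n_deleterious) and
#'   \code{perHybrid} (female/male counts and mid_parent)
#' @export
identifyDeleterious <- function(annotations, carriers, manifest,
                                region = "CDS") {
  sets <- .deleteriousGeneSets(annotations, carriers, region)
  cnt <- table(sets$line_id)
  perLine <- data.frame(line_id = names(cnt), n_deleterious = as.integer(cnt),
                        stringsAsFactors = FALSE)
  getN <- function(id) ifelse(id %in% names(cnt), as.integer(cnt[id]), 0L)
  perHybrid <- data.frame(
    hybrid_id = manifest$hybrid_id,
    female_n = getN(manifest$female_id), male_n = getN(manifest$male_id),
    stringsAsFactors = FALSE)
  perHybrid$mid_parent <- (perHybrid$female_n + perHybrid$male_n) / 2
  list(perLine = perLine, perHybrid = perHybrid)
}

#' Complementary deleterious pairs
#'
#' A gene forms a complementary pair in a hybrid when exactly one parental
#' allele carries one or more high-effect coding variants and the other
#' maintains a functional coding sequence; genes deleterious in both parents
#' (or neither) are excluded.
#'
#' @inheritParams identifyDeleterious
#' @return list with \code{pairs} (gene_id, hybrid_id, deleterious_parent)
#'   and \code{perHybrid} counts
#' @export
findComplementaryPairs <- function(annotations, carriers, manifest,
                                   region = "CDS") {
  sets <- .deleteriousGeneSets(annotations, carriers, region)
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    fg <- sets$gene_id[sets$line_id == manifest$female_id[i]]
    mg <- sets$gene_id[sets$line_id == manifest$male_id[i]]
    femOnly <- setdiff(fg, mg)
    malOnly <- setdiff(mg, fg)
    if (length(femOnly) + length(malOnly) == 0) next
    out[[i]] <- data.frame(
      gene_id = c(femOnly, malOnly),
      hybrid_id = manifest$hybrid_id[i],
      deleterious_parent = c(rep("female", length(femOnly)),
                             rep("male", length(malOnly))),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), hybrid_id = character(),
               deleterious_parent = character(), stringsAsFactors = FALSE)
  cnt <- table(factor(pairs$hybrid_id, levels = manifest$hybrid_id))
  list(pairs = pairs,
       perHybrid = data.frame(hybrid_id = manifest$hybrid_id,
                              n_pairs = as.integer(cnt),
                              stringsAsFactors = FALSE))
}

#' Call suppression of deleterious alleles
#'
#' A complementary pair is suppressed when the functional allele is the more
#' expressed one, the allelic imbalance exceeds the fold threshold
#' (|log2(functional/deleterious)| > \code{lfcThreshold} with the functional
#' allele on top) and the exact binomial test survives BH FDR control
#' (per-hybrid families). Pairs without haplotype reads are dropped from the
#' denominator.
#'
#' @param pairs complementary pair table (gene_id, hybrid_id,
#'   deleterious_parent)
#' @param hap haplotype counts (gene_id, hybrid_id, maternal_count,
#'   paternal_count; replicate/density rows are pooled)
#' @param fdrLevel,lfcThreshold suppression thresholds (0.05 and 1)
#' @return list with the scored \code{pairs} (counts, log2 ratio, p, fdr,
#'   suppressed) and \code{perHybrid} suppression proportions
#' @export
callSuppression <- function(pairs, hap, fdrLevel = 0.05, lfcThreshold = 1) {
  pooled <- .poolHaplotype(hap, by = c("gene_id", "hybrid_id"))
  x <- merge(pairs, pooled, by = c("gene_id", "hybrid_id"))
  zero <- x$maternal_count + x$paternal_count == 0
  if (any(zero)) {
    message(sum(zero), " zero-total pair(s) dropped from the denominator")
    x <- x[!zero, , drop = FALSE]
  }
  if (!nrow(x)) {
    x$deleterious_count <- x$functional_count <- x$log2_ratio <-
      x$p_value <- x$fdr <- numeric(0)
    x$suppressed <- logical(0)
    return(list(pairs = x,
                perHybrid = data.frame(hybrid_id = character(),
                                       n_pairs = integer(),
                                       n_suppressed = integer(),
                                       proportion = numeric(),
                                       stringsAsFactors = FALSE)))
  }
  x$deleterious_count <- ifelse(x$deleterious_parent == "female",
                                x$maternal_count, x$paternal_count)
  x$functional_count <- ifelse(x$deleterious_parent == "female",
                               x$paternal_count, x$maternal_count)
  x$log2_ratio <- log2((x$functional_count + 0.5) /
                         (x$deleterious_count + 0.5))
  n <- x$functional_count + x$deleterious_count
  x$p_value <- vapply(seq_len(nrow(x)), function(i)
    binom.test(x$functional_count[i], n[i], 0.5)$p.value, numeric(1))
  x$fdr <- ave(x$p_value, x$hybrid_id,
               FUN = function(p) p.adjust(p, method = "BH"))
  x$suppressed <- x$functional_count > x$deleterious_count &
    x$log2_ratio > lfcThreshold & x$fdr < fdrLevel
  agg <- tapply(x$suppressed, x$hybrid_id, function(s) c(length(s), sum(s)))
  perHybrid <- data.frame(
    hybrid_id = names(agg),
    n_pairs = vapply(agg, `[`, numeric(1), 1),
    n_suppressed = vapply(agg, `[`, numeric(1), 2),
    stringsAsFactors = FALSE)
  perHybrid$proportion <- perHybrid$n_suppressed / perHybrid$n_pairs
  rownames(x) <- NULL
  list(pairs = x, perHybrid = perHybrid)
}

#' Region-wise trends of complemented GERP-deleterious variants
#'
#' Counts, per hybrid, complemented variants (carried by exactly one parent)
#' with GERP RS scores above \code{rsThreshold}, split into cis-regulatory
#' (2-kb upstream) and coding regions, and correlates each region's count
#' with hybrid covariates such as release year, trait value or heterosis.
#'
#' @param annotations variant table with gerp_rs and region
#' @param carriers carrier table (variant_id, line_id)
#' @param manifest trio manifest
#' @param hybridData data.frame keyed by hybrid_id whose remaining numeric
#'   columns (e.g. release_year, GYPP, heterosis) are correlated with the
#'   counts
#' @param rsThreshold GERP deleterious cutoff (RS > 2)
#' @param regions the two region labels analysed
#' @return list with \code{counts} per hybrid per region and
#'   \code{correlations} (region, variable, r, r2, p)
#' @export
gerpRegionTrends <- function(annotations, carriers, manifest, hybridData,
                             rsThreshold = 2,
                             regions = c("cis_upstream_2kb", "CDS")) {
  if (nrow(manifest) < 3)
    stop("correlations require at least 3 hybrids")
  del <- annotations[annotations$gerp_rs > rsThreshold &
                       annotations$region %in% regions, , drop = FALSE]
  x <- merge(carriers, del[, c("variant_id", "region")], by = "variant_id")
  counts <- data.frame(hybrid_id = manifest$hybrid_id,
                       stringsAsFactors = FALSE)
  for (rg in regions) {
    counts[[rg]] <- vapply(seq_len(nrow(manifest)), function(i) {
      vf <- x$variant_id[x$line_id == manifest$female_id[i] &
                           x$region == rg]
      vm <- x$variant_id[x$line_id == manifest$male_id[i] & x$region == rg]
      # complemented: carried by exactly one parent
      length(setdiff(vf, vm)) + length(setdiff(vm, vf))
    }, numeric(1))
  }
  vars <- setdiff(names(hybridData), "hybrid_id")
  idx <- match(counts$hybrid_id, hybridData$hybrid_id)
  cors <- list()
  for (rg in regions) for (v in vars) {
    yv <- hybridData[[v]][idx]
    ct <- counts[[rg]]
    ok <- is.finite(yv) & is.finite(ct)
    if (sum(ok) < 3) next
    r <- if (sd(ct[ok]) == 0 || sd(yv[ok]) == 0) NA_real_ else
      cor(ct[ok], yv[ok])
    if (is.na(r)) {
      warning("zero variance for ", rg, " vs ", v,
              "; correlation undefined")
      cors[[length(cors) + 1L]] <- data.frame(
        region = rg, variable = v, n = sum(ok), r = NA_real_,
        r2 = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    } else {
      ct2 <- correlateTraits(ct[ok], yv[ok])
      cors[[length(cors) + 1L]] <- data.frame(
        region = rg, variable = v, n = sum(ok), r = ct2$r, r2 = ct2$r2,
        p = ct2$p, stringsAsFactors = FALSE)
    }
  }
  list(counts = counts, correlations = do.call(rbind, cors))
}
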