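#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Simulation configuration for the synthetic trio/stage/density study design
#'
#' Holds every knob of the synthetic-data generator: the crossing design
#' (number of hybrid trios, SNPs, genes, stages, planting densities,
#' replicates), the allele-specific expression model on the logit scale
#' (per-SNP intercepts, genotype and treatment random-effect SDs), read-depth
#' and overdispersion parameters, the planted fractions of single-parent
#' expressed (SPE), deleterious and suppressed genes, the expression
#' inheritance-mode mixture, and the planted correlation between
#' transcriptomic entropy reduction and heterosis.
#'
#' @slot nHybrids number of F1 hybrids (each with its own two inbred parents)
#' @slot nSnps number of genic SNPs carried through phasing and ASE
#' @slot nGenes number of genes in the expression matrix
#' @slot stages developmental stage labels
#' @slot densities planting-density treatment labels
#' @slot nReplicates biological replicates per genotype x stage x density cell
#' @slot seed integer seed; a fixed seed gives byte-identical output
#' @slot aseMeanRatio mean ASE ratio of the alternative allele used as the
#'   centre of the per-SNP intercept distribution (default 0.4675, a mild
#'   reference bias typical of alignment-based allele counting)
#' @slot beta0Sd SD of per-SNP logit-scale intercepts around
#'   \code{qlogis(aseMeanRatio)}
#' @slot aseEffectSd SD of the per-hybrid genotype random effect (logit scale)
#' @slot densityEffectSd SD of the per-treatment random effect (logit scale)
#' @slot meanDepth mean total read count per SNP per sample
#' @slot nbDispersion negative-binomial dispersion of read totals
#'   (variance = mu + dispersion * mu^2)
#' @slot parentHetRate,conflictRate,missingRate rates of heterozygous-parent,
#'   Mendelian-conflict and missing-genotype trio records
#' @slot fracSpe fraction of genes planted as single-parent expressed
#' @slot speCeRate fraction of SPE genes complemented (expressed) in the hybrid
#' @slot fracDeleterious fraction of genes carrying a high-effect allele in
#'   exactly one parent (complementary pairs)
#' @slot fracBothDeleterious fraction of genes deleterious in both parents
#' @slot fracSuppressed fraction of complementary pairs planted with the
#'   deleterious allele transcriptionally suppressed
#' @slot inheritanceMix named proportions over additive, dominantHP,
#'   dominantLP, overdominantAHP, overdominantBLP (must sum to 1)
#' @slot fracParentalDE fraction of genes differentially expressed between the
#'   two parents (the set eligible for inheritance-mode classification)
#' @slot entropyHeterosisR planted correlation between entropy reduction and
#'   absolute heterosis
#' @slot entropyTiltMean,entropyTiltSd mean and SD across hybrids of the
#'   expression-concentration tilt that lowers hybrid entropy
#' @slot gerpCisYearR,gerpCdsYearR planted correlations of per-hybrid
#'   complemented GERP-deleterious variant counts (cis-regulatory / CDS) with
#'   hybrid release year
#' @slot gerpFracDeleterious fraction of GERP-scored variants with RS > 2
#' @slot yearRange release-year span of the hybrids
#' @slot traitName phenotype trait simulated (grain yield per plot by default)
#' @slot exprDispersion NB dispersion of expression counts
#' @slot densityEffectFrac fraction of genes responding to planting density
#' @slot densityEffectLog2 absolute log2 fold change of density-responsive
#'   genes
#' @slot stageEffectSd SD (log scale) of per-gene stage effects
#' @export
setClass("SimulationConfig",
  representation(
    nHybrids = "integer", nSnps = "integer", nGenes = "integer",
    stages = "character", densities = "character", nReplicates = "integer",
    seed = "integer",
    aseMeanRatio = "numeric", beta0Sd = "numeric",
    aseEffectSd = "numeric", densityEffectSd = "numeric",
    meanDepth = "numeric", nbDispersion = "numeric",
    parentHetRate = "numeric", conflictRate = "numeric",
    missingRate = "numeric",
    fracSpe = "numeric", speCeRate = "numeric",
    fracDeleterious = "numeric", fracBothDeleterious = "numeric",
    fracSuppressed = "numeric",
    inheritanceMix = "numeric", fracParentalDE = "numeric",
    entropyHeterosisR = "numeric", entropyTiltMean = "numeric",
    entropyTiltSd = "numeric",
    gerpCisYearR = "numeric", gerpCdsYearR = "numeric",
    gerpFracDeleterious = "numeric",
    yearRange = "integer", traitName = "character",
    exprDispersion = "numeric", densityEffectFrac = "numeric",
    densityEffectLog2 = "numeric", stageEffectSd = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  fr <- c(parentHetRate = object@parentHetRate,
          conflictRate = object@conflictRate,
          missingRate = object@missingRate,
          fracSpe = object@fracSpe, speCeRate = object@speCeRate,
          fracDeleterious = object@fracDeleterious,
          fracBothDeleterious = object@fracBothDeleterious,
          fracSuppressed = object@fracSuppressed,
          fracParentalDE = object@fracParentalDE,
          gerpFracDeleterious = object@gerpFracDeleterious)
  bad <- fr < 0 | fr > 1
  if (any(bad))
    msg <- c(msg, paste0("fractions outside [0,1]: ",
                         paste(names(fr)[bad], collapse = ", ")))
  mix <- object@inheritanceMix
  want <- c("additive", "dominantHP", "dominantLP",
            "overdominantAHP", "overdominantBLP")
  if (!setequal(names(mix), want))
    msg <- c(msg, "inheritanceMix must be named over the five mode classes")
  else if (abs(sum(mix) - 1) > 1e-8)
    msg <- c(msg, "inheritanceMix must sum to 1")
  if (object@nReplicates < 2L)
    msg <- c(msg, "nReplicates must be >= 2")
  if (any(c(object@aseEffectSd, object@densityEffectSd, object@beta0Sd) < 0))
    msg <- c(msg, "effect SDs must be >= 0")
  if (abs(object@entropyHeterosisR) > 1 ||
      abs(object@gerpCisYearR) > 1 || abs(object@gerpCdsYearR) > 1)
    msg <- c(msg, "planted correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults mirror the trio study design this package targets: 20 landmark
#' hybrids with their parents, three developmental stages (V4, V10, VT), two
#' planting densities (HPD, LPD), three replicates, an ASE intercept
#' distribution centred on ratio 0.4675, an inheritance-mode mixture matching
#' the reported prevalence of additive/dominant/overdominant expression, a
#' 0.5 suppressed fraction among complementary deleterious pairs, and release
#' years spanning 1960-2010.
#'
#' @param nHybrids,nSnps,nGenes design sizes
#' @param stages,densities,nReplicates sampling design
#' @param seed integer seed
#' @param aseMeanRatio,beta0Sd,aseEffectSd,densityEffectSd ASE model knobs
#' @param meanDepth,nbDispersion allele-count depth model
#' @param parentHetRate,conflictRate,missingRate trio discordance rates
#' @param fracSpe,speCeRate,fracDeleterious,fracBothDeleterious,fracSuppressed
#'   planted gene-class fractions
#' @param inheritanceMix named proportions over the five planted modes
#' @param fracParentalDE fraction of genes DE between parents
#' @param entropyHeterosisR,entropyTiltMean,entropyTiltSd entropy planting
#' @param gerpCisYearR,gerpCdsYearR,gerpFracDeleterious GERP planting
#' @param yearRange integer length-2 release-year span
#' @param traitName phenotype trait label
#' @param exprDispersion,densityEffectFrac,densityEffectLog2,stageEffectSd
#'   expression model knobs
#' @return a validated \linkS4class{SimulationConfig}
#' @examples
#' cfg <- simulationConfig(nHybrids = 4, nSnps = 50, nGenes = 100, seed = 1)
#' @export
simulationConfig <- function(nHybrids = 20, nSnps = 500, nGenes = 1000,
                             stages = c("V4", "V10", "VT"),
                             densities = c("HPD", "LPD"),
                             nReplicates = 3, seed = 1,
                             aseMeanRatio = 0.4675, beta0Sd = 0.5,
                             aseEffectSd = 0.3, densityEffectSd = 0.1,
                             meanDepth = 100, nbDispersion = 0.2,
                             parentHetRate = 0.05, conflictRate = 0.02,
                             missingRate = 0.02,
                             fracSpe = 0.05, speCeRate = 0.569,
                             fracDeleterious = 0.10,
                             fracBothDeleterious = 0.02,
                             fracSuppressed = 0.5,
                             inheritanceMix = c(additive = 0.550,
                                                dominantHP = 0.235,
                                                dominantLP = 0.183,
                                                overdominantAHP = 0.015,
                                                overdominantBLP = 0.017),
                             fracParentalDE = 0.4,
                             entropyHeterosisR = 0.5,
                             entropyTiltMean = 0.06, entropyTiltSd = 0.05,
                             gerpCisYearR = 0.6, gerpCdsYearR = 0.0,
                             gerpFracDeleterious = 0.6,
                             yearRange = c(1960L, 2010L),
                             traitName = "GYPP",
                             exprDispersion = 0.01,
                             densityEffectFrac = 0.1,
                             densityEffectLog2 = 1.2,
                             stageEffectSd = 0.3) {
  new("SimulationConfig",
      nHybrids = as.integer(nHybrids), nSnps = as.integer(nSnps),
      nGenes = as.integer(nGenes), stages = as.character(stages),
      densities = as.character(densities),
      nReplicates = as.integer(nReplicates), seed = as.integer(seed),
      aseMeanRatio = aseMeanRatio, beta0Sd = beta0Sd,
      aseEffectSd = aseEffectSd, densityEffectSd = densityEffectSd,
      meanDepth = meanDepth, nbDispersion = nbDispersion,
      parentHetRate = parentHetRate, conflictRate = conflictRate,
      missingRate = missingRate,
      fracSpe = fracSpe, speCeRate = speCeRate,
      fracDeleterious = fracDeleterious,
      fracBothDeleterious = fracBothDeleterious,
      fracSuppressed = fracSuppressed,
      inheritanceMix = inheritanceMix, fracParentalDE = fracParentalDE,
      entropyHeterosisR = entropyHeterosisR,
      entropyTiltMean = entropyTiltMean, entropyTiltSd = entropyTiltSd,
      gerpCisYearR = gerpCisYearR, gerpCdsYearR = gerpCdsYearR,
      gerpFracDeleterious = gerpFracDeleterious,
      yearRange = as.integer(yearRange), traitName = traitName,
      exprDispersion = exprDispersion,
      densityEffectFrac = densityEffectFrac,
      densityEffectLog2 = densityEffectLog2,
      stageEffectSd = stageEffectSd)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      object@nHybrids, "hybrids,", object@nSnps, "SNPs,",
      object@nGenes, "genes\n")
  cat("  design:", paste(object@stages, collapse = "/"), "x",
      paste(object@densities, collapse = "/"), "x",
      object@nReplicates, "replicates; seed", object@seed, "\n")
  cat("  ASE: mean ratio", object@aseMeanRatio,
      " sd(beta0)", object@beta0Sd,
      " sd(genotype)", object@aseEffectSd,
      " sd(treatment)", object@densityEffectSd, "\n")
})

#' Trio genotype records
#'
#' Per-SNP genotypes of (female, male, hybrid) trios with, after
#' \code{\link{phaseTrio}}, the phased hybrid genotype and a filter label.
#' Genotype codes are \code{"0/0"}, \code{"0/1"}, \code{"1/1"} or
#' \code{"./."}; phased codes are \code{"0|1"} (reference allele maternal),
#' \code{"1|0"} or \code{"none"}.
#'
#' @slot records a \code{DataFrame} with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{hybrid_id}, \code{female_id}, \code{male_id},
#'   \code{female_gt}, \code{male_gt}, \code{hybrid_gt}, \code{phased_gt},
#'   \code{filter_reason}
#' @slot summary named integer vector of filter_reason counts (filled by
#'   \code{phaseTrio})
#' @export
setClass("TrioGenotypes",
  representation(records = "DataFrame", summary = "integer"))

.GT_CODES <- c("0/0", "0/1", "1/1", "./.")
.FILTER_REASONS <- c("kept", "parent_het", "conflict", "uninformative",
                     "missing")

setValidity("TrioGenotypes", function(object) {
  rec <- object@records
  need <- c("snp_id", "chrom", "pos", "hybrid_id", "female_id", "male_id",
            "female_gt", "male_gt", "hybrid_gt", "phased_gt", "filter_reason")
  miss <- setdiff(need, colnames(rec))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  ph <- rec$phased_gt
  fr <- rec$filter_reason
  ok <- is.na(fr) | fr %in% c(.FILTER_REASONS, "malformed")
  if (!all(ok)) return("invalid filter_reason values")
  phased <- !is.na(ph) & ph != "none"
  if (any(phased & (is.na(fr) | fr != "kept")))
    return("phased records must have filter_reason 'kept'")
  i01 <- which(!is.na(ph) & ph == "0|1")
  if (length(i01) && !all(rec$female_gt[i01] == "0/0" &
                          rec$male_gt[i01] == "1/1"))
    return("0|1 requires female 0/0 and male 1/1")
  i10 <- which(!is.na(ph) & ph == "1|0")
  if (length(i10) && !all(rec$female_gt[i10] == "1/1" &
                          rec$male_gt[i10] == "0/0"))
    return("1|0 requires female 1/1 and male 0/0")
  TRUE
})

#' Construct a TrioGenotypes object
#'
#' @param records data.frame or DataFrame of trio records; \code{phased_gt}
#'   and \code{filter_reason} are added (as \code{NA}) when absent.
#' @return a \linkS4class{TrioGenotypes}
#' @export
TrioGenotypes <- function(records) {
  records <- DataFrame(records)
  if (is.null(records$phased_gt))
    records$phased_gt <- rep(NA_character_, nrow(records))
  if (is.null(records$filter_reason))
    records$filter_reason <- rep(NA_character_, nrow(records))
  new("TrioGenotypes", records = records,
      summary = setNames(integer(0), character(0)))
}

#' @describeIn TrioGenotypes access the per-record table
#' @param x a TrioGenotypes object
#' @export
trioRecords <- function(x) {
  stopifnot(is(x, "TrioGenotypes"))
  x@records
}

#' @describeIn TrioGenotypes filter_reason counts from the last phasing run
#' @export
phasingSummary <- function(x) {
  stopifnot(is(x, "TrioGenotypes"))
  x@summary
}

setMethod("show", "TrioGenotypes", function(object) {
  rec <- object@records
  cat("TrioGenotypes:", nrow(rec), "records,",
      length(unique(rec$snp_id)), "SNPs,",
      length(unique(rec$hybrid_id)), "hybrids\n")
  if (length(object@summary)) {
    cat("  phasing:",
        paste(names(object@summary), object@summary, collapse = ", "), "\n")
  }
})

setMethod("dim", "TrioGenotypes", function(x) dim(x@records))

#' Coerce TrioGenotypes to data.frame
#' @param x a TrioGenotypes object
#' @param ... ignored
#' @export
as.data.frame.TrioGenotypes <- function(x, ...) {
  as.data.frame(trioRecords(x))
}
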