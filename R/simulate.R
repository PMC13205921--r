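## Synthetic-data generators. Every generator draws from a seed derived
## deterministically from the config seed plus a stage constant, so the whole
## study regenerates byte-identically for a fixed seed while the stages stay
## independently reproducible.

.stageSeed <- function(config, k) {
  as.integer((as.double(config@seed) + k * 1000003) %% 2147483647)
}

.hybridIds <- function(config) sprintf("H%02d", seq_len(config@nHybrids))
.femaleIds <- function(config) sprintf("F%02d", seq_len(config@nHybrids))
.maleIds   <- function(config) sprintf("M%02d", seq_len(config@nHybrids))
.geneIds   <- function(config) sprintf("G%04d", seq_len(config@nGenes))

#' Trio manifest of a simulation design
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return data.frame with hybrid_id, female_id, male_id
#' @export
trioManifest <- function(config) {
  data.frame(hybrid_id = .hybridIds(config),
             female_id = .femaleIds(config),
             male_id = .maleIds(config),
             stringsAsFactors = FALSE)
}

#' Simulate trio genotypes
#'
#' Draws per-SNP parental genotypes (homozygous, from a per-SNP alternative
#' allele frequency) and the Mendelian hybrid genotype, contaminated at the
#' configured rates with heterozygous-parent, Mendelian-conflict and missing
#' records so that downstream phasing has every case to handle.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return list with \code{trios} (a \linkS4class{TrioGenotypes}, unphased)
#'   and \code{truth} (per-record planted case and phase, per-SNP allele
#'   frequency)
#' @export
simulateTrios <- function(config) {
  if (config@nSnps < 1L)
    stop("empty input: nSnps must be >= 1")
  set.seed(.stageSeed(config, 1L))
  man <- trioManifest(config)
  nS <- config@nSnps; nH <- config@nHybrids
  chrom <- sort(sample(sprintf("chr%d", 1:10), nS, replace = TRUE))
  pos <- integer(nS)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(2e8, length(i)))
  }
  snp_id <- paste0(sub("chr", "", chrom), "_", pos)
  f <- runif(nS, 0.35, 0.65)

  n <- nS * nH
  snpIdx <- rep(seq_len(nS), times = nH)
  hybIdx <- rep(seq_len(nH), each = nS)
  pNorm <- 1 - config@parentHetRate - config@conflictRate - config@missingRate
  if (pNorm <= 0) stop("discordance rates sum to >= 1")
  case <- sample(c("normal", "parent_het", "conflict", "missing"), n,
                 replace = TRUE,
                 prob = c(pNorm, config@parentHetRate, config@conflictRate,
                          config@missingRate))
  fa <- f[snpIdx]
  femHom <- ifelse(runif(n) < fa, "1/1", "0/0")
  malHom <- ifelse(runif(n) < fa, "1/1", "0/0")
  female_gt <- femHom
  male_gt <- malHom
  hybrid_gt <- ifelse(femHom == malHom, femHom, "0/1")

  ip <- which(case == "parent_het")
  if (length(ip)) {
    whichParent <- runif(length(ip)) < 0.5
    female_gt[ip][whichParent] <- "0/1"
    male_gt[ip][!whichParent] <- "0/1"
    hybrid_gt[ip] <- sample(c("0/0", "0/1", "1/1"), length(ip),
                            replace = TRUE, prob = c(0.25, 0.5, 0.25))
  }
  ic <- which(case == "conflict")
  if (length(ic)) {
    # both parents share a homozygote yet the hybrid is heterozygous
    hom <- ifelse(runif(length(ic)) < fa[ic], "1/1", "0/0")
    female_gt[ic] <- hom
    male_gt[ic] <- hom
    hybrid_gt[ic] <- "0/1"
  }
  im <- which(case == "missing")
  if (length(im)) {
    member <- sample(3L, length(im), replace = TRUE)
    female_gt[im][member == 1L] <- "./."
    male_gt[im][member == 2L] <- "./."
    hybrid_gt[im][member == 3L] <- "./."
  }

  truePhase <- rep("none", n)
  informative <- case == "normal" & female_gt != male_gt
  truePhase[informative & female_gt == "0/0"] <- "0|1"
  truePhase[informative & female_gt == "1/1"] <- "1|0"
  trueCase <- ifelse(case == "normal",
                     ifelse(informative, "informative", "uninformative"),
                     case)

  rec <- data.frame(
    snp_id = snp_id[snpIdx], chrom = chrom[snpIdx], pos = pos[snpIdx],
    hybrid_id = man$hybrid_id[hybIdx],
    female_id = man$female_id[hybIdx], male_id = man$male_id[hybIdx],
    female_gt = female_gt, male_gt = male_gt, hybrid_gt = hybrid_gt,
    stringsAsFactors = FALSE)
  truth <- list(
    records = data.frame(snp_id = rec$snp_id, hybrid_id = rec$hybrid_id,
                         case = trueCase, true_phase = truePhase,
                         stringsAsFactors = FALSE),
    snps = data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                      alt_freq = f, stringsAsFactors = FALSE))
  list(trios = TrioGenotypes(rec), truth = truth)
}

#' Fully informative trio genotypes
#'
#' Constructs the idealised design in which every SNP is heterozygous and
#' phaseable in every hybrid (female parents homozygous reference, male
#' parents homozygous alternative). Used for calibration and
#' parameter-recovery studies where the analysed SNP set, not the
#' genotyping process, is of interest.
#'
#' @param nSnps,nHybrids design size
#' @return a \linkS4class{TrioGenotypes}
#' @export
informativeTrios <- function(nSnps, nHybrids) {
  snp <- sprintf("snp%05d", seq_len(nSnps))
  hyb <- sprintf("H%02d", seq_len(nHybrids))
  rec <- expand.grid(snp_id = snp, hybrid_id = hyb,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(rec$snp_id, snp)
  rec$chrom <- "chr1"
  rec$pos <- i
  rec$female_id <- sub("H", "F", rec$hybrid_id)
  rec$male_id <- sub("H", "M", rec$hybrid_id)
  rec$female_gt <- "0/0"
  rec$male_gt <- "1/1"
  rec$hybrid_gt <- "0/1"
  TrioGenotypes(rec)
}

#' Simulate per-SNP allele-specific read counts
#'
#' For every SNP heterozygous (and phaseable) in a hybrid, read totals are
#' drawn negative-binomially and alternative-allele counts binomially with
#' success probability from the logit model
#' \code{logit(p) = beta0_snp + alpha_(snp,hybrid) + gamma_(snp,density)}.
#' SNPs inside genes planted as suppressed complementary deleterious pairs
#' get their allelic balance overridden so the functional parental allele is
#' expressed about fourfold higher than the deleterious one.
#'
#' @param trios a \linkS4class{TrioGenotypes} (or the list returned by
#'   \code{\link{simulateTrios}})
#' @param config a \linkS4class{SimulationConfig}
#' @param beta0 optional numeric vector of per-SNP logit intercepts (named by
#'   snp_id or in SNP order), overriding the configured distribution
#' @param snpGene optional data.frame (snp_id, gene_id) used with
#'   \code{suppression}
#' @param suppression optional data.frame (gene_id, hybrid_id,
#'   deleterious_parent, suppressed) from the annotation generator
#' @return list with \code{counts} (snp_id, hybrid_id, density, replicate,
#'   alt_count, total_count) and \code{truth} (beta0, random effects, which
#'   rows were suppression-overridden)
#' @export
simulateAlleleCounts <- function(trios, config, beta0 = NULL,
                                 snpGene = NULL, suppression = NULL) {
  if (config@meanDepth <= 0) stop("meanDepth must be positive")
  if (is.list(trios) && !is(trios, "TrioGenotypes")) trios <- trios$trios
  set.seed(.stageSeed(config, 2L))
  rec <- as.data.frame(trioRecords(trios))
  het <- rec[rec$hybrid_gt == "0/1" &
             rec$female_gt %in% c("0/0", "1/1") &
             rec$male_gt %in% c("0/0", "1/1") &
             rec$female_gt != rec$male_gt, , drop = FALSE]
  if (!nrow(het)) stop("no phaseable heterozygous records to simulate from")

  snps <- unique(het$snp_id)
  hybs <- unique(het$hybrid_id)
  nS <- length(snps); nH <- length(hybs); nT <- length(config@densities)
  if (is.null(beta0)) {
    b0 <- rnorm(nS, qlogis(config@aseMeanRatio), config@beta0Sd)
    names(b0) <- snps
  } else {
    b0 <- if (!is.null(names(beta0))) beta0[snps] else setNames(beta0, snps)
    stopifnot(!anyNA(b0))
  }
  alpha <- matrix(rnorm(nS * nH, 0, config@aseEffectSd), nS, nH,
                  dimnames = list(snps, hybs))
  gamma <- matrix(rnorm(nS * nT, 0, config@densityEffectSd), nS, nT,
                  dimnames = list(snps, config@densities))

  si <- match(het$snp_id, snps)
  hi <- match(het$hybrid_id, hybs)
  eta0 <- b0[si] + alpha[cbind(si, hi)]

  overridden <- rep(FALSE, nrow(het))
  if (!is.null(suppression) && !is.null(snpGene) && nrow(suppression)) {
    sup <- suppression[as.logical(suppression$suppressed), , drop = FALSE]
    if (nrow(sup)) {
      gene <- snpGene$gene_id[match(het$snp_id, snpGene$snp_id)]
      key <- paste(gene, het$hybrid_id)
      supKey <- paste(sup$gene_id, sup$hybrid_id)
      hit <- match(key, supKey)
      idx <- which(!is.na(hit))
      if (length(idx)) {
        delPar <- sup$deleterious_parent[hit[idx]]
        altCarrier <- ifelse(het$female_gt[idx] == "1/1", "female", "male")
        altIsDeleterious <- altCarrier == delPar
        # functional allele ~4x the deleterious one (|log2 ratio| = 2)
        eta0[idx] <- ifelse(altIsDeleterious, -1.386, 1.386)
        overridden[idx] <- TRUE
      }
    }
  }

  nRep <- config@nReplicates
  nCell <- nrow(het) * nT * nRep
  base <- het[rep(seq_len(nrow(het)), each = nT * nRep), , drop = FALSE]
  density <- rep(rep(config@densities, each = nRep), times = nrow(het))
  replicate <- rep(rep(seq_len(nRep), times = nT), times = nrow(het))
  eta <- rep(eta0, each = nT * nRep) +
    gamma[cbind(rep(si, each = nT * nRep), match(density, config@densities))]
  total <- rnbinom(nCell, mu = config@meanDepth,
                   size = 1 / config@nbDispersion)
  alt <- rbinom(nCell, total, plogis(eta))
  counts <- data.frame(snp_id = base$snp_id, hybrid_id = base$hybrid_id,
                       density = density, replicate = replicate,
                       alt_count = alt, total_count = total,
                       stringsAsFactors = FALSE)
  truth <- list(
    beta0 = data.frame(snp_id = snps, beta0 = unname(b0),
                       true_ratio = plogis(unname(b0)),
                       stringsAsFactors = FALSE),
    alpha = alpha, gamma = gamma,
    suppressed_records = unique(data.frame(
      snp_id = het$snp_id[overridden], hybrid_id = het$hybrid_id[overridden],
      stringsAsFactors = FALSE)))
  list(counts = counts, truth = truth)
}

.expectedEntropy <- function(meanMat) {
  # meanMat: genes x samples expected relative expression for one genotype
  freq <- sweep(meanMat, 2, colSums(meanMat), "/")
  p <- rowMeans(freq)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Simulate the gene expression matrix
#'
#' Counts are negative-binomial around role-specific means implied by each
#' gene's planted inheritance mode (additive mid-parent, dominant high/low
#' parent, overdominant above/below the parental range), with planted
#' single-parent-expressed (SPE) genes, shared multiplicative stage effects,
#' a planting-density response for a subset of genes, library sizes jittered
#' by +/-20 percent, and a per-hybrid expression-concentration tilt that
#' lowers hybrid transcriptomic entropy (the tilt strength is the latent
#' factor later shared with heterosis).
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return list with \code{se} (a \code{SummarizedExperiment} carrying
#'   \code{counts} and \code{fpkm} assays, sample metadata in colData and
#'   gene lengths in rowData) and \code{truth} (per-gene modes/flags and
#'   per-hybrid tilt and expected entropies)
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom stats rnorm runif rbinom rnbinom setNames qlogis plogis median
#'   quantile rexp sd cor complete.cases
#' @export
simulateExpression <- function(config) {
  set.seed(.stageSeed(config, 3L))
  man <- trioManifest(config)
  genes <- .geneIds(config)
  nG <- config@nGenes; nH <- config@nHybrids
  len <- round(runif(nG, 500, 5000))
  base <- exp(rnorm(nG, log(300), 1.2))

  isDE <- runif(nG) < config@fracParentalDE
  l2fc <- ifelse(isDE, sample(c(-1, 1), nG, replace = TRUE) *
                   (1 + rexp(nG, 1.2)),
                 rnorm(nG, 0, 0.15))
  femMean <- base * 2^(l2fc / 2)
  malMean <- base * 2^(-l2fc / 2)

  nSpe <- round(config@fracSpe * nG)
  speIdx <- if (nSpe > 0) sample.int(nG, nSpe) else integer(0)
  speFlag <- logical(nG); speFlag[speIdx] <- TRUE
  speSilent <- rep(NA_character_, nG)
  if (nSpe > 0) {
    silentFem <- runif(nSpe) < 0.5
    speSilent[speIdx] <- ifelse(silentFem, "female", "male")
    expMean <- pmax(base[speIdx], 50)
    # silent parents are fully off: at desk-scale transcriptome sizes a
    # single stray read already exceeds the 0.1 FPKM silence threshold
    femMean[speIdx] <- ifelse(silentFem, 0, expMean)
    malMean[speIdx] <- ifelse(silentFem, expMean, 0)
    isDE[speIdx] <- TRUE
  }

  mode <- rep("additive", nG)
  deNonSpe <- which(isDE & !speFlag)
  mode[deNonSpe] <- sample(names(config@inheritanceMix), length(deNonSpe),
                           replace = TRUE, prob = config@inheritanceMix)
  mid <- (femMean + malMean) / 2
  hi <- pmax(femMean, malMean)
  lo <- pmin(femMean, malMean)
  hybMean <- mid
  hybMean[mode == "dominantHP"] <- hi[mode == "dominantHP"]
  hybMean[mode == "dominantLP"] <- lo[mode == "dominantLP"]
  hybMean[mode == "overdominantAHP"] <-
    (mid + 2 * (hi - mid))[mode == "overdominantAHP"]
  hybMean[mode == "overdominantBLP"] <-
    pmax(0.01, (mid - 2 * (hi - mid))[mode == "overdominantBLP"])
  ceFlag <- rep(NA, nG)
  if (nSpe > 0) {
    ce <- runif(nSpe) < config@speCeRate
    ceFlag[speIdx] <- ce
    expMean <- pmax(femMean[speIdx], malMean[speIdx])
    hybMean[speIdx] <- ifelse(ce, 0.8 * expMean, 0)
    mode[speIdx] <- "spe"
  }

  stageF <- matrix(exp(rnorm(nG * length(config@stages), 0,
                             config@stageEffectSd)),
                   nG, length(config@stages),
                   dimnames = list(genes, config@stages))
  densGene <- runif(nG) < config@densityEffectFrac
  densL2 <- ifelse(densGene,
                   sample(c(-1, 1), nG, replace = TRUE) *
                     config@densityEffectLog2, 0)
  densF <- cbind(HPD = 2^(densL2 / 2), LPD = 2^(-densL2 / 2))
  colnames(densF) <- config@densities[seq_len(min(2, length(config@densities)))]
  if (length(config@densities) > 2)
    densF <- cbind(densF, matrix(1, nG, length(config@densities) - 2,
                                 dimnames = list(NULL, config@densities[-(1:2)])))

  # per-hybrid entropy tilt: higher-expressed genes boosted -> lower entropy
  sLatent <- rnorm(nH)
  delta <- config@entropyTiltMean + config@entropyTiltSd * sLatent
  uG <- as.numeric(scale(log(base)))

  lines <- data.frame(
    genotype_id = c(man$hybrid_id, man$female_id, man$male_id),
    role = rep(c("hybrid", "female", "male"), each = nH),
    hybrid_id = rep(man$hybrid_id, 3),
    stringsAsFactors = FALSE)
  lineMeans <- matrix(0, nG, nrow(lines),
                      dimnames = list(genes, lines$genotype_id))
  for (i in seq_len(nrow(lines))) {
    lineMeans[, i] <- switch(lines$role[i],
      hybrid = hybMean * exp(delta[match(lines$hybrid_id[i],
                                         man$hybrid_id)] * uG),
      female = femMean,
      male = malMean)
  }

  smp <- expand.grid(replicate = seq_len(config@nReplicates),
                     density = config@densities, stage = config@stages,
                     genotype_id = lines$genotype_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  smp$role <- lines$role[match(smp$genotype_id, lines$genotype_id)]
  smp$hybrid_id <- lines$hybrid_id[match(smp$genotype_id, lines$genotype_id)]
  smp$sample_id <- paste(smp$genotype_id, smp$stage, smp$density,
                         smp$replicate, sep = "_")
  libF <- runif(nrow(smp), 0.8, 1.2)

  mu <- lineMeans[, smp$genotype_id, drop = FALSE] *
    stageF[, smp$stage, drop = FALSE] *
    densF[, smp$density, drop = FALSE]
  mu <- sweep(mu, 2, libF, "*")
  counts <- matrix(rnbinom(length(mu), mu = as.numeric(mu),
                           size = 1 / config@exprDispersion),
                   nG, nrow(smp), dimnames = list(genes, smp$sample_id))
  libSize <- colSums(counts)
  fpkm <- sweep(counts * 1e9 / len, 2, pmax(libSize, 1), "/")

  se <- SummarizedExperiment(
    assays = list(counts = counts, fpkm = fpkm),
    colData = DataFrame(smp[, c("sample_id", "genotype_id", "role",
                                "hybrid_id", "stage", "density",
                                "replicate")], row.names = smp$sample_id),
    rowData = DataFrame(gene_id = genes, length = len))

  # expected entropies from the noise-free mean profiles (the planted truth)
  cellMeans <- function(id) {
    grid <- expand.grid(stage = config@stages, density = config@densities,
                        stringsAsFactors = FALSE)
    sapply(seq_len(nrow(grid)), function(k)
      lineMeans[, id] * stageF[, grid$stage[k]] * densF[, grid$density[k]])
  }
  expH <- vapply(lines$genotype_id,
                 function(id) .expectedEntropy(cellMeans(id)), numeric(1))
  hybT <- data.frame(
    hybrid_id = man$hybrid_id, tilt = delta, latent = sLatent,
    H_hybrid = expH[man$hybrid_id], H_female = expH[man$female_id],
    H_male = expH[man$male_id], stringsAsFactors = FALSE)
  hybT$expected_dH <- (hybT$H_female + hybT$H_male) / 2 - hybT$H_hybrid

  truth <- list(
    genes = data.frame(gene_id = genes, length = len, base_mean = base,
                       parental_log2fc = l2fc, parental_de = isDE,
                       mode = mode, spe = speFlag,
                       spe_silent_parent = speSilent, ce = ceFlag,
                       density_log2fc = densL2,
                       female_mean = femMean, male_mean = malMean,
                       hybrid_mean = hybMean, stringsAsFactors = FALSE),
    hybrids = hybT)
  list(se = se, truth = truth)
}

#' Simulate phenotypes and variant-effect annotations
#'
#' Assigns release years over the configured span, draws mid-parent trait
#' values and an absolute heterosis that correlates (at the planted level)
#' with each hybrid's expected transcriptomic entropy reduction, fabricates a
#' SnpEff-style effect/impact annotation table with GERP RS scores and
#' CDS / 2-kb-upstream region labels, and plants per-hybrid counts of
#' complemented GERP-deleterious variants whose correlation with release year
#' differs between cis-regulatory and coding regions.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param expressionTruth optional \code{truth} element of
#'   \code{\link{simulateExpression}}; when supplied, heterosis is tied to
#'   the expected entropy reduction, otherwise to the latent factor alone
#' @return list with \code{phenotypes}, \code{annotations}, \code{carriers}
#'   and \code{truth}
#' @export
simulatePhenotypesAndAnnotations <- function(config, expressionTruth = NULL) {
  set.seed(.stageSeed(config, 4L))
  man <- trioManifest(config)
  genes <- .geneIds(config)
  nH <- config@nHybrids
  years <- sample(seq(config@yearRange[1], config@yearRange[2]), nH,
                  replace = TRUE)

  ## deleterious complementation / suppression structure
  nPair <- round(config@fracDeleterious * config@nGenes)
  nBoth <- round(config@fracBothDeleterious * config@nGenes)
  ann <- list(); car <- list(); pairs <- list()
  vid <- 0L
  mkvar <- function(gene, lineIds, effect, impact, region, rs) {
    vid <<- vid + 1L
    id <- sprintf("var%06d", vid)
    ann[[length(ann) + 1L]] <<- data.frame(
      variant_id = id, gene_id = gene, effect = effect, impact = impact,
      gerp_rs = rs, region = region, stringsAsFactors = FALSE)
    car[[length(car) + 1L]] <<- data.frame(
      variant_id = id, line_id = lineIds, stringsAsFactors = FALSE)
    id
  }
  highEffects <- c("frameshift", "stop_gained", "splice_acceptor",
                   "splice_donor", "gene_fusion", "exon_loss", "start_lost",
                   "stop_lost", "transcript_ablation")
  rsDraw <- function(n) ifelse(runif(n) < config@gerpFracDeleterious,
                               runif(n, 2.05, 6), runif(n, 0, 1.95))
  for (h in seq_len(nH)) {
    if (nPair > 0) {
      gs <- sample(genes, nPair)
      delPar <- sample(c("female", "male"), nPair, replace = TRUE)
      supp <- runif(nPair) < config@fracSuppressed
      for (k in seq_len(nPair)) {
        lineId <- if (delPar[k] == "female") man$female_id[h] else
          man$male_id[h]
        nv <- sample(1:2, 1)
        for (j in seq_len(nv))
          mkvar(gs[k], lineId, sample(highEffects, 1), "high", "CDS",
                rsDraw(1))
      }
      pairs[[h]] <- data.frame(gene_id = gs, hybrid_id = man$hybrid_id[h],
                               deleterious_parent = delPar,
                               suppressed = supp, stringsAsFactors = FALSE)
    }
    if (nBoth > 0) {
      gs2 <- sample(setdiff(genes, if (nPair > 0) pairs[[h]]$gene_id else
        character(0)), nBoth)
      for (g in gs2) {
        mkvar(g, man$female_id[h], sample(highEffects, 1), "high", "CDS",
              rsDraw(1))
        mkvar(g, man$male_id[h], sample(highEffects, 1), "high", "CDS",
              rsDraw(1))
      }
    }
  }

  ## complemented GERP-deleterious variants with planted year correlations
  zy <- as.numeric(scale(years))
  planted <- function(r) {
    z <- r * zy + sqrt(max(0, 1 - r^2)) * rnorm(nH)
    pmax(0L, as.integer(round(30 + 8 * z)))
  }
  cisN <- planted(config@gerpCisYearR)
  cdsN <- planted(config@gerpCdsYearR)
  for (h in seq_len(nH)) {
    par <- sample(c(man$female_id[h], man$male_id[h]), cisN[h] + cdsN[h],
                  replace = TRUE)
    regs <- c(rep("cis_upstream_2kb", cisN[h]), rep("CDS", cdsN[h]))
    for (k in seq_along(par))
      mkvar(sample(genes, 1), par[k], "other", "modifier", regs[k],
            runif(1, 2.05, 6))
  }

  ## phenotypes: heterosis tied to expected entropy reduction
  if (!is.null(expressionTruth)) {
    zdH <- as.numeric(scale(expressionTruth$hybrids$expected_dH))
  } else {
    zdH <- rnorm(nH)
  }
  r <- config@entropyHeterosisR
  hetAbs <- 60 + 18 * (r * zdH + sqrt(max(0, 1 - r^2)) * rnorm(nH))
  ph <- list()
  for (d in config@densities) {
    femV <- rnorm(nH, 100, 15) - ifelse(d == "HPD", 10, 0)
    malV <- rnorm(nH, 100, 15) - ifelse(d == "HPD", 10, 0)
    midV <- (femV + malV) / 2
    hybV <- midV + hetAbs + rnorm(nH, 0, 2)
    ph[[d]] <- rbind(
      data.frame(genotype_id = man$female_id, role = "female",
                 trait = config@traitName, density = d, value = femV,
                 release_year = NA_integer_, stringsAsFactors = FALSE),
      data.frame(genotype_id = man$male_id, role = "male",
                 trait = config@traitName, density = d, value = malV,
                 release_year = NA_integer_, stringsAsFactors = FALSE),
      data.frame(genotype_id = man$hybrid_id, role = "hybrid",
                 trait = config@traitName, density = d, value = hybV,
                 release_year = years, stringsAsFactors = FALSE))
  }
  phenotypes <- do.call(rbind, ph)
  rownames(phenotypes) <- NULL

  annotations <- do.call(rbind, ann)
  carriers <- do.call(rbind, car)
  truth <- list(
    pairs = do.call(rbind, pairs),
    years = data.frame(hybrid_id = man$hybrid_id, release_year = years,
                       stringsAsFactors = FALSE),
    gerp_counts = data.frame(hybrid_id = man$hybrid_id, release_year = years,
                             cis_count = cisN, cds_count = cdsN,
                             stringsAsFactors = FALSE),
    heterosis = data.frame(hybrid_id = man$hybrid_id,
                           trait = config@traitName,
                           true_abs_heterosis = hetAbs,
                           stringsAsFactors = FALSE))
  list(phenotypes = phenotypes, annotations = annotations,
       carriers = carriers, truth = truth)
}

#' Simulate a complete study
#'
#' Runs all generators in dependency order: trio genotypes, the SNP-to-gene
#' map, the expression matrix (whose entropy tilt is the latent factor for
#' heterosis), phenotypes/annotations, and allele-specific counts whose
#' balance honours the planted suppression structure. With \code{outdir} set,
#' all tables, a minimal phased-input VCF, the config and the ground-truth
#' tables are written as plain text.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param outdir optional directory to write the study to
#' @return list with elements \code{config}, \code{trios}, \code{snpGene},
#'   \code{expression} (SummarizedExperiment), \code{alleleCounts},
#'   \code{phenotypes}, \code{annotations}, \code{carriers}, \code{manifest}
#'   and \code{truth}
#' @export
simulateStudy <- function(config, outdir = NULL) {
  tr <- simulateTrios(config)
  set.seed(.stageSeed(config, 5L))
  snps <- tr$truth$snps$snp_id
  genes <- .geneIds(config)
  gene <- sample(genes, length(snps), replace = TRUE)
  gene[runif(length(snps)) < 0.05] <- NA  # some SNPs fall outside genes
  snpGene <- data.frame(snp_id = snps, gene_id = gene,
                        stringsAsFactors = FALSE)
  ex <- simulateExpression(config)
  pa <- simulatePhenotypesAndAnnotations(config, ex$truth)
  ac <- simulateAlleleCounts(tr, config, snpGene = snpGene,
                             suppression = pa$truth$pairs)
  out <- list(config = config, trios = tr$trios, snpGene = snpGene,
              expression = ex$se, alleleCounts = ac$counts,
              phenotypes = pa$phenotypes, annotations = pa$annotations,
              carriers = pa$carriers, manifest = trioManifest(config),
              truth = list(trios = tr$truth, expression = ex$truth,
                           phenotypes = pa$truth, alleleCounts = ac$truth))
  if (!is.null(outdir)) writeStudy(out, outdir)
  invisible(out)
}
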