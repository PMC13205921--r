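## End-to-end orchestration: simulate (or load) inputs, phase, run the ASE
## models, classify inheritance, score deleterious load, compute entropy and
## phenotype statistics, and write self-describing outputs.

#' Pipeline configuration
#'
#' Collects every stage threshold; the defaults are the thresholds the
#' package's methods are calibrated around (DE FDR 0.01 with |log2FC| > 1,
#' ASE FDR 0.05, suppression FDR 0.05, density-response FDR 0.01, SPE
#' expressed/silent FPKM cutoffs 1 and 0.1, GERP RS > 2, at least 10
#' heterozygous hybrids and 10 reads per ASE observation).
#'
#' @param simulation a \linkS4class{SimulationConfig} used when no input
#'   directory is given
#' @param inputDir optional directory of pre-existing study tables (the
#'   layout written by \code{\link{writeStudy}})
#' @param outdir optional output directory
#' @param deFdr,deLfc multifactor/parental DE thresholds
#' @param aseFdr,aseMinHybrids,aseMinTotal population ASE thresholds
#' @param imbalanceFdr,imbalanceMinTotal haplotype imbalance thresholds
#' @param responseFdr,responseLfc allelic density-response thresholds
#' @param suppressionFdr,suppressionLfc deleterious suppression thresholds
#' @param speExpr,speSilent SPE FPKM cutoffs
#' @param gerpRs GERP deleterious cutoff
#' @param daBands D/A category band edges
#' @param entropyMinFpkm gene filter for entropy profiles
#' @param mcmc an \code{\link{aseModelSpec}}
#' @param maxAseSnps cap on the number of SNPs carried into the MCMC scan
#'   (keeps full runs at desk scale); NULL for no cap
#' @return a list of class \code{PipelineConfig}
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           inputDir = NULL, outdir = NULL,
                           deFdr = 0.01, deLfc = 1,
                           aseFdr = 0.05, aseMinHybrids = 10,
                           aseMinTotal = 10,
                           imbalanceFdr = 0.05, imbalanceMinTotal = 20,
                           responseFdr = 0.01, responseLfc = 1,
                           suppressionFdr = 0.05, suppressionLfc = 1,
                           speExpr = 1, speSilent = 0.1,
                           gerpRs = 2, daBands = c(0.25, 0.75, 1.25),
                           entropyMinFpkm = 1,
                           mcmc = aseModelSpec(),
                           maxAseSnps = NULL) {
  stopifnot(is(simulation, "SimulationConfig"),
            deFdr > 0, deFdr < 1, aseFdr > 0, aseFdr < 1,
            length(daBands) == 3, !is.unsorted(daBands))
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Validate pipeline input tables
#'
#' Checks that each file exists and carries its required columns; for trio
#' tables passed to the hybrid ASE stage, checks that the hybrid genotypes
#' are phased.
#'
#' @param paths named list/vector of file paths; recognised names are
#'   genotypes, allele_counts, snp_gene_map, counts, fpkm, sample_metadata,
#'   phenotypes, annotations, carriers, trios
#' @return data.frame of violations (empty when everything validates); row
#'   and column counts are reported via message()
#' @export
validateInputs <- function(paths) {
  schema <- list(
    genotypes = c("snp_id", "hybrid_id", "female_gt", "male_gt",
                  "hybrid_gt"),
    allele_counts = c("snp_id", "hybrid_id", "density", "replicate",
                      "alt_count", "total_count"),
    snp_gene_map = c("snp_id", "gene_id"),
    sample_metadata = c("sample_id", "genotype_id", "role", "stage",
                        "density", "replicate"),
    phenotypes = c("genotype_id", "role", "trait", "density", "value"),
    annotations = c("variant_id", "gene_id", "effect", "impact", "gerp_rs",
                    "region"),
    carriers = c("variant_id", "line_id"),
    trios = c("hybrid_id", "female_id", "male_id"))
  viol <- list()
  note <- function(file, problem)
    viol[[length(viol) + 1L]] <<- data.frame(file = file, problem = problem,
                                             stringsAsFactors = FALSE)
  for (nm in names(paths)) {
    f <- paths[[nm]]
    if (!file.exists(f)) {
      note(f, "file does not exist")
      next
    }
    tab <- .readTSV(f)
    message(nm, ": ", nrow(tab), " rows, ", ncol(tab), " columns")
    req <- schema[[nm]]
    if (!is.null(req)) {
      miss <- setdiff(req, names(tab))
      if (length(miss))
        note(f, paste("missing column(s):", paste(miss, collapse = ", ")))
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(file = character(), problem = character(),
               stringsAsFactors = FALSE)
}

.stageRun <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Stages: simulate (or load) the study, phase the trios, fit the
#' population ASE model, compute per-hybrid haplotype ASE with regulatory
#' and density-response classification, call parental DE / SPE / CE and
#' inheritance modes, score deleterious complementation and suppression with
#' GERP region trends, profile transcriptomic entropy, and compute phenotype
#' heterosis and genetic gain. A stage failure aborts with the stage name;
#' outputs produced so far remain on disk when \code{outdir} is set.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param verbose print stage timings
#' @return list of stage outputs plus a \code{report} of summary tables
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  tick <- function(stage) {
    say(sprintf("[%s] %s", format(round(difftime(Sys.time(), t0,
                                                 units = "secs"), 1)),
                stage))
  }
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)

  tick("simulate")
  study <- .stageRun("simulate", simulateStudy(config$simulation,
                                               outdir = outdir))
  man <- study$manifest
  se <- study$expression

  tick("phase")
  phased <- .stageRun("phase", phaseTrio(study$trios))

  tick("ase_population")
  obs <- study$alleleCounts
  if (!is.null(config$maxAseSnps)) {
    keep <- unique(obs$snp_id)
    keep <- keep[seq_len(min(length(keep), config$maxAseSnps))]
    obs <- obs[obs$snp_id %in% keep, , drop = FALSE]
  }
  asePop <- .stageRun("ase_population",
                      fitASEPopulation(obs,
                                       minHybrids = config$aseMinHybrids,
                                       minTotal = config$aseMinTotal,
                                       spec = config$mcmc,
                                       fdrLevel = config$aseFdr))
  altFreq <- setNames(study$truth$trios$snps$alt_freq,
                      study$truth$trios$snps$snp_id)
  aseSummary <- if (nrow(asePop$fits))
    summarizeASE(asePop$fits, study$snpGene, altFreq) else list()

  tick("ase_hybrid")
  hap <- .stageRun("ase_hybrid",
                   aggregateHaplotypeCounts(study$alleleCounts, phased,
                                            study$snpGene))
  imb <- .stageRun("ase_hybrid",
                   testAllelicImbalance(hap,
                                        minTotal = config$imbalanceMinTotal,
                                        fdrLevel = config$imbalanceFdr))
  consistency <- if (nrow(imb)) classifyDensityConsistency(imb) else NULL

  tick("inheritance")
  inh <- .stageRun("inheritance", {
    lapply(seq_len(nrow(man)), function(i) {
      fid <- man$female_id[i]; mid <- man$male_id[i]
      hid <- man$hybrid_id[i]
      de <- callParentalDE(se, fid, mid, fdrLevel = config$deFdr)
      trip <- expressionTriples(se, hid, fid, mid)
      spece <- callSpeCe(trip, config$speExpr, config$speSilent)
      spece$hybrid_id <- hid
      cd <- as.data.frame(SummarizedExperiment::colData(se))
      cond <- cd$stage == cd$stage[1] & cd$density == cd$density[1]
      sub <- function(id) {
        sel <- cond & cd$genotype_id == id
        m <- SummarizedExperiment::assay(se, "counts")[, sel, drop = FALSE]
        m
      }
      deGenes <- de$gene_id[de$de]
      call <- if (length(deGenes)) {
        m1 <- sub(fid)[deGenes, , drop = FALSE]
        m2 <- sub(mid)[deGenes, , drop = FALSE]
        mF <- sub(hid)[deGenes, , drop = FALSE]
        cbind(hybrid_id = hid,
              classifyInheritance(m1, m2, mF, daBands = config$daBands))
      } else NULL
      hh <- hap[hap$hybrid_id == hid, , drop = FALSE]
      resp <- if (nrow(hh))
        classifyAllelicResponse(hh, fdrLevel = config$responseFdr,
                                lfcThreshold = config$responseLfc) else NULL
      pooled <- if (nrow(imb)) .poolHaplotype(
        imb[imb$hybrid_id == hid, , drop = FALSE],
        by = c("gene_id", "hybrid_id")) else NULL
      reg <- if (!is.null(pooled) && nrow(pooled))
        classifyRegulatoryPattern(pooled, de) else NULL
      list(hybrid_id = hid, parentalDE = de, spece = spece,
           inheritance = call, regulatory = reg, response = resp)
    })
  })
  speceAll <- do.call(rbind, lapply(inh, `[[`, "spece"))
  speceSummary <- summarizeSpeCe(speceAll)

  tick("deleterious")
  delet <- .stageRun("deleterious", {
    idd <- identifyDeleterious(study$annotations, study$carriers, man)
    cp <- findComplementaryPairs(study$annotations, study$carriers, man)
    sup <- callSuppression(cp$pairs, hap,
                           fdrLevel = config$suppressionFdr,
                           lfcThreshold = config$suppressionLfc)
    list(identified = idd, pairs = cp, suppression = sup)
  })

  tick("entropy")
  ent <- .stageRun("entropy", trioEntropy(se, man, config$entropyMinFpkm))

  tick("heterosis_stats")
  het <- .stageRun("heterosis_stats",
                   computeHeterosis(study$phenotypes, man))
  gain <- lapply(split(het, het$density), function(d)
    geneticGain(d$absolute_heterosis, d$release_year))
  entAssoc <- .stageRun("heterosis_stats",
                        entropyHeterosisAssociation(ent, het))
  years <- study$truth$phenotypes$years
  hybData <- data.frame(hybrid_id = years$hybrid_id,
                        release_year = years$release_year,
                        stringsAsFactors = FALSE)
  hv <- het[het$trait == config$simulation@traitName, , drop = FALSE]
  hybData$heterosis <- tapply(hv$absolute_heterosis, hv$hybrid_id,
                              mean)[hybData$hybrid_id]
  gerp <- .stageRun("deleterious",
                    gerpRegionTrends(study$annotations, study$carriers,
                                     man, hybData,
                                     rsThreshold = config$gerpRs))

  report <- list(
    phasing = phasingSummary(phased),
    ase_population = aseSummary,
    ase_imbalance = if (nrow(imb))
      table(imb$hybrid_id, imb$ase) else NULL,
    density_consistency = if (!is.null(consistency))
      table(consistency$density_consistency) else NULL,
    inheritance_modes = table(unlist(lapply(inh, function(x)
      if (!is.null(x$inheritance)) x$inheritance$mode else character(0)))),
    regulatory_patterns = table(unlist(lapply(inh, function(x)
      if (!is.null(x$regulatory)) x$regulatory$pattern else character(0)))),
    allelic_response = table(unlist(lapply(inh, function(x)
      if (!is.null(x$response)) x$response$allelic_response else
        character(0)))),
    spe_ce = speceSummary[c("meanSpe", "meanCe", "pctCe")],
    suppression = delet$suppression$perHybrid,
    gerp = gerp$correlations,
    entropy_association = entAssoc,
    genetic_gain = gain)

  out <- list(config = config, study = study, phased = phased,
              asePopulation = asePop, haplotype = hap, imbalance = imb,
              consistency = consistency, inheritance = inh,
              speceSummary = speceSummary, deleterious = delet,
              gerp = gerp, entropy = ent, heterosis = het,
              entropyAssociation = entAssoc, report = report)

  if (!is.null(outdir)) {
    .writeTSV(as.data.frame(trioRecords(phased)),
              file.path(outdir, "phased_genotypes.tsv"))
    writeTrioVCF(phased, file.path(outdir, "phased_genotypes.vcf"))
    if (nrow(asePop$fits))
      .writeTSV(asePop$fits, file.path(outdir, "ase_population_fits.tsv"))
    .writeTSV(hap, file.path(outdir, "haplotype_counts.tsv"))
    if (nrow(imb)) .writeTSV(imb, file.path(outdir, "ase_imbalance.tsv"))
    .writeTSV(ent, file.path(outdir, "entropy.tsv"))
    .writeTSV(het, file.path(outdir, "heterosis.tsv"))
    if (nrow(delet$suppression$pairs))
      .writeTSV(delet$suppression$pairs,
                file.path(outdir, "suppression.tsv"))
    meta <- list(
      package = "heterASE",
      version = as.character(utils::packageVersion("heterASE")),
      seed = config$simulation@seed,
      null_ratio = asePop$null,
      n_nonconverged = asePop$nNonConverged,
      posterior_p = "two-sided posterior tail probability about the null",
      haplotype_counting = "per-SNP summation (inputs free of double-counted reads)",
      thresholds = config[c("deFdr", "deLfc", "aseFdr", "aseMinHybrids",
                            "aseMinTotal", "imbalanceFdr", "responseFdr",
                            "suppressionFdr", "suppressionLfc", "speExpr",
                            "speSilent", "gerpRs", "daBands",
                            "entropyMinFpkm")])
    yaml::write_yaml(meta, file.path(outdir, "run_metadata.yaml"))
  }
  invisible(out)
}
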