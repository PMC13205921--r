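test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(nReplicates = 1), "nReplicates")
  expect_error(simulationConfig(fracSpe = 1.2), "fractions")
  expect_error(simulationConfig(inheritanceMix = c(additive = 0.5,
                                                   dominantHP = 0.2,
                                                   dominantLP = 0.2,
                                                   overdominantAHP = 0.05,
                                                   overdominantBLP = 0.1)),
               "sum to 1")
  expect_error(simulationConfig(entropyHeterosisR = 1.5), "correlations")
})

test_that("trio generator refuses empty input and hits planted case rates", {
  expect_error(simulateTrios(simulationConfig(nSnps = 0)), "empty")
  cfg <- simulationConfig(nHybrids = 10, nSnps = 400, seed = 9)
  tr <- simulateTrios(cfg)
  truth <- tr$truth$records
  n <- nrow(truth)
  for (case in c("parent_het", "conflict", "missing")) {
    rate <- switch(case, parent_het = cfg@parentHetRate,
                   conflict = cfg@conflictRate, missing = cfg@missingRate)
    se <- sqrt(rate * (1 - rate) / n)
    expect_lt(abs(mean(truth$case == case) - rate), 3 * se + 1e-9,
              label = case)
  }
  # every informative record carries a known phase
  inf <- truth[truth$case == "informative", ]
  expect_true(all(inf$true_phase %in% c("0|1", "1|0")))
})

test_that("a fixed seed regenerates the study byte-identically", {
  cfg <- simulationConfig(nHybrids = 3, nSnps = 40, nGenes = 60, seed = 33)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(as.data.frame(trioRecords(s1$trios)),
                   as.data.frame(trioRecords(s2$trios)))
  expect_identical(s1$alleleCounts, s2$alleleCounts)
  expect_identical(SummarizedExperiment::assay(s1$expression, "counts"),
                   SummarizedExperiment::assay(s2$expression, "counts"))
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$annotations, s2$annotations)
  d1 <- tempfile(); d2 <- tempfile()
  writeStudy(s1, d1); writeStudy(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
})

test_that("allele counts follow the planted logit model", {
  expect_error(
    simulateAlleleCounts(informativeTrios(5, 5),
                         simulationConfig(meanDepth = 0)),
    "meanDepth")
  # symmetric null: no intercept spread, no random effects
  cfg0 <- simulationConfig(nHybrids = 12, nSnps = 60, seed = 5,
                           aseMeanRatio = 0.5, beta0Sd = 0,
                           aseEffectSd = 0, densityEffectSd = 0)
  ac <- simulateAlleleCounts(informativeTrios(60, 12), cfg0)
  frac <- sum(ac$counts$alt_count) / sum(ac$counts$total_count)
  se <- 0.5 / sqrt(sum(ac$counts$total_count))
  expect_lt(abs(frac - 0.5), 3 * se)
  # planted ratio 0.2 at large depth
  cfg2 <- simulationConfig(nHybrids = 12, nSnps = 40, seed = 6,
                           aseMeanRatio = 0.2, beta0Sd = 0,
                           aseEffectSd = 0, densityEffectSd = 0,
                           meanDepth = 5000)
  ac2 <- simulateAlleleCounts(informativeTrios(40, 12), cfg2)
  frac2 <- sum(ac2$counts$alt_count) / sum(ac2$counts$total_count)
  expect_lt(abs(frac2 - 0.2), 3 * sqrt(0.2 * 0.8 /
                                         sum(ac2$counts$total_count)))
  # zero-total records are retained for downstream filters to drop
  cfgz <- simulationConfig(nHybrids = 10, nSnps = 50, seed = 7,
                           meanDepth = 2, nbDispersion = 1)
  acz <- simulateAlleleCounts(informativeTrios(50, 10), cfgz)
  expect_gt(sum(acz$counts$total_count == 0), 0)
  expect_true(all(acz$counts$alt_count <= acz$counts$total_count))
})

test_that("expression generator plants modes, SPE structure and full truth",
{
  st <- smallStudy()
  tg <- st$truth$expression$genes
  se <- st$expression
  expect_setequal(tg$gene_id, rownames(se))
  # additive genes sit at the mid-parent mean by construction
  add <- tg[tg$mode == "additive", ]
  expect_equal(add$hybrid_mean, (add$female_mean + add$male_mean) / 2)
  # AHP genes exceed the high parent
  ahp <- tg[tg$mode == "overdominantAHP", ]
  expect_true(all(ahp$hybrid_mean > pmax(ahp$female_mean, ahp$male_mean)))
  # planted SPE genes are genuinely silent/expressed on realized FPKM
  man <- st$manifest
  trip <- expressionTriples(se, man$hybrid_id[1], man$female_id[1],
                            man$male_id[1])
  spe <- tg$spe
  silentF <- spe & tg$spe_silent_parent == "female"
  silentM <- spe & tg$spe_silent_parent == "male"
  expect_true(all(trip$fpkm_p1[silentF] < 0.1))
  expect_true(all(trip$fpkm_p2[silentM] < 0.1))
  expect_true(all(trip$fpkm_p2[silentF] > 1))
  expect_true(all(trip$fpkm_p1[silentM] > 1))
})

test_that("planted SPE gene count is binomial around its target", {
  cfg <- simulationConfig(nHybrids = 2, nGenes = 1000, nSnps = 10,
                          fracSpe = 0.1, seed = 17)
  ex <- simulateExpression(cfg)
  nSpe <- sum(ex$truth$genes$spe)
  expect_lt(abs(nSpe - 100), 3 * sqrt(1000 * 0.1 * 0.9) + 1)
})

test_that("phenotype generator respects a null entropy-heterosis link", {
  cfg <- simulationConfig(nHybrids = 40, nGenes = 100, nSnps = 10,
                          seed = 19, entropyHeterosisR = 0)
  ex <- simulateExpression(cfg)
  pa <- simulatePhenotypesAndAnnotations(cfg, ex$truth)
  r <- cor(ex$truth$hybrids$expected_dH,
           pa$truth$heterosis$true_abs_heterosis)
  expect_lt(abs(r), 3 / sqrt(40))
})

test_that("zero deleterious fraction yields zero complementary pairs", {
  cfg <- simulationConfig(nHybrids = 4, nGenes = 100, nSnps = 10, seed = 21,
                          fracDeleterious = 0, fracBothDeleterious = 0,
                          gerpCisYearR = 0, gerpCdsYearR = 0)
  pa <- simulatePhenotypesAndAnnotations(cfg)
  man <- trioManifest(cfg)
  cp <- findComplementaryPairs(pa$annotations, pa$carriers, man)
  expect_identical(nrow(cp$pairs), 0L)
})

test_that("ground truth covers every generated entity", {
  st <- smallStudy()
  expect_true(all(st$alleleCounts$snp_id %in%
                    st$truth$alleleCounts$beta0$snp_id))
  expect_true(all(rownames(st$expression) %in%
                    st$truth$expression$genes$gene_id))
  expect_true(all(st$manifest$hybrid_id %in%
                    st$truth$phenotypes$years$hybrid_id))
  rec <- as.data.frame(trioRecords(st$trios))
  tkey <- paste(st$truth$trios$records$snp_id,
                st$truth$trios$records$hybrid_id)
  expect_true(all(paste(rec$snp_id, rec$hybrid_id) %in% tkey))
})
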