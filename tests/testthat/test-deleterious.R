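annRow <- function(id, gene, effect = "frameshift", impact = "high",
                   rs = 3, region = "CDS")
  data.frame(variant_id = id, gene_id = gene, effect = effect,
             impact = impact, gerp_rs = rs, region = region,
             stringsAsFactors = FALSE)

toyManifest <- data.frame(hybrid_id = "H1", female_id = "F1",
                          male_id = "M1", stringsAsFactors = FALSE)

test_that("deleterious counting is gene-level with mid-parent averaging", {
  ann <- rbind(annRow("v1", "gA"), annRow("v2", "gA"),  # same gene, twice
               annRow("v3", "gB"), annRow("v4", "gC"),
               annRow("v5", "gD", effect = "missense", impact = "moderate"))
  car <- data.frame(variant_id = c("v1", "v2", "v3", "v4", "v5"),
                    line_id = c("F1", "F1", "F1", "M1", "M1"))
  out <- identifyDeleterious(ann, car, toyManifest)
  # F1 carries gA (once, despite two variants) and gB; M1 carries gC only
  expect_identical(out$perLine$n_deleterious[out$perLine$line_id == "F1"],
                   2L)
  expect_identical(out$perLine$n_deleterious[out$perLine$line_id == "M1"],
                   1L)
  expect_equal(out$perHybrid$mid_parent, 1.5)
  # no high-effect annotations at all
  out0 <- identifyDeleterious(ann[5, ], car[5, ], toyManifest)
  expect_equal(out0$perHybrid$mid_parent, 0)
})

test_that("complementary pairs require exactly one deleterious parent", {
  ann <- rbind(annRow("v1", "gA"), annRow("v2", "gB"), annRow("v3", "gB"),
               annRow("v4", "gC", effect = "synonymous",
                      impact = "low"))
  car <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                    line_id = c("F1", "F1", "M1", "F1"))
  cp <- findComplementaryPairs(ann, car, toyManifest)
  # gA: female only -> pair; gB: both parents -> excluded; gC: not
  # high-effect -> excluded
  expect_identical(cp$pairs$gene_id, "gA")
  expect_identical(cp$pairs$deleterious_parent, "female")
})

test_that("suppression calls the one pair with the right direction, fold
          and significance", {
  pairs <- data.frame(gene_id = c("g1", "g2", "g3"), hybrid_id = "H1",
                      deleterious_parent = "male",
                      stringsAsFactors = FALSE)
  hap <- data.frame(gene_id = c("g1", "g2", "g3"), hybrid_id = "H1",
                    maternal_count = c(80L, 55L, 20L),   # functional allele
                    paternal_count = c(20L, 45L, 80L),   # deleterious allele
                    stringsAsFactors = FALSE)
  out <- callSuppression(pairs, hap)
  sup <- setNames(out$pairs$suppressed, out$pairs$gene_id)
  expect_identical(unname(sup[c("g1", "g2", "g3")]),
                   c(TRUE, FALSE, FALSE))
  expect_identical(sum(out$pairs$suppressed), 1L)
  expect_equal(out$perHybrid$proportion, 1 / 3)
})

test_that("suppression counts are monotone in the fold threshold and
          proportions stay in [0, 1]", {
  set.seed(31)
  n <- 60
  pairs <- data.frame(gene_id = sprintf("g%02d", 1:n), hybrid_id = "H1",
                      deleterious_parent = sample(c("female", "male"), n,
                                                  TRUE),
                      stringsAsFactors = FALSE)
  fun <- rbinom(n, 200, runif(n, 0.3, 0.95))
  hap <- data.frame(gene_id = pairs$gene_id, hybrid_id = "H1",
                    maternal_count = ifelse(pairs$deleterious_parent ==
                                              "male", fun, 200L - fun),
                    paternal_count = ifelse(pairs$deleterious_parent ==
                                              "male", 200L - fun, fun),
                    stringsAsFactors = FALSE)
  counts <- sapply(c(0.5, 1, 1.5, 2, 3), function(th)
    sum(callSuppression(pairs, hap, lfcThreshold = th)$pairs$suppressed))
  expect_true(all(diff(counts) <= 0))
  props <- callSuppression(pairs, hap)$perHybrid$proportion
  expect_true(all(props >= 0 & props <= 1))
})

test_that("GERP region trends recover the generator's planted correlations",
{
  cfg <- simulationConfig(nHybrids = 30, nGenes = 200, nSnps = 10,
                          seed = 32, gerpCisYearR = 0.6, gerpCdsYearR = 0)
  pa <- simulatePhenotypesAndAnnotations(cfg)
  man <- trioManifest(cfg)
  g <- gerpRegionTrends(pa$annotations, pa$carriers, man,
                        pa$truth$years)
  rCis <- g$correlations$r[g$correlations$region == "cis_upstream_2kb"]
  rCds <- g$correlations$r[g$correlations$region == "CDS"]
  expect_lt(abs(rCis - 0.6), 3 * (1 - 0.6^2) / sqrt(30))
  expect_lt(abs(rCds - 0), 3 / sqrt(30))
})

test_that("GERP trend edge cases: sub-threshold scores, zero variance,
          too few hybrids", {
  man3 <- data.frame(hybrid_id = c("H1", "H2", "H3"),
                     female_id = c("F1", "F2", "F3"),
                     male_id = c("M1", "M2", "M3"))
  hd <- data.frame(hybrid_id = man3$hybrid_id, release_year = c(1970,
                                                                1990, 2005))
  ann <- annRow(sprintf("v%d", 1:3), sprintf("g%d", 1:3), rs = 1.5,
                region = "cis_upstream_2kb")
  car <- data.frame(variant_id = sprintf("v%d", 1:3),
                    line_id = c("F1", "F2", "F3"))
  out <- expect_warning(gerpRegionTrends(ann, car, man3, hd),
                        "zero variance")
  expect_true(all(out$counts$cis_upstream_2kb == 0))  # RS 1.5 never counts
  expect_true(all(is.na(out$correlations$r)))
  expect_error(gerpRegionTrends(ann, car, man3[1:2, ], hd), "3 hybrids")
})
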