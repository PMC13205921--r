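test_that("D/A ratio arithmetic, symmetry and degenerate input", {
  expect_equal(computeDA(6, 14, 10), 0)
  expect_equal(computeDA(6, 14, 14), 1)
  expect_equal(computeDA(6, 14, 18), 2)
  expect_equal(computeDA(6, 14, 2), -2)
  expect_equal(computeDA(14, 6, 18), computeDA(6, 14, 18))
  expect_true(is.na(computeDA(5, 5, 7)))
})

test_that("SPE and CE thresholds apply the silent/expressed FPKM gates", {
  trip <- data.frame(gene_id = c("a", "b", "c", "d"),
                     fpkm_p1 = c(0.05, 0.5, 0.05, 5),
                     fpkm_p2 = c(3, 3, 3, 8),
                     fpkm_f1 = c(2, 2, 0.8, 6))
  out <- callSpeCe(trip)
  expect_identical(out$spe, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(out$ce, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(out$spe_silent_parent[1], "female")
  expect_identical(out$parent_class,
                   c("genotype_dependent", "genotype_dependent",
                     "genotype_dependent", "expressed"))
})

test_that("parental DE tiers follow the fold-change ladder", {
  set.seed(21)
  # 100 planted genes over the tier ladder (random direction) on a
  # background of 300 undisturbed genes that anchor the normalisation
  folds <- rep(c(0, 1.5, 2.5, 3.5), 25) *
    sample(c(-1, 1), 100, replace = TRUE)
  mu <- 500
  planted <- rep(c(0, 1.5, 2.5, 3.5), 25)
  cnt <- cbind(nbMat(c(mu * 2^folds, rep(mu, 300)), 4, 0.02),
               nbMat(rep(mu, 400), 4, 0.02))
  rownames(cnt) <- sprintf("g%03d", seq_len(400))
  cd <- data.frame(genotype_id = rep(c("F1p", "M1p"), each = 4),
                   stage = "V4", density = "HPD",
                   role = rep(c("female", "male"), each = 4),
                   replicate = rep(1:4, 2))
  cd$sample_id <- paste0(cd$genotype_id, "_", cd$replicate)
  colnames(cnt) <- cd$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt, fpkm = cnt),
    colData = S4Vectors::DataFrame(cd, row.names = cd$sample_id))
  res <- callParentalDE(se, "F1p", "M1p")[1:100, ]
  expect_gte(mean(res$tier[planted == 0] == "none"), 0.9)
  expect_gte(mean(res$tier[planted == 1.5] == "DE_2"), 0.8)
  expect_gte(mean(res$tier[planted == 2.5] == "DE_4"), 0.8)
  expect_gte(mean(res$tier[planted == 3.5] == "DE_8"), 0.8)
  expect_true(all(res$de[res$tier != "none"]))
  # estimated fold changes carry the planted orientation (female over male)
  expect_gt(cor(res$log2fc, folds), 0.99)
})

test_that("planted inheritance modes are recovered by BIC classification", {
  gen <- plantedInheritance(nPer = 40, seed = 22)
  out <- classifyInheritance(gen$m1, gen$m2, gen$mF)
  expect_gte(mean(out$mode[gen$idx] == gen$planted), 0.9)
  # relabelling parents leaves the call invariant (D/A uses mean and max)
  out2 <- classifyInheritance(gen$m2, gen$m1, gen$mF)
  expect_gte(mean(out2$mode[gen$idx] == gen$planted), 0.9)
})

test_that("multifactor DE recovers a planted hybrid effect and stays quiet
          on null genes", {
  set.seed(23)
  nG <- 400
  grid <- expand.grid(replicate = 1:3, density = c("HPD", "LPD"),
                      stage = c("V4", "V10"),
                      role = c("hybrid", "female", "male"),
                      stringsAsFactors = FALSE)
  grid$genotype_id <- paste0(substr(grid$role, 1, 1), "01")
  grid$sample_id <- sprintf("s%02d", seq_len(nrow(grid)))
  mu <- matrix(200, nG, nrow(grid))
  hybridGenes <- 1:20
  mu[hybridGenes, grid$role == "hybrid"] <- 800     # planted 4-fold effect
  cnt <- matrix(rnbinom(length(mu), mu = as.numeric(mu), size = 20),
                nG, nrow(grid),
                dimnames = list(sprintf("g%04d", 1:nG), grid$sample_id))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    colData = S4Vectors::DataFrame(grid, row.names = grid$sample_id))
  res <- fitMultifactorDE(se)
  hv <- res$hybrid_vs_inbred
  expect_true(all(hv$de[hybridGenes]))
  expect_lt(mean(abs(hv$log2fc[hybridGenes] - 2)), 0.3)
  # the same genes carry no density effect
  expect_false(any(res$density$de[hybridGenes]))
  # null genes: at most 2% flagged at FDR 0.01 with the fold-change gate
  nullGenes <- setdiff(seq_len(nG), hybridGenes)
  expect_lte(mean(hv$de[nullGenes]), 0.02)
  expect_lte(mean(res$density$de[nullGenes]), 0.02)
})

test_that("a confounded design aborts naming the factors", {
  grid <- data.frame(replicate = rep(1:3, 4),
                     density = rep(c("HPD", "LPD"), each = 6),
                     stage = rep(c("V4", "V10"), 6),
                     role = rep(c("hybrid", "female"), each = 6),
                     genotype_id = rep(c("H01", "F01"), each = 6))
  grid$sample_id <- sprintf("s%02d", seq_len(nrow(grid)))
  cnt <- matrix(100L, 20, nrow(grid),
                dimnames = list(sprintf("g%02d", 1:20), grid$sample_id))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    colData = S4Vectors::DataFrame(grid, row.names = grid$sample_id))
  expect_error(fitMultifactorDE(se), "rank deficient")
})

test_that("CE never exceeds SPE per hybrid on simulated studies", {
  st <- smallStudy()
  man <- st$manifest
  spece <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
    out <- callSpeCe(expressionTriples(st$expression, man$hybrid_id[i],
                                       man$female_id[i], man$male_id[i]))
    out$hybrid_id <- man$hybrid_id[i]
    out
  }))
  s <- summarizeSpeCe(spece)
  expect_true(all(s$perHybrid$n_ce <= s$perHybrid$n_spe))
  expect_true(s$pctCe >= 0 && s$pctCe <= 100)
})
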