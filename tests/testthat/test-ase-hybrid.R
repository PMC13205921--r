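phasedToy <- function(snps, phases, hybrid = "H1") {
  df <- data.frame(snp_id = snps, chrom = "chr1", pos = seq_along(snps),
                   hybrid_id = hybrid, female_id = "F1", male_id = "M1",
                   female_gt = ifelse(phases == "0|1", "0/0", "1/1"),
                   male_gt = ifelse(phases == "0|1", "1/1", "0/0"),
                   hybrid_gt = "0/1", phased_gt = phases,
                   filter_reason = "kept", stringsAsFactors = FALSE)
  TrioGenotypes(df)
}

countRow <- function(snp, alt, tot, hybrid = "H1", dens = "HPD", rep = 1L)
  data.frame(snp_id = snp, hybrid_id = hybrid, density = dens,
             replicate = rep, alt_count = alt, total_count = tot,
             stringsAsFactors = FALSE)

test_that("haplotype aggregation sums per-SNP counts with phase
          orientation", {
  ph <- phasedToy(c("s1", "s2", "s3"), c("1|0", "1|0", "0|1"))
  # s1, s2 in geneA; alt allele is maternal for 1|0
  cnt <- rbind(countRow("s1", 10, 15), countRow("s2", 20, 35),
               countRow("s3", 4, 10))
  map <- data.frame(snp_id = c("s1", "s2", "s3"),
                    gene_id = c("geneA", "geneA", "geneB"))
  hap <- aggregateHaplotypeCounts(cnt, ph, map)
  a <- hap[hap$gene_id == "geneA", ]
  expect_identical(c(a$maternal_count, a$paternal_count), c(30L, 20L))
  b <- hap[hap$gene_id == "geneB", ]
  expect_identical(c(b$maternal_count, b$paternal_count), c(6L, 4L))
  # unmapped genes absent; multi-gene SNPs dropped with a warning
  map2 <- rbind(map, data.frame(snp_id = "s3", gene_id = "geneC"))
  expect_warning(hap2 <- aggregateHaplotypeCounts(cnt, ph, map2),
                 "multiple genes")
  expect_false("geneB" %in% hap2$gene_id)
})

test_that("flipping every phase exactly swaps maternal and paternal", {
  st <- smallStudy()
  ph <- phaseTrio(st$trios)
  hap <- aggregateHaplotypeCounts(st$alleleCounts, ph, st$snpGene)
  rec <- trioRecords(ph)
  rec$phased_gt[rec$phased_gt == "0|1"] <- "flip"
  rec$phased_gt[rec$phased_gt == "1|0"] <- "0|1"
  rec$phased_gt[rec$phased_gt == "flip"] <- "1|0"
  rec$female_gt2 <- rec$female_gt
  rec$female_gt <- rec$male_gt
  rec$male_gt <- rec$female_gt2
  rec$female_gt2 <- NULL
  flipped <- aggregateHaplotypeCounts(st$alleleCounts,
                                      TrioGenotypes(rec), st$snpGene)
  expect_identical(hap$maternal_count, flipped$paternal_count)
  expect_identical(hap$paternal_count, flipped$maternal_count)
})

hapRow <- function(gene, m, p, hybrid = "H1", dens = "HPD", rep = 1L)
  data.frame(gene_id = gene, hybrid_id = hybrid, density = dens,
             replicate = rep, maternal_count = m, paternal_count = p,
             stringsAsFactors = FALSE)

test_that("allelic imbalance testing matches exact binomial closed forms", {
  hap <- rbind(hapRow("g1", 50, 50), hapRow("g2", 80, 20),
               hapRow("g3", 0, 40), hapRow("g4", 5, 5))
  res <- testAllelicImbalance(hap, minTotal = 20)
  expect_false("g4" %in% res$gene_id)  # below the read minimum
  g1 <- res[res$gene_id == "g1", ]
  expect_equal(g1$p_value, 1)
  expect_false(g1$ase)
  g2 <- res[res$gene_id == "g2", ]
  expect_equal(g2$ase_log2_ratio, 2)
  expect_lt(g2$p_value, 1e-6)
  expect_true(g2$ase)
  g3 <- res[res$gene_id == "g3", ]
  expect_equal(g3$p_value, 2 * 0.5^40)
})

test_that("regulatory patterns follow the BIC model comparison at high
          depth", {
  de <- data.frame(gene_id = sprintf("g%d", 1:6),
                   log2fc = c(2, 2, 2, 2, 1, 2),
                   de = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  tab <- rbind(hapRow("g1", 800, 200),   # ratio 2 = parental: cis only
               hapRow("g2", 500, 500),   # balanced despite parental DE
               hapRow("g3", 333, 667),   # opposite to parental direction
               hapRow("g4", 667, 333),   # ratio 1 < parental 2
               hapRow("g5", 800, 200),   # ratio 2 > parental 1
               hapRow("g6", 800, 200))   # no parental DE info
  out <- classifyRegulatoryPattern(tab, de)
  expect_identical(out$pattern,
                   c("cis_only", "trans_only", "unexpected",
                     "cis_plus_trans_same", "cis_plus_trans_opposite",
                     "ambiguous"))
})

test_that("planted regulatory classes are recovered at depth >= 500", {
  set.seed(12)
  n <- 150
  cls <- rep(c("cis", "trans", "cis_trans"), each = n / 3)
  L <- runif(n, 1.5, 3) * sample(c(-1, 1), n, TRUE)
  r <- ifelse(cls == "cis", L, ifelse(cls == "trans", 0, L / 2))
  depth <- 600
  m <- rbinom(n, depth, 2^r / (1 + 2^r))
  tab <- hapRow(sprintf("g%03d", 1:n), m, depth - m)
  de <- data.frame(gene_id = tab$gene_id, log2fc = L, de = TRUE)
  out <- classifyRegulatoryPattern(tab, de)
  hit <- (cls == "cis" & out$pattern == "cis_only") |
    (cls == "trans" & out$pattern == "trans_only") |
    (cls == "cis_trans" & grepl("^cis_plus_trans", out$pattern))
  expect_gte(mean(hit), 0.9)
  # partition: one pattern per eligible gene
  expect_false(anyNA(out$pattern))
})

test_that("density consistency classes cover the four ASE configurations", {
  mk <- function(gene, rHPD, rLPD, aseH, aseL)
    data.frame(gene_id = gene, hybrid_id = "H1",
               density = c("HPD", "LPD"),
               maternal_count = 50L, paternal_count = 50L,
               ase_log2_ratio = c(rHPD, rLPD), ase = c(aseH, aseL))
  res <- rbind(mk("g1", 1, 1, TRUE, TRUE),    # same bias both densities
               mk("g2", 1, -1, TRUE, TRUE),   # bias flips
               mk("g3", 1, 1, TRUE, FALSE),
               mk("g4", 1, 1, FALSE, TRUE),
               mk("g5", 1, 1, FALSE, FALSE))
  out <- classifyDensityConsistency(res)
  got <- setNames(out$density_consistency, out$gene_id)
  expect_identical(unname(got[c("g1", "g2", "g3", "g4", "g5")]),
                   c("consistent", "direction_shift", "HPD_only",
                     "LPD_only", "none"))
  # single-density genes classified from that density alone, flagged
  one <- mk("g6", 2, 0, TRUE, FALSE)[1, ]
  out1 <- classifyDensityConsistency(one)
  expect_identical(out1$density_consistency, "HPD_only")
  expect_true(out1$single_density)
})

test_that("allele-specific density response categories and swap symmetry",
{
  set.seed(13)
  # planted response genes on a background of null genes that anchor the
  # library-size normalisation
  genes <- c("up_both", "fem_only", "opposite", "flat",
             sprintf("null%02d", 1:30))
  fcM <- c(4, 4, 4, 1, rep(1, 30))
  fcP <- c(4, 1, 0.25, 1, rep(1, 30))
  mk <- function(dens, rep) {
    f <- function(fc) rnbinom(length(genes),
                              mu = if (dens == "HPD") 300 * fc else
                                rep(300, length(genes)), size = 50)
    data.frame(gene_id = genes, hybrid_id = "H1", density = dens,
               replicate = rep, maternal_count = f(fcM),
               paternal_count = f(fcP), stringsAsFactors = FALSE)
  }
  hap <- do.call(rbind, lapply(c("HPD", "LPD"), function(d)
    do.call(rbind, lapply(1:4, function(r) mk(d, r)))))
  out <- classifyAllelicResponse(hap, fdrLevel = 0.01)
  got <- setNames(out$allelic_response, out$gene_id)
  expect_identical(unname(got[genes[1:4]]),
                   c("same_direction", "female_specific",
                     "opposite_direction", "none"))
  expect_true(all(got[genes[-(1:4)]] == "none"))
  # swapping the parental labels mirrors the classification
  swapped <- hap
  swapped$maternal_count <- hap$paternal_count
  swapped$paternal_count <- hap$maternal_count
  out2 <- classifyAllelicResponse(swapped, fdrLevel = 0.01)
  got2 <- setNames(out2$allelic_response, out2$gene_id)
  expect_identical(unname(got2["fem_only"]), "male_specific")
  expect_identical(unname(got2[c("up_both", "opposite", "flat")]),
                   unname(got[c("up_both", "opposite", "flat")]))
  expect_equal(out2$maternal_log2fc, out$paternal_log2fc)
  # with a single replicate the call degrades to none, flagged
  out3 <- classifyAllelicResponse(hap[hap$replicate == 1, ])
  expect_true(all(out3$allelic_response == "none"))
  expect_true(all(out3$insufficient_replicates))
})
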