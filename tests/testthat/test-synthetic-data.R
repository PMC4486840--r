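test_that("RI panel with zero recombination is single-ancestry per chromosome", {
  geno <- simulateRiPanel(15, data.frame(name = c("1", "2"),
                                         lengthMb = c(50, 40),
                                         nMarkers = c(10, 8)),
                          cmPerMb = 0, seed = 1)
  m <- markerInfo(geno)
  for (chr in unique(m$chr)) {
    sub <- genoCalls(geno)[, m$id[m$chr == chr], drop = FALSE]
    expect_true(all(apply(sub, 1, function(r) length(unique(r)) == 1)))
  }
})

test_that("adjacent-marker correlation vanishes in the independence limit", {
  # enormous genetic distance drives the RI switch probability to 0.5
  geno <- simulateRiPanel(10000, data.frame(name = "1", lengthMb = 100,
                                            nMarkers = 5),
                          cmPerMb = 1e6, seed = 2)
  g <- genoCalls(geno)
  for (j in 1:4) expect_lt(abs(cor(g[, j], g[, j + 1])), 0.05)
})

test_that("panel simulation is deterministic given the seed, file included", {
  spec <- data.frame(name = "1", lengthMb = 80, nMarkers = 12)
  g1 <- simulateRiPanel(20, spec, seed = 7)
  g2 <- simulateRiPanel(20, spec, seed = 7)
  expect_identical(genoCalls(g1), genoCalls(g2))
  f1 <- tempfile(); f2 <- tempfile()
  writeGenotypes(g1, f1, seed = 7)
  writeGenotypes(g2, f2, seed = 7)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero markers on a chromosome is rejected", {
  expect_error(simulateRiPanel(
    10, data.frame(name = "1", lengthMb = 50, nMarkers = 0), seed = 1),
    "at least one marker")
})

test_that("noise-free planted trait takes exactly mu +/- a", {
  geno <- simulateRiPanel(12, data.frame(name = "1", lengthMb = 50,
                                         nMarkers = 6), seed = 3)
  tr <- simulateStrainTrait(geno, "1_m0003", additive = 0.5, h2 = 1,
                            mu = 10, seed = 4)
  x <- genoCalls(geno)[, "1_m0003"]
  expect_equal(unname(traitValues(tr)),
               unname(10 + 0.5 * x[names(traitValues(tr))]))
  expect_setequal(unique(traitValues(tr)), c(9.5, 10.5))
})

test_that("residual variance follows the heritability formula", {
  # h2 = a^2 / (a^2 + sigma^2) with Var(x) = 1  =>  sigma^2 = 1 at
  # h2 = 0.5, a = 1 (closed-form oracle)
  geno <- simulateRiPanel(4000, data.frame(name = "1", lengthMb = 50,
                                           nMarkers = 4), seed = 5)
  tr <- simulateStrainTrait(geno, "1_m0002", additive = 1, h2 = 0.5,
                            mu = 3, seed = 6)
  x <- genoCalls(geno)[names(traitValues(tr)), "1_m0002"]
  resid <- traitValues(tr) - 3 - 1 * x
  expect_lt(abs(var(resid) - 1), 0.1)
})

test_that("inconsistent and degenerate trait specs are rejected or handled", {
  geno <- simulateRiPanel(12, data.frame(name = "1", lengthMb = 50,
                                         nMarkers = 4), seed = 8)
  expect_error(simulateStrainTrait(geno, "1_m0001", additive = 1, h2 = 0,
                                   seed = 1), "inconsistent")
  expect_error(simulateStrainTrait(geno, "nope", additive = 1, h2 = 0.5,
                                   seed = 1), "not present")
  # missing genotype at the planted marker drops that line
  calls <- genoCalls(geno)
  calls[1, "1_m0002"] <- NA
  geno2 <- new("GenotypeMatrix", calls = calls, markers = markerInfo(geno))
  tr <- simulateStrainTrait(geno2, "1_m0002", additive = 1, h2 = 0.9,
                            seed = 2)
  expect_equal(length(traitValues(tr)), 11)
  expect_false(rownames(calls)[1] %in% names(traitValues(tr)))
})

test_that("null GWAS p-values are uniform and LD makes neighbours agree", {
  ann <- simulateAnnotation(data.frame(chr = "1", startMb = 0, endMb = 500),
                            1250, 1, seed = 9)
  sim <- simulateGwasRegion(ann$human, snpsPerGene = 8, arCorr = 0,
                            seed = 10)
  p <- snpTable(sim$gwas)$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)

  ann2 <- simulateAnnotation(data.frame(chr = "1", startMb = 0, endMb = 200),
                             400, 1, seed = 11)
  sim2 <- simulateGwasRegion(ann2$human, snpsPerGene = 8, arCorr = 0.99,
                             seed = 12)
  p2 <- snpTable(sim2$gwas)$p
  idx <- seq_along(p2)
  adjacent <- (idx %% 8) != 0           # pairs within the same gene
  expect_gt(cor(p2[which(adjacent)], p2[which(adjacent) + 1],
                method = "spearman"), 0.9)
})

test_that("a causal gene's minimum p-value beats 1e-6 almost always", {
  ann <- simulateAnnotation(data.frame(chr = "1", startMb = 0, endMb = 1),
                            1, 1, seed = 13)
  hits <- vapply(1:40, function(i) {
    sim <- simulateGwasRegion(ann$human, snpsPerGene = 8, arCorr = 0.8,
                              causal = "HGENE0001", ncp = 6, seed = 100 + i)
    min(snpTable(sim$gwas)$p) < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("LD store from the GWAS simulator holds the AR r-squared exactly", {
  ann <- simulateAnnotation(data.frame(chr = "1", startMb = 0, endMb = 1),
                            1, 1, seed = 14)
  sim <- simulateGwasRegion(ann$human, snpsPerGene = 4, arCorr = 0.8,
                            seed = 15)
  s <- snpTable(sim$gwas)$snp
  expect_equal(ldR2(sim$ld, s[1], s[2]), 0.8^2)
  expect_equal(ldR2(sim$ld, s[1], s[4]), (0.8^3)^2)
  expect_equal(ldR2(sim$ld, s[4], s[1]), (0.8^3)^2)  # symmetric
})

test_that("non-PD LD requests and bad rates are rejected", {
  ann <- simulateAnnotation(data.frame(chr = "1", startMb = 0, endMb = 1),
                            1, 1, seed = 16)
  expect_error(simulateGwasRegion(ann$human, arCorr = 1, seed = 1))
  expect_error(simulateAnnotation(
    data.frame(chr = "1", startMb = 0, endMb = 1), 2, 1.5, seed = 1))
})

test_that("homolog rate 1 and 0 bracket the homolog count", {
  r <- data.frame(chr = "1", startMb = 10, endMb = 20)
  a1 <- simulateAnnotation(r, 12, 1, seed = 17)
  expect_equal(length(a1$homology@mouse), 12)
  region <- makeRegion("1", 10, 20)
  expect_equal(homologsInRegion(region, a1$mouse, a1$homology)@n, 12)
  a0 <- simulateAnnotation(r, 12, 0, seed = 18)
  expect_equal(homologsInRegion(region, a0$mouse, a0$homology)@n, 0)
  # genes that cannot be tiled without overlap are rejected
  expect_error(simulateAnnotation(
    data.frame(chr = "1", startMb = 0, endMb = 1e-5), 100, 1, seed = 1),
    "too small")
})

test_that("expression modules have the planted correlation structure", {
  # zero noise: probes of one module are perfectly correlated
  ex0 <- simulateExpression(c(a = "M", b = "M"), geneNoiseSd = 0,
                            probeNoiseSd = 0, nStrains = 10,
                            probesPerGene = 2, seed = 19)
  r0 <- corValues(correlationMatrix(
    SummarizedExperiment::assay(ex0$expr, "exprs")))
  expect_true(all(abs(r0 - 1) < 1e-12))

  # independent factors: cross-module mean |r| near 0
  ex1 <- simulateExpression(setNames(as.character(1:20), paste0("g", 1:20)),
                            geneNoiseSd = 0.1, probeNoiseSd = 0.1,
                            nStrains = 200, probesPerGene = 1, seed = 20)
  r1 <- corValues(correlationMatrix(
    SummarizedExperiment::assay(ex1$expr, "exprs")))
  expect_lt(mean(abs(r1[upper.tri(r1)])), 0.1)

  # variance-decomposition oracle: loading 1, Var(factor) 1, total residual
  # variance 1 => expected cross-gene probe r = 1 / (1 + 1) = 0.5
  ex2 <- simulateExpression(setNames(rep("M", 10), paste0("g", 1:10)),
                            geneNoiseSd = sqrt(0.5), probeNoiseSd = sqrt(0.5),
                            nStrains = 500, probesPerGene = 1, seed = 21)
  r2 <- corValues(correlationMatrix(
    SummarizedExperiment::assay(ex2$expr, "exprs")))
  expect_lt(abs(mean(r2[upper.tri(r2)]) - 0.5), 0.05)

  expect_error(simulateExpression(c(a = "M"), nStrains = 2, seed = 1),
               ">= 3")
})

test_that("condition up-calls use the two-fold threshold", {
  ex <- simulateExpression(c(a = "M", b = "M", c = "N"), nStrains = 5,
                           nConditions = 200, seed = 22)
  expect_true(is.logical(ex$conditions))
  expect_equal(dim(ex$conditions), c(3, 200))
  # same-module genes co-up more often than cross-module genes
  joint_in <- mean(ex$conditions["a", ] & ex$conditions["b", ])
  joint_out <- mean(ex$conditions["a", ] & ex$conditions["c", ])
  expect_gt(joint_in, joint_out)
})
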