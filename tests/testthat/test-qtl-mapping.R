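test_that("LRS matches the hand-computed two-group example", {
  # genotypes B,B,D,D with trait 0,1,1,2: RSS0 = 2, RSS1 = 1,
  # LRS = 4 ln 2; additive = (1.5 - 0.5) / 2 = +0.5
  e <- crossqtl:::.lrsEngine(matrix(c(-1L, -1L, 1L, 1L), ncol = 1),
                             matrix(c(0, 1, 1, 2), ncol = 1))
  expect_equal(e$lrs[1, 1], 4 * log(2), tolerance = 1e-12)
  expect_equal(e$additive[1, 1], 0.5, tolerance = 1e-12)
})

test_that("scan agrees with an independent lm-based oracle", {
  set.seed(41)
  for (rep in 1:5) {
    calls <- matrix(sample(c(-1L, 1L), 10 * 6, replace = TRUE), 10, 6)
    calls[sample(60, 4)] <- NA
    geno <- makeGeno(calls)
    y <- rnorm(10)
    tr <- makeTrait(y, strainNames(geno))
    tab <- scanTable(lrsScan(geno, tr))
    for (j in 1:6) {
      x <- calls[, j]
      ok <- !is.na(x)
      if (length(unique(x[ok])) < 2) {
        expect_true(is.na(tab$lrs[j]))
        next
      }
      fit1 <- lm(y[ok] ~ x[ok])
      rss1 <- sum(residuals(fit1)^2)
      rss0 <- sum(residuals(lm(y[ok] ~ 1))^2)
      expect_equal(tab$lrs[j], sum(ok) * log(rss0 / rss1),
                   tolerance = 1e-10)
      expect_equal(tab$additive[j],
                   unname(coef(fit1)[2]), tolerance = 1e-10)
    }
  }
})

test_that("LRS is affine-invariant; the additive coefficient rescales", {
  geno <- simulateRiPanel(30, data.frame(name = "1", lengthMb = 60,
                                         nMarkers = 10), seed = 42)
  tr <- simulateStrainTrait(geno, "1_m0005", additive = 1, h2 = 0.6,
                            seed = 43)
  t2 <- makeTrait(3 * traitValues(tr) + 100, id = "scaled")
  s1 <- scanTable(lrsScan(geno, tr))
  s2 <- scanTable(lrsScan(geno, t2))
  expect_equal(s2$lrs, s1$lrs, tolerance = 1e-10)
  expect_equal(s2$additive, 3 * s1$additive, tolerance = 1e-10)
})

test_that("negative additive coefficient means the B allele raises the trait", {
  calls <- matrix(rep(c(-1L, 1L), each = 4), ncol = 1)
  geno <- makeGeno(cbind(calls, calls[8:1]))
  y <- c(5, 5, 5, 5, 1, 1, 1, 1)      # B-class mean > D-class mean
  tab <- scanTable(lrsScan(geno, makeTrait(y, rownames(genoCalls(geno)))))
  expect_lt(tab$additive[1], 0)
})

test_that("degenerate scans are handled: zero variance, few strains", {
  geno <- simulateRiPanel(10, data.frame(name = "1", lengthMb = 50,
                                         nMarkers = 5), seed = 44)
  expect_warning(sc <- lrsScan(geno, makeTrait(rep(1, 10),
                                               strainNames(geno))),
                 "zero variance")
  expect_true(all(scanTable(sc)$lrs == 0))
  tr <- makeTrait(rnorm(5), strainNames(geno)[1:5])
  expect_error(lrsScan(geno, tr), ">= 8 strains")
})

test_that("threshold is the stated order statistic and is monotone in alpha", {
  expect_equal(thresholdFromMaxima(1:20, 0.05), 19)
  expect_equal(thresholdFromMaxima(1:20, 0.5), 10)
  maxima <- runif(500)
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  th <- vapply(alphas, thresholdFromMaxima, numeric(1), maxima = maxima)
  expect_true(all(diff(th) >= 0))     # non-decreasing in 1 - alpha
})

test_that("permutation thresholds are reproducible and used strictly", {
  geno <- simulateRiPanel(20, data.frame(name = "1", lengthMb = 50,
                                         nMarkers = 8), seed = 45)
  tr <- simulateStrainTrait(geno, "1_m0004", additive = 1, h2 = 0.4,
                            seed = 46)
  t1 <- permutationThreshold(geno, tr, nPerm = 200, seed = 9)
  t2 <- permutationThreshold(geno, tr, nPerm = 200, seed = 9)
  expect_identical(thresholdLrs(t1), thresholdLrs(t2))
  expect_identical(t1@maxima, t2@maxima)
  expect_error(permutationThreshold(geno, makeTrait(rep(1, 20),
                                                    strainNames(geno)),
                                    nPerm = 200, seed = 1),
               "two distinct")
  # strict inequality: a scan sitting exactly at the threshold is not called
  sc <- makeScan(c(1, 2, 3))
  expect_length(significantIntervals(sc, 3), 0)
})

test_that("interval extraction splits or merges runs by the marker gap", {
  lrs <- c(9, 9, 1, 1, 9)             # hi hi lo lo hi
  sc <- makeScan(lrs)
  r1 <- significantIntervals(sc, 5, maxGapMarkers = 1)
  expect_length(r1, 2)                # gap of 2 > 1: separate regions
  expect_length(subRegions(r1[[1]]), 0)

  r2 <- significantIntervals(sc, 5, maxGapMarkers = 2)
  expect_length(r2, 1)                # merged parent with two sub-regions
  expect_length(subRegions(r2[[1]]), 2)
  expect_equal(r2[[1]]@startMb, 10)
  expect_equal(r2[[1]]@endMb, 50)
  expect_equal(subRegions(r2[[1]])[[1]]@endMb, 20)
  expect_equal(subRegions(r2[[1]])[[2]]@startMb, 50)

  expect_length(significantIntervals(makeScan(c(1, 2, 1)), 5), 0)
})

test_that("consensus regions union-merge across traits and count support", {
  a <- makeRegion("1", 10, 20, id = "tA")
  b <- makeRegion("1", 15, 30, id = "tB")
  cons <- consensusRegions(list(list(a), list(b)))
  expect_length(cons, 1)
  expect_equal(c(cons[[1]]@startMb, cons[[1]]@endMb), c(10, 30))
  expect_equal(cons[[1]]@support, 2L)

  d <- makeRegion("1", 40, 50, id = "tB")
  cons2 <- consensusRegions(list(list(a), list(d)))
  expect_length(cons2, 2)

  seven <- lapply(sprintf("t%d", 1:7), function(id)
    list(makeRegion("1", 156.2, 175.3, id = id)))
  cons7 <- consensusRegions(seven)
  expect_length(cons7, 1)
  expect_equal(cons7[[1]]@support, 7L)
})

test_that("trait filtering keeps exactly the traits with a significant marker", {
  trs <- list(makeTrait(rnorm(10), sprintf("S%02d", 1:10), id = "a"),
              makeTrait(rnorm(10), sprintf("S%02d", 1:10), id = "b"))
  scans <- list(makeScan(c(1, 8, 2)), makeScan(c(1, 2, 3)))
  expect_equal(filterTraits(trs, scans, list(5, 5)), trs[1])
  expect_equal(filterTraits(list(), list(), list()), list())
})

test_that("planted QTL are recovered with the peak at the planted marker", {
  geno <- simulateRiPanel(75, data.frame(name = "1", lengthMb = 100,
                                         nMarkers = 40), seed = 47)
  tr <- simulateStrainTrait(geno, "1_m0020", additive = 1, h2 = 0.5,
                            seed = 48)
  sc <- lrsScan(geno, tr)
  th <- permutationThreshold(geno, tr, nPerm = 200, seed = 49)
  regs <- significantIntervals(sc, th)
  expect_gte(length(regs), 1)
  spans <- vapply(regs, function(r)
    r@startMb <= 48.75 && r@endMb >= 48.75, logical(1))
  expect_true(any(spans))             # planted marker at 48.75 Mb covered
})
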