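test_that("correlation matrices match direct-sum Pearson computation", {
  x <- c(0, 1, 2); y <- c(0, 2, 1)
  cr <- correlationMatrix(rbind(a = x, b = y))
  expect_equal(cr@r["a", "b"], 0.5, tolerance = 1e-12)
  # brute-force oracle from the definition
  set.seed(60)
  m <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("i", 1:5), NULL))
  cr2 <- correlationMatrix(m)
  for (i in 1:4) for (j in (i + 1):5) {
    xi <- m[i, ]; xj <- m[j, ]
    num <- sum((xi - mean(xi)) * (xj - mean(xj)))
    den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(cr2@r[i, j], num / den, tolerance = 1e-12)
    expect_equal(cr2@p[i, j], cor.test(xi, xj)$p.value, tolerance = 1e-10)
  }
  expect_equal(unname(diag(cr2@r)), rep(1, 5))
  expect_equal(cr2@r, t(cr2@r))
  # perfect correlation and anti-correlation
  cr3 <- correlationMatrix(rbind(x, x, -x))
  expect_equal(cr3@r[1, 2], 1)
  expect_equal(cr3@r[1, 3], -1)
})

test_that("correlation handles missing values pairwise and flags zero variance", {
  m <- rbind(a = c(1, 2, 3, 4, NA), b = c(2, 1, 4, NA, 5),
             c = c(1, 3, 2, 5, 4))
  cr <- correlationMatrix(m)
  expect_equal(cr@n["a", "b"], 3)
  expect_equal(cr@n["a", "c"], 4)
  expect_warning(crz <- correlationMatrix(rbind(k = rep(1, 4),
                                                l = c(1, 2, 3, 4))),
                 "zero-variance")
  expect_true(is.na(crz@r["k", "l"]))
  expect_error(correlationMatrix(rbind(c(1, 2, NA, NA), c(NA, NA, 1, 2))),
               "at least 3 samples")
})

test_that("coexpression calls combine the r and adjusted-p gates", {
  expect_equal(coexpressionCalls(correlationMatrix(matrix(rnorm(9), 3)),
                                 nProbes = 63)@adjustedAlpha,
               0.05 / 63)
  # conjunction: strong r with weak p (tiny n) is not called
  set.seed(61)
  z <- rnorm(4)
  m <- rbind(a = z, b = z + rnorm(4, 0, 0.8))
  cr <- correlationMatrix(m)
  cc <- coexpressionCalls(cr, nProbes = 10)
  if (abs(cr@r["a", "b"]) >= 0.5 && cr@p["a", "b"] > 0.005)
    expect_false(cc@calls["a", "b"])
  # strong r with strong p is called
  n <- 40
  z2 <- rnorm(n)
  m2 <- rbind(a = z2, b = z2 + rnorm(n, 0, 0.5), c = rnorm(n))
  cc2 <- coexpressionCalls(correlationMatrix(m2), nProbes = 3)
  expect_true(cc2@calls["a", "b"])
  expect_false(cc2@calls["a", "c"])
  expect_false(any(diag(cc2@calls)))
})

test_that("probe consistency screen keeps correlated siblings only", {
  set.seed(62)
  z <- rnorm(30)
  m <- rbind(g_p01 = z + rnorm(30, 0, 0.2),
             g_p02 = z + rnorm(30, 0, 0.2),
             g_p03 = rnorm(30))
  rd <- S4Vectors::DataFrame(gene_id = rep("g", 3),
                             region_type = rep("exon", 3),
                             row.names = rownames(m))
  colnames(m) <- sprintf("S%02d", 1:30)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), rowData = rd)
  expect_equal(consistentProbes(se, "g"), c("g_p01", "g_p02"))

  se1 <- se[1, ]
  expect_message(kept <- consistentProbes(se1, "g"), "single probe")
  expect_equal(kept, "g_p01")
})

test_that("phenotype screen demands every probe agree, with one sign", {
  set.seed(63)
  z <- rnorm(25)
  probes <- rbind(p1 = z + rnorm(25, 0, 0.2), p2 = z + rnorm(25, 0, 0.2))
  phen <- rbind(both = z + rnorm(25, 0, 0.3),
                onlyp1 = probes["p1", ] - z + rnorm(25, 0, 0.1),
                neg = -z + rnorm(25, 0, 0.3))
  keep <- phenotypeScreen(probes, phen)
  expect_true("both" %in% keep)
  expect_true("neg" %in% keep)          # consistent negative sign is fine
  expect_false("onlyp1" %in% keep)
  # mixed signs against different probes are dropped
  mix <- rbind(flip = c(probes["p1", 1:12], -probes["p2", 13:25]))
  probesFlip <- rbind(p1 = probes["p1", ], p2 = -probes["p2", ])
  keep2 <- phenotypeScreen(probesFlip, phen["both", , drop = FALSE])
  expect_length(keep2, 0)
})

test_that("conditional coexpression equals the joint-up fraction", {
  conds <- matrix(FALSE, 3, 20,
                  dimnames = list(c("target", "g5", "gnever"), NULL))
  conds["target", 1:10] <- TRUE
  conds["g5", c(1:5, 15, 16)] <- TRUE   # 5 of the target's 10 up-conditions
  cc <- conditionalCoexpression(conds, "target")
  expect_equal(cc$value[cc$gene == "g5"], 0.5)
  expect_equal(cc$joint_up[cc$gene == "g5"], 5)
  expect_equal(cc$value[cc$gene == "gnever"], 0)

  conds["gnever", ] <- conds["target", ]   # exactly the target's conditions
  cc2 <- conditionalCoexpression(conds, "target")
  expect_equal(cc2$value[cc2$gene == "gnever"], 1)
  expect_true(cc2$common[cc2$gene == "gnever"])

  off <- matrix(FALSE, 2, 4, dimnames = list(c("t", "g"), NULL))
  expect_error(conditionalCoexpression(off, "t"), "never up-regulated")
})

test_that("conditional coexpression is invariant to up-call-preserving rescaling", {
  set.seed(64)
  conds <- matrix(runif(5 * 40) < 0.3, 5, 40,
                  dimnames = list(paste0("g", 1:5), NULL))
  conds[1, 1:8] <- TRUE
  a <- conditionalCoexpression(conds, "g1")
  b <- conditionalCoexpression(conds * 7L, "g1")   # any positive coding
  expect_equal(a, b)
})

test_that("ORA reproduces the enumerated hypergeometric tail", {
  universe <- paste0("u", 1:10)
  term <- universe[1:5]
  lst <- universe[1:4]
  res <- oraEnrichment(lst, list(T1 = term), universe)
  # brute-force oracle: enumerate all 4-subsets of the universe
  combos <- combn(10, 4)
  tail <- mean(apply(combos, 2, function(ix) sum(ix <= 5) >= 4))
  expect_equal(res$p, tail, tolerance = 1e-12)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$q, res$p)                       # single term: q = p

  res2 <- oraEnrichment(lst, list(comp = universe[5:10]), universe)
  expect_equal(res2$p, 1, tolerance = 1e-12)       # overlap can't be beaten
  expect_error(oraEnrichment(character(0), list(T1 = term), universe),
               "empty")
  expect_error(oraEnrichment("zzz", list(T1 = term), universe), "subset")

  # BH ordering: q monotone in p order, q >= p, q <= 1
  set.seed(65)
  terms <- lapply(1:8, function(i) sample(universe, sample(3:7, 1)))
  names(terms) <- paste0("T", 1:8)
  res3 <- oraEnrichment(lst, terms, universe)
  expect_true(all(res3$q >= res3$p - 1e-15))
  expect_true(all(res3$q <= 1))
  expect_equal(res3$q, p.adjust(res3$p, "BH")[order(order(res3$q, res3$p))],
               tolerance = 1e-12)
})

test_that("PC1 synthetic traits obey the two-trait closed form", {
  set.seed(66)
  z <- rnorm(20)
  perfect <- cbind(z, 2 * z + 3)
  expect_equal(pc1Trait(perfect)$varianceFraction, 1, tolerance = 1e-12)
  for (i in 1:5) {
    m <- matrix(rnorm(40), 20, 2)
    r <- cor(m[, 1], m[, 2])
    expect_equal(pc1Trait(m)$varianceFraction, (1 + abs(r)) / 2,
                 tolerance = 1e-12)
    # sign flip leaves the fraction unchanged and the loading sum >= 0
    res <- pc1Trait(-m)
    expect_equal(res$varianceFraction, (1 + abs(r)) / 2, tolerance = 1e-12)
    expect_gte(sum(res$loadings), 0)
    expect_equal(sum(res$loadings^2), 1, tolerance = 1e-12)
  }
  expect_error(pc1Trait(cbind(z, rep(1, 20))), "constant")
})
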