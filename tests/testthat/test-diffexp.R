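test_that("log2 fold change arithmetic", {
  expect_equal(log2FoldChange(20, 40), 1.0)
  expect_equal(log2FoldChange(0.01, 10.24), 10.0)
  expect_equal(log2FoldChange(3.7, 3.7), 0.0)
  expect_error(log2FoldChange(0, 5), "non-positive")
  # antisymmetry
  expect_equal(log2FoldChange(5, 80), -log2FoldChange(80, 5))
})

test_that("chi-square statistic matches the closed form and chisq.test", {
  r <- chisqDE(20, 1e6, 40, 1e6)
  expect_equal(r$chi2, 6.66687, tolerance = 1e-5)
  expect_equal(r$p, 0.00982, tolerance = 1e-3)
  expect_true(r$tested)
  set.seed(99)
  for (i in 1:100) {
    ta <- sample(1e4:1e6, 1); tb <- sample(1e4:1e6, 1)
    a <- sample(0:200, 1); b <- sample(0:200, 1)
    mine <- chisqDE(a, ta, b, tb)
    # closed form, computed independently
    tab <- matrix(c(a, ta - a, b, tb - b), nrow = 2, byrow = TRUE)
    N <- sum(tab)
    num <- tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]
    den <- prod(rowSums(tab)) * prod(colSums(tab))
    closed <- if (den > 0) N * num^2 / den else 0
    expect_equal(mine$chi2, closed, tolerance = 1e-9)
    if (a + b > 0) {
      ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-8)
    }
  }
})

test_that("testing gate, symmetry and degenerate tables", {
  expect_false(chisqDE(5, 1e6, 8, 1e6)$tested)
  expect_true(chisqDE(5, 1e6, 11, 1e6)$tested)
  eq <- chisqDE(30, 1e6, 30, 1e6)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  # symmetric under swapping libraries
  expect_equal(chisqDE(17, 2e6, 90, 3e6)$chi2,
               chisqDE(90, 3e6, 17, 2e6)$chi2)
  expect_error(chisqDE(10, 5, 1, 10), "exceeds")
})

test_that("Jaccard index point estimates and bootstrap CI", {
  j <- jaccardIndex(c("a", "b", "c"), c("b", "c", "d"), nBoot = 200)
  expect_equal(j$point, 0.5)
  same <- jaccardIndex(letters[1:5], letters[1:5], nBoot = 200)
  expect_equal(same$point, 1)
  expect_equal(c(same$ciLow, same$ciHigh), c(1, 1))
  expect_equal(jaccardIndex(c("a"), c("b"), nBoot = 50)$point, 0)
  expect_error(jaccardIndex(character(0), character(0)), "empty")
  # same seed reproduces the CI
  j1 <- jaccardIndex(letters[1:10], letters[5:15], nBoot = 300, seed = 4)
  j2 <- jaccardIndex(letters[1:10], letters[5:15], nBoot = 300, seed = 4)
  expect_identical(j1, j2)
})

test_that("bootstrap CI width shrinks with set size", {
  mk <- function(n) paste0("u", seq_len(n))
  small <- jaccardIndex(mk(20), paste0("u", 11:30), nBoot = 500, seed = 2)
  big <- jaccardIndex(mk(200), paste0("u", 101:300), nBoot = 500, seed = 2)
  expect_lt(big$ciHigh - big$ciLow, small$ciHigh - small$ciLow)
})

test_that("library clustering uses 1 - Pearson r with average linkage", {
  set.seed(5)
  base <- matrix(rpois(60, 50) + 1L, nrow = 20)
  raw <- cbind(A = base[, 1], B = base[, 2], C = base[, 1],  # C == A
               D = base[, 3])
  rownames(raw) <- paste0("u", 1:20)
  x <- normalizeRpm(mirExperiment(raw))
  hc <- clusterLibraries(x)
  merged <- cutree(hc, h = 1e-10)
  expect_equal(merged[["A"]], merged[["C"]])  # identical -> distance 0
  # doubling all counts of a library shifts log2 rpm, correlation unchanged
  raw2 <- raw; raw2[, "D"] <- raw[, "A"] * 2L
  x2 <- normalizeRpm(mirExperiment(raw2, cleanedTotal = colSums(raw2)))
  hc2 <- clusterLibraries(x2)
  expect_equal(cutree(hc2, h = 1e-10)[["A"]], cutree(hc2, h = 1e-10)[["D"]])
  # constant profile errors with the library named
  raw3 <- raw; raw3[, "B"] <- 7L
  x3 <- normalizeRpm(mirExperiment(raw3))
  expect_error(clusterLibraries(x3), "B")
})

test_that("libraries cluster by growing condition when it dominates", {
  set.seed(8)
  nU <- 40
  mu <- rnorm(nU, 8, 1.5)
  cond <- c(FD = 0, GH = 3)
  popEff <- c(Deh = 0, Mun = 0.15, Chit = 0.3)
  libs <- expand.grid(pop = names(popEff), cond = names(cond),
                      stringsAsFactors = FALSE)
  raw <- sapply(seq_len(nrow(libs)), function(k) {
    y <- mu + ifelse(seq_len(nU) <= 20, cond[libs$cond[k]], 0) +
      popEff[libs$pop[k]] + rnorm(nU, 0, 0.1)
    as.integer(round(2^y))
  })
  colnames(raw) <- paste(libs$pop, libs$cond, sep = "_")
  rownames(raw) <- paste0("u", seq_len(nU))
  x <- normalizeRpm(mirExperiment(raw))
  hc <- clusterLibraries(x)
  groups <- cutree(hc, k = 2)
  condOf <- sub(".*_", "", names(groups))
  expect_equal(length(unique(groups[condOf == "FD"])), 1L)
  expect_equal(length(unique(groups[condOf == "GH"])), 1L)
  expect_true(groups[condOf == "FD"][1] != groups[condOf == "GH"][1])
  # Newick export round-trips through ape
  nwk <- dendrogramNewick(hc)
  expect_equal(sort(ape::read.tree(text = nwk)$tip.label),
               sort(colnames(raw)))
})

test_that("two-way ANOVA matches a hand-computed balanced oracle", {
  set.seed(12)
  design <- expand.grid(rep = 1:3, population = c("P1", "P2", "P3"),
                        condition = c("FD", "GH"),
                        stringsAsFactors = FALSE)
  design$library <- sprintf("L%02d", seq_len(nrow(design)))
  raw <- matrix(rpois(2 * nrow(design), 300) + 1L, nrow = 2,
                dimnames = list(c("u1", "u2"), design$library))
  x <- normalizeRpm(mirExperiment(raw))
  res <- anovaPopTmt(x, design)
  # balanced two-way ANOVA from scratch
  y <- log2(rpm(x)["u1", ])
  A <- factor(design$population); B <- factor(design$condition)
  gm <- mean(y)
  ssA <- sum(tapply(y, A, length) * (tapply(y, A, mean) - gm)^2)
  ssB <- sum(tapply(y, B, length) * (tapply(y, B, mean) - gm)^2)
  cellMean <- tapply(y, list(A, B), mean)
  ssAB <- sum(3 * (sweep(sweep(cellMean, 1, tapply(y, A, mean)), 2,
                         tapply(y, B, mean)) + gm)^2)
  ssE <- sum((y - cellMean[cbind(A, B)])^2)
  dfE <- length(y) - nlevels(A) * nlevels(B)
  Fpop <- (ssA / (nlevels(A) - 1)) / (ssE / dfE)
  Ftmt <- (ssB / (nlevels(B) - 1)) / (ssE / dfE)
  Fint <- (ssAB / ((nlevels(A) - 1) * (nlevels(B) - 1))) / (ssE / dfE)
  expect_equal(res$F_pop[1], Fpop, tolerance = 1e-8)
  expect_equal(res$F_tmt[1], Ftmt, tolerance = 1e-8)
  expect_equal(res$F_int[1], Fint, tolerance = 1e-8)
  expect_equal(res$p_pop[1], pf(Fpop, 2, dfE, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("ANOVA detects planted population effects and respects symmetry", {
  set.seed(13)
  design <- expand.grid(rep = 1:3, population = c("P1", "P2"),
                        condition = c("FD", "GH"),
                        stringsAsFactors = FALSE)
  design$library <- sprintf("L%02d", seq_len(nrow(design)))
  nU <- 30
  y <- matrix(rnorm(nU * nrow(design), 8, 0.25), nrow = nU)
  y[1, design$population == "P2"] <- y[1, design$population == "P2"] + 1 # 4 sd
  raw <- matrix(as.integer(round(2^y)), nrow = nU,
                dimnames = list(paste0("u", 1:nU), design$library))
  x <- normalizeRpm(mirExperiment(raw))
  res <- anovaPopTmt(x, design)
  expect_lt(res$p_pop[1], 0.01)
  # null units: condition p-values behave like a uniform sample
  expect_lt(mean(res$p_tmt[-1] < 0.05), 0.25)
  expect_gt(mean(res$p_tmt[-1] > 0.2), 0.4)
  # swapping the factor labels swaps the p-values
  d2 <- design; d2$population <- design$condition
  d2$condition <- design$population
  res2 <- anovaPopTmt(x, d2)
  expect_equal(res2$p_pop, res$p_tmt, tolerance = 1e-10)
  expect_equal(res2$p_tmt, res$p_pop, tolerance = 1e-10)
  # all-equal responses: p = 1 by convention
  rawc <- matrix(8L, nrow = 1, ncol = nrow(design),
                 dimnames = list("flat", design$library))
  xc <- normalizeRpm(mirExperiment(rawc))
  resc <- anovaPopTmt(xc, design)
  expect_equal(resc$p_pop, 1)
  expect_equal(resc$p_tmt, 1)
})

test_that("monotone-altitude rule needs the same significant direction twice", {
  de1 <- data.frame(unit = c("a", "b", "c", "d"),
                    log2fc = c(2, 2, -2, 0.2),
                    p = c(0.01, 0.01, 0.01, 0.01),
                    tested = TRUE)
  de2 <- data.frame(unit = c("a", "b", "c", "d"),
                    log2fc = c(2, -2, -2, 0.2),
                    p = c(0.01, 0.01, 0.01, 0.01),
                    tested = TRUE)
  mono <- altitudeMonotoneUnits(de1, de2)
  expect_equal(mono$increasing, "a")
  expect_equal(mono$decreasing, "c")
})
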