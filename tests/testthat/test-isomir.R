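toy <- makeToyAnnotation()
hpA <- toy$hpA
s5 <- 7L; e5 <- 27L   # 5p mature span on hpA

cls <- function(tag) classifyIsomiR(tag, hpA, s5, e5)

test_that("each isomiR category is recognized from its defining variation", {
  expect_equal(cls(toy$m5)$category, "canonical")

  sh <- cls(substring(hpA, s5 + 1L, e5 + 1L))
  expect_equal(sh$category, "shifted")
  expect_equal(c(sh$offset5, sh$offset3), c(1L, 1L))

  ta <- cls(substring(hpA, s5, e5 + 1L))
  expect_equal(ta$category, "template_3p")
  expect_equal(ta$offset3, 1L)
  # 3' deletion is also a template variant
  expect_equal(cls(substring(hpA, s5, e5 - 2L))$category, "template_3p")

  ss <- cls(substring(hpA, s5 - 1L, e5))
  expect_equal(ss$category, "start_site")
  expect_equal(ss$offset5, -1L)

  expect_equal(cls(substring(hpA, s5 - 1L, e5 + 2L))$category, "both_end")

  cont <- substring(hpA, e5 + 1L, e5 + 1L)      # template continuation
  ntaBase <- setdiff(c("A", "C", "G", "T"), cont)[1]
  nta <- cls(paste0(toy$m5, ntaBase))
  expect_equal(nta$category, "nontemplate_3p")
  expect_equal(nta$tail, chartr("T", "U", ntaBase))
  expect_equal(nta$offset5, 0L)

  v <- toy$m5
  substring(v, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substring(v, 10, 10))[1]
  sub <- cls(v)
  expect_equal(sub$category, "substitution")
  expect_equal(sub$mismatches, 10L)

  # a length-preserving final-base mismatch is a non-templated tail
  w <- toy$m5
  substring(w, 21, 21) <- setdiff(c("A", "C", "G", "T"),
                                  substring(w, 21, 21))[1]
  expect_equal(cls(w)$category, "nontemplate_3p")

  expect_error(classifyIsomiR(strrep("A", 17), hpA, s5, e5), "size filter")
})

test_that("classifier agrees with the brute-force oracle on enumerations", {
  set.seed(21)
  for (rep in 1:4) {
    hp <- makePerfectHairpin(paste(sample(c("A", "C", "G", "T"), 21, TRUE),
                                   collapse = ""))
    tags <- enumerateIsomirTags(hp$seq, hp$matureSpan[1], hp$matureSpan[2])
    for (tg in tags) {
      a <- classifyIsomiR(tg, hp$seq, hp$matureSpan[1], hp$matureSpan[2])
      b <- oracleClassifyIsomiR(tg, hp$seq, hp$matureSpan[1],
                                hp$matureSpan[2])
      expect_identical(a[c("category", "offset5", "offset3", "tail")],
                       b[c("category", "offset5", "offset3", "tail")])
    }
  }
})

test_that("enlarging the window only rescues unassigned tags", {
  set.seed(22)
  hp <- makePerfectHairpin(paste(sample(c("A", "C", "G", "T"), 21, TRUE),
                                 collapse = ""), ext = "ACGTACGT",
                           loop = "GAATTCGGCA")
  tags <- enumerateIsomirTags(hp$seq, hp$matureSpan[1], hp$matureSpan[2],
                              window = 8L)
  for (tg in tags) {
    small <- classifyIsomiR(tg, hp$seq, hp$matureSpan[1], hp$matureSpan[2],
                            window = 3L)
    large <- classifyIsomiR(tg, hp$seq, hp$matureSpan[1], hp$matureSpan[2],
                            window = 8L)
    if (small$category != "unassigned")
      expect_identical(small$category, large$category)
  }
})

test_that("tags assign to one mature each and summaries are exhaustive", {
  tags <- S4Vectors::DataFrame(sequence = c(
    toy$m5,                                  # canonical
    paste0(toy$m5, "A"),                     # NTA (continuation is G)
    substring(hpA, s5, e5 + 1L),             # template_3p
    toy$mB))                                 # canonical of hpB
  tags$counts <- matrix(c(80L, 15L, 5L, 30L), ncol = 1,
                        dimnames = list(NULL, "L1"))
  asg <- assignIsomiRs(tags, toy$index)
  expect_equal(nrow(asg), 4L)
  expect_equal(sort(unique(asg$mature)),
               c("ath-miR501a-5p", "ath-miR502a"))
  s <- isomirSummary(asg, "L1")
  props <- as.matrix(s[, grep("^prop_", names(s))])
  expect_equal(unname(rowSums(props)), rep(1, nrow(s)))
  r1 <- s[s$mature == "ath-miR501a-5p", ]
  expect_equal(r1$total, 100L)
  expect_equal(r1$prop_canonical, 0.8)
  expect_equal(r1$dominance, 0.8)
  expect_equal(r1$n_distinct, 3L)
  expect_gte(r1$dominance, 1 / r1$n_distinct)
  r2 <- s[s$mature == "ath-miR502a", ]
  expect_equal(r2$dominance, 1.0)
  # dominance is scale invariant
  tags2 <- tags; tags2$counts <- tags$counts * 10L
  s2 <- isomirSummary(assignIsomiRs(tags2, toy$index), "L1")
  expect_equal(s2$dominance, s$dominance)
})

test_that("NTA base composition is expression-weighted over A, C, G, U", {
  cont <- substring(hpA, e5 + 1L, e5 + 1L)
  stopifnot(cont == "G")  # toy hairpin pins the continuation to G
  tags <- S4Vectors::DataFrame(sequence = c(paste0(toy$m5, "A"),
                                            paste0(toy$m5, "C"),
                                            paste0(toy$m5, "T")))
  tags$counts <- matrix(c(32L, 30L, 38L), ncol = 1,
                        dimnames = list(NULL, "L1"))
  asg <- assignIsomiRs(tags, toy$index)
  comp <- ntaBaseComposition(asg, "L1")
  expect_equal(unname(comp), c(0.32, 0.30, 0, 0.38))
  expect_equal(sum(comp), 1)
  one <- tags[3, ]
  compU <- ntaBaseComposition(assignIsomiRs(one, toy$index), "L1")
  expect_equal(unname(compU["U"]), 1.0)
  empty <- assignIsomiRs(tags[0, ], toy$index)
  expect_warning(res <- ntaBaseComposition(empty, "L1"), "no 3' NTA")
  expect_length(res, 0)
})

test_that("arm usage ratios and binomial significance", {
  raw <- matrix(c(160L, 10L,
                  50L, 50L,
                  16384L, 1L,
                  100L, 0L),
                ncol = 4,
                dimnames = list(c("ath-miR501a-5p", "ath-miR501a-3p"),
                                c("L1", "L2", "L3", "L4")))
  raw <- rbind(raw, "ath-miR502a" = 0L)
  x <- normalizeRpm(mirExperiment(raw, cleanedTotal = rep(1e6, 4)))
  u <- armUsage(x, toy$index, "ath-MIR501a", "L1")
  expect_equal(u$log2Ratio, 4.0)
  u2 <- armUsage(x, toy$index, "ath-MIR501a", "L2")
  expect_equal(u2$log2Ratio, 0)
  expect_equal(u2$p, 1)
  expect_equal(armUsage(x, toy$index, "ath-MIR501a", "L3")$log2Ratio, 14)
  # zero count guarded by the 0.01-rpm convention
  u4 <- armUsage(x, toy$index, "ath-MIR501a", "L4")
  expect_equal(u4$log2Ratio, log2((100 / 1e6 * 1e6) / 0.01))
  expect_error(armUsage(x, toy$index, "ath-MIR502a", "L1"), "lacks")
  tab <- armUsageTable(x, toy$index, libraries = c("L1", "L2", "L3"))
  expect_equal(nrow(tab), 3L)
  tab4 <- armUsageTable(x, toy$index)
  expect_equal(nrow(tab4), 0L)  # L4 lacks 3p expression
})
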