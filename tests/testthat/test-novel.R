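rc <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))

test_that("candidate loci respect the abundance floor and merge overlaps", {
  set.seed(31)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  tagA <- substring(bg, 501, 521)
  tagB <- substring(bg, 510, 530)   # overlaps tagA
  tagC <- substring(bg, 1501, 1521)
  genome <- Biostrings::DNAStringSet(c(chr1 = bg))
  tags <- S4Vectors::DataFrame(sequence = c(tagA, tagB, tagC))
  tags$counts <- matrix(c(12L, 25L, 9L), ncol = 1,
                        dimnames = list(NULL, "L"))
  loci <- candidateLoci(tags, genome, flank = 100L)
  # tagC (count 9) excluded; tagA+tagB merged, led by tagB
  expect_equal(length(loci), 1L)
  expect_equal(S4Vectors::mcols(loci)$matureSeq, tagB)
  expect_equal(S4Vectors::mcols(loci)$count, 25)
  # window = tag +/- flank
  expect_equal(GenomicRanges::width(loci), 21L + 200L)
  # a solitary count-10 tag is a candidate
  tags2 <- S4Vectors::DataFrame(sequence = tagC)
  tags2$counts <- matrix(10L, dimnames = list(NULL, "L"))
  expect_equal(length(candidateLoci(tags2, genome)), 1L)
})

test_that("repeat-derived tags are discarded", {
  unit <- "TGACCTGGTCTGACTCGGATC"
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep(c(unit, "TTTTTTTTTT"), 25), collapse = "")))
  tags <- S4Vectors::DataFrame(sequence = unit)
  tags$counts <- matrix(50L, dimnames = list(NULL, "L"))
  expect_message(loci <- candidateLoci(tags, genome), "repeat")
  expect_equal(length(loci), 0L)
})

test_that("the folding contract is validated and violations are fold_error", {
  cand <- newHairpinCandidate("GGGAAACCC" , c(2L, 5L))
  ok <- foldPrecursor(cand, stubFolder(list(
    GGGAAACCC = list(structure = "(((...)))", mfe = -3.1))))
  expect_equal(ok@structure, "(((...)))")
  expect_equal(ok@mfe, -3.1)
  short <- foldPrecursor(cand, stubFolder(list(GGGAAACCC = "((..))")))
  expect_false(short@verdict)
  expect_equal(short@failureReasons, "fold_error")
  unbal <- foldPrecursor(cand, stubFolder(list(GGGAAACCC = "(((...))).")))
  expect_equal(unbal@failureReasons, "fold_error")
  err <- foldPrecursor(cand, function(s) stop("engine down"))
  expect_equal(err@failureReasons, "fold_error")
})

test_that("a perfect duplex passes; each spoiler fails with its own reason", {
  set.seed(32)
  mature <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
  hp <- makePerfectHairpin(mature)
  cand <- newHairpinCandidate(hp$seq, hp$matureSpan)
  cand <- foldPrecursor(cand, stubFolder(setNames(list(hp$structure),
                                                  hp$seq)))
  cand <- validateHairpin(cand)
  expect_true(cand@verdict)
  expect_equal(cand@geometry$nMismatch, 0L)
  expect_equal(nrow(cand@geometry$bulges), 0L)

  n <- nchar(hp$seq)
  # spoiler 1: five unpaired mature positions (symmetric internal loop)
  st <- strsplit(hp$structure, "")[[1]]
  st[10:14] <- "."                      # mature side (positions 10..14)
  st[n + 1 - (10:14)] <- "."            # star side, symmetric
  mm <- validateHairpin(foldPrecursor(
    newHairpinCandidate(hp$seq, hp$matureSpan),
    stubFolder(setNames(list(paste(st, collapse = "")), hp$seq))))
  expect_false(mm@verdict)
  expect_equal(mm@failureReasons, "mismatches>4")
  expect_equal(mm@geometry$nMismatch, 5L)

  # spoiler 2: one 3-nt asymmetric bulge on the star arm
  bulged <- makeBulgedStructure(hp$seq, hp$matureSpan, bulge = 3L)
  bl <- validateHairpin(foldPrecursor(
    newHairpinCandidate(bulged$seq, hp$matureSpan),
    stubFolder(setNames(list(bulged$structure), bulged$seq))))
  expect_false(bl@verdict)
  expect_equal(bl@failureReasons, "bulge>2nt")

  # spoiler 3: mature spanning the terminal loop pairs with itself
  loopSpan <- c(20L, 40L)
  lp <- validateHairpin(foldPrecursor(
    newHairpinCandidate(hp$seq, loopSpan),
    stubFolder(setNames(list(hp$structure), hp$seq))))
  expect_false(lp@verdict)
  expect_true("not_opposite_arms" %in% lp@failureReasons)

  # two 1-nt bulges exceed the bulge-count criterion
  twob <- makeBulgedStructure(hp$seq, hp$matureSpan, bulge = c(1L, 1L))
  tb <- validateHairpin(foldPrecursor(
    newHairpinCandidate(twob$seq, hp$matureSpan),
    stubFolder(setNames(list(twob$structure), twob$seq))))
  expect_false(tb@verdict)
  expect_equal(tb@failureReasons, "bulge_count>1")
})

test_that("a thermodynamic folder confirms the constructed inverted repeat", {
  mature <- "TGACCTGGTCTGACTCGGATCACGGTACCG"   # 30 nt stem arm
  hp <- makePerfectHairpin(mature, ext = "", loop = "GAATTC")
  res <- viennaFolder()(hp$seq)
  expect_equal(nchar(res$structure), nchar(hp$seq))
  expect_lt(res$mfe, -20)
  p <- altimiR:::.dotBracketPairs(res$structure)
  paired <- sum(p[hp$matureSpan[1]:hp$matureSpan[2]] > 0)
  expect_gte(paired, 28L)
})

test_that("genomic origin agrees with a brute-force interval scan", {
  set.seed(33)
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1000, 1000, 1700, 5000, 5000),
                     c(2500, 1400, 2500, 6000, 6000)),
    type = c("gene", "exon", "exon", "gene", "exon"))
  st <- sample(1:8000, 1000, replace = TRUE)
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + 20L))
  got <- annotateOrigin(loci, genes)
  ex <- as.data.frame(genes[genes$type == "exon"])
  gn <- as.data.frame(genes[genes$type == "gene"])
  want <- vapply(seq_along(st), function(i) {
    a <- st[i]; b <- st[i] + 20L
    hitEx <- any(a <= ex$end & b >= ex$start)
    hitGn <- any(a <= gn$end & b >= gn$start)
    if (hitEx) "exonic" else if (hitGn) "intronic" else "intergenic"
  }, "")
  expect_equal(got, want)
  expect_true(all(c("exonic", "intronic", "intergenic") %in% got))
})

test_that("novel discovery is deterministic with a stub engine", {
  set.seed(34)
  mature <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
  hp <- makePerfectHairpin(mature)
  pad1 <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  pad2 <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(pad1, hp$seq, pad2)))
  tags <- S4Vectors::DataFrame(sequence = mature)
  tags$counts <- matrix(40L, dimnames = list(NULL, "L"))
  engine <- function(seq)
    list(structure = strrep(".", nchar(seq)), mfe = -1)
  r1 <- novelHairpins(tags, genome, engine, minAbundance = 10)
  r2 <- novelHairpins(tags, genome, engine, minAbundance = 10)
  expect_identical(r1, r2)
  expect_true(all(!r1$verdict))  # all-dot structure: no duplex
})
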