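adapter <- "TGGAATTCTCGGGTGCCAAGG"
q <- function(n, ch = "I") strrep(ch, n)

test_that("adapter trimming, quality and size filters behave and conserve reads", {
  ins21 <- "TGACCTGGTCTGACTCGGATC"          # 21 nt, kept
  ins17 <- "TGACCTGGTCTGACTCG"              # 17 nt, size-dropped
  noAd <- strrep("ACGT", 10)                # 40 nt, no adapter, size-dropped
  seqs <- c(paste0(ins21, adapter),         # perfect adapter
            paste0(ins21, adapter),         # collapsing: identical insert
            paste0(ins21, adapter),
            paste0(ins17, adapter),
            paste0(adapter, "ACGTACGT"),    # adapter at read start
            paste0(ins21, adapter),         # low quality
            noAd)
  quals <- c(q(nchar(seqs[1])), q(nchar(seqs[2])), q(nchar(seqs[3])),
             q(nchar(seqs[4])), q(nchar(seqs[5])),
             q(nchar(seqs[6]), "#"), q(nchar(seqs[7])))
  fq <- writeTestFastq(seqs, quals, tempfile(fileext = ".fastq"))
  res <- trimAndFilter(c(libA = fq), adapter)
  tt <- res$totals
  expect_equal(tt$raw, 7L)
  expect_equal(tt$dropped_empty, 1L)
  expect_equal(tt$dropped_quality, 1L)
  expect_equal(tt$dropped_size, 2L)
  expect_equal(tt$kept, 3L)
  # conservation: raw = empty + quality + size + collapsed-tag total
  expect_equal(tt$raw, tt$dropped_empty + tt$dropped_quality +
                 tt$dropped_size + sum(res$tags$counts[, "libA"]))
  expect_equal(res$tags$sequence, ins21)
  expect_equal(unname(res$tags$counts[, "libA"]), 3L)
})

test_that("adapter seed tolerates one mismatch", {
  ins <- "TGACCTGGTCTGACTCGGATC"
  mutAd <- adapter
  substring(mutAd, 3, 3) <- "T"   # one mismatch inside the 8-nt seed
  fq <- writeTestFastq(paste0(ins, mutAd), q(nchar(ins) + nchar(mutAd)),
                       tempfile(fileext = ".fastq"))
  res <- trimAndFilter(c(l = fq), adapter)
  expect_equal(res$tags$sequence, ins)
})

test_that("hierarchical classification is sequential and order-dependent", {
  toy <- makeToyAnnotation()
  trnaFrag <- "GGGCCCGGGTTTAAACCCGGG"
  shared <- "AATTCCGGAATTCCGGAATTC"          # present in two pools
  genomeOnly <- "CACACACACATGTGTGTGTGT"
  genome <- Biostrings::DNAStringSet(paste0(
    "AAAA", trnaFrag, "TT", shared, "TT", genomeOnly, "TT", toy$hpA, "TT",
    toy$hpB, "CCGG"))
  names(genome) <- "chr1"
  pools <- referencePools(
    genome,
    cDNA = Biostrings::DNAStringSet(paste0("TTTT", shared, "AAAA")),
    t_rRNA = Biostrings::DNAStringSet(paste0("CC", trnaFrag, shared, "GG")))
  tags <- c(trnaFrag, shared, genomeOnly, toy$m5, "TTTTTTTTTTTTTTTTTTTTT")
  cl <- classifyHierarchical(tags, pools, toy$index)
  expect_equal(cl$label,
               c("t_rRNA", "cDNA", "clean_unassigned", "miRNA",
                 "unmapped_genome"))
  expect_equal(cl$assigned[cl$label == "miRNA"], "ath-miR501a-5p")
  # permuting pool order flips only the tag present in both pools
  pools2 <- referencePools(
    genome,
    t_rRNA = Biostrings::DNAStringSet(paste0("CC", trnaFrag, shared, "GG")),
    cDNA = Biostrings::DNAStringSet(paste0("TTTT", shared, "AAAA")))
  cl2 <- classifyHierarchical(tags, pools2, toy$index)
  expect_equal(cl2$label[2], "t_rRNA")
  expect_equal(cl$label[-2], cl2$label[-2])
})

test_that("classification with zero mismatches equals a brute-force scan", {
  set.seed(42)
  toy <- makeToyAnnotation()
  poolA <- vapply(1:3, function(i) paste(
    sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), "")
  poolB <- vapply(1:3, function(i) paste(
    sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), "")
  genomeSeq <- paste(c(poolA, poolB, toy$hpA, toy$hpB,
                       replicate(4, paste(sample(c("A", "C", "G", "T"), 200,
                                                 TRUE), collapse = ""))),
                     collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr = genomeSeq))
  pools <- referencePools(genome,
                          cDNA = Biostrings::DNAStringSet(poolA),
                          t_rRNA = Biostrings::DNAStringSet(poolB))
  # random tags drawn from genome substrings plus nonsense
  tags <- unique(c(
    vapply(1:60, function(i) {
      s <- sample(nchar(genomeSeq) - 25, 1)
      substring(genomeSeq, s, s + sample(18:25, 1))
    }, ""),
    vapply(1:20, function(i) paste(sample(c("A", "C", "G", "T"), 21, TRUE),
                                   collapse = ""), "")))
  cl <- classifyHierarchical(tags, pools, toy$index)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  oracle <- vapply(tags, function(tg) {
    inAny <- function(subjects) any(vapply(subjects, function(s)
      grepl(tg, s, fixed = TRUE), TRUE))
    if (!inAny(c(genomeSeq, rc(genomeSeq)))) return("unmapped_genome")
    if (inAny(poolA)) return("cDNA")
    if (inAny(poolB)) return("t_rRNA")
    if (tg %in% expressionUnits(toy$index)$sequence) return("miRNA")
    "clean_unassigned"
  }, "", USE.NAMES = FALSE)
  expect_equal(cl$label, oracle)
})

test_that("length distribution bins by size and sums to the library total", {
  tags <- S4Vectors::DataFrame(sequence = c(strrep("A", 21), strrep("C", 24),
                                            strrep("G", 24)))
  tags$counts <- matrix(c(5L, 4L, 3L, 0L, 0L, 0L), ncol = 2,
                        dimnames = list(NULL, c("l1", "l2")))
  h <- lengthDistribution(tags, "l1")
  expect_equal(unname(h[c("21", "24")]), c(5L, 7L))
  expect_equal(sum(h), sum(tags$counts[, "l1"]))
  expect_equal(sum(lengthDistribution(tags, "l2")), 0L)
})
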