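# Independent oracles and small fixture builders. Everything here is written
# directly from the category/rule definitions, deliberately not sharing code
# with the package internals it checks.

# Brute-force isomiR classifier: same documented precedence, independent
# implementation (manual scanning loops, no shared helpers).
oracleClassifyIsomiR <- function(tag, hairpin, start, end, window = 5L,
                                 maxTail = 5L, maxSub = 2L) {
  tag <- chartr("u", "T", chartr("U", "T", toupper(tag)))
  hairpin <- chartr("U", "T", toupper(hairpin))
  len <- nchar(tag)
  hlen <- nchar(hairpin)
  canonical <- substring(hairpin, start, end)
  out <- function(cat, o5 = 0L, o3 = 0L, tail = "")
    list(category = cat, offset5 = o5, offset3 = o3,
         tail = chartr("T", "U", tail))

  if (tag == canonical) return(out("canonical"))

  # every exact occurrence, by manual scan
  occ <- integer(0)
  if (len <= hlen)
    for (i in seq_len(hlen - len + 1L))
      if (substring(hairpin, i, i + len - 1L) == tag) occ <- c(occ, i)
  if (length(occ)) {
    o5 <- occ - start
    o3 <- occ + len - 1L - end
    ok <- which(abs(o5) <= window & abs(o3) <= window)
    if (length(ok)) {
      best <- ok[order(abs(o5[ok]) + abs(o3[ok]), occ[ok])][1L]
      a <- o5[best]; b <- o3[best]
      cat <- if (a == b) "shifted"
      else if (a == 0L) "template_3p"
      else if (b == 0L) "start_site"
      else "both_end"
      return(out(cat, a, b))
    }
  }

  # non-templated 3' tail: anchor the 5' end at start + d, take the maximal
  # templated prefix, require a 1..maxTail tail and a near-canonical 3' end
  for (d in c(0L, as.vector(rbind(-seq_len(window), seq_len(window))))) {
    s2 <- start + d
    if (s2 < 1L || s2 > hlen) next
    p <- 0L
    while (p < len && s2 + p <= hlen &&
           substring(tag, p + 1L, p + 1L) ==
           substring(hairpin, s2 + p, s2 + p)) p <- p + 1L
    tailLen <- len - p
    if (p < 1L || tailLen < 1L || tailLen > maxTail) next
    if (abs((s2 + p - 1L) - end) > maxTail) next
    tail <- substring(tag, p + 1L, len)
    if (d == 0L) return(out("nontemplate_3p", 0L, (s2 + p - 1L) - end, tail))
    return(out("both_end", d, (s2 + p - 1L) - end, tail))
  }

  # internal substitutions
  if (len == nchar(canonical)) {
    mm <- integer(0)
    for (i in seq_len(len))
      if (substring(tag, i, i) != substring(canonical, i, i))
        mm <- c(mm, i)
    if (length(mm) >= 1L && length(mm) <= maxSub && !(1L %in% mm) &&
        !(len %in% mm))
      return(out("substitution"))
  }
  out("unassigned")
}

# Enumerate the oracle test tags for one mature: all windowed substrings,
# all one-base 3' extensions of the canonical, all single-substitution
# variants of the canonical. Only size-filter-compatible lengths.
enumerateIsomirTags <- function(hairpin, start, end, window = 5L) {
  hlen <- nchar(hairpin)
  tags <- character(0)
  for (o5 in -window:window) for (o3 in -window:window) {
    s <- start + o5; e <- end + o3
    if (s < 1L || e > hlen || e <= s) next
    len <- e - s + 1L
    if (len < 18L || len > 28L) next
    tags <- c(tags, substring(hairpin, s, e))
  }
  canonical <- substring(hairpin, start, end)
  if (nchar(canonical) + 1L <= 28L)
    tags <- c(tags, paste0(canonical, c("A", "C", "G", "T")))
  for (i in seq_len(nchar(canonical)))
    for (b in setdiff(c("A", "C", "G", "T"), substring(canonical, i, i))) {
      v <- canonical
      substring(v, i, i) <- b
      tags <- c(tags, v)
    }
  unique(tags)
}

# Write a FASTQ file from sequences and quality strings.
writeTestFastq <- function(seqs, quals, path) {
  stopifnot(length(seqs) == length(quals))
  out <- character(4L * length(seqs))
  out[seq(1, length(out), 4)] <- paste0("@r", seq_along(seqs))
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- quals
  writeLines(out, path)
  path
}

# Hand-built two-hairpin annotation: hpA has 5p and 3p matures, hpB a single
# unlabeled mature. Returns the index plus the raw sequences.
makeToyAnnotation <- function() {
  m5 <- "TGACCTGGTCTGACTCGGATC"                      # 21 nt
  loop <- "GATTTCGG"
  hpA <- paste0("ACGCTG", m5, loop,
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(m5))), "CAGCGT")
  m3 <- substring(hpA, 38, 58)
  mB <- "TTGGACTGAAGGGAGCTCCCT"                      # 21 nt
  hpB <- paste0("GGAACC", mB, "GCCTTAAG",
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(mB))), "GGTTCC")
  mature <- Biostrings::DNAStringSet(c(
    "ath-miR501a-5p" = m5, "ath-miR501a-3p" = m3, "ath-miR502a" = mB))
  hairpin <- Biostrings::DNAStringSet(c(
    "ath-MIR501a" = hpA, "ath-MIR502a" = hpB))
  list(index = loadAnnotation(mature, hairpin),
       m5 = m5, m3 = m3, mB = mB, hpA = hpA, hpB = hpB)
}

# Variant of the perfect hairpin with asymmetric bulges on the star arm.
# `bulge` is a vector of bulge sizes; the star arm is split evenly and the
# extra unpaired bases inserted between the chunks. Assumes the
# makePerfectHairpin layout (ext | mature | loop | star | ext').
makeBulgedStructure <- function(seq, span, bulge) {
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  E <- substring(seq, 1L, span[1] - 1L)
  M <- substring(seq, span[1], span[2])
  stem <- nchar(E) + nchar(M)
  loopLen <- nchar(seq) - 2L * stem
  L <- substring(seq, span[2] + 1L, span[2] + loopLen)
  mlen <- nchar(M)
  nb <- length(bulge)
  cuts <- round(seq(mlen, 0, length.out = nb + 2L))[2:(nb + 1L)]
  right <- ""; rstruct <- ""
  hi <- mlen
  for (k in seq_len(nb)) {
    right <- paste0(right, rc(substring(M, cuts[k] + 1L, hi)),
                    strrep("A", bulge[k]))
    rstruct <- paste0(rstruct, strrep(")", hi - cuts[k]),
                      strrep(".", bulge[k]))
    hi <- cuts[k]
  }
  right <- paste0(right, rc(substring(M, 1L, hi)), rc(E))
  rstruct <- paste0(rstruct, strrep(")", hi + nchar(E)))
  list(seq = paste0(E, M, L, right),
       structure = paste0(strrep("(", stem), strrep(".", loopLen), rstruct))
}

# Perfect inverted-repeat precursor with an armlen-bp stem: returns sequence,
# dot-bracket structure, and the 1-based mature span on the 5' arm.
makePerfectHairpin <- function(mature, ext = "ACGCTG", loop = "GATTTCGG") {
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  seqc <- paste0(ext, mature, loop, rc(mature), rc(ext))
  stem <- nchar(ext) + nchar(mature)
  list(seq = seqc,
       structure = paste0(strrep("(", stem), strrep(".", nchar(loop)),
                          strrep(")", stem)),
       matureSpan = c(nchar(ext) + 1L, nchar(ext) + nchar(mature)))
}
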