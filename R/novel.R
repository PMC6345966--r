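#' Candidate novel miRNA loci from clean unassigned tags
#'
#' Tags with a summed count of at least `minAbundance` are mapped exactly to
#' the genome (both strands); tags hitting more than `maxLoci` positions are
#' discarded as repeat-derived. Overlapping tag hits on one strand are merged
#' into a locus led by its most abundant tag (the putative mature), and a
#' precursor window of the mature plus `flank` nt on each side is emitted.
#'
#' @param tags [S4Vectors::DataFrame] of clean unassigned tags (`sequence`,
#'   `counts`).
#' @param genome `DNAStringSet`.
#' @param minAbundance minimum summed read count (default 10).
#' @param flank window extension per side in nt (default 100).
#' @param maxLoci repeat filter: maximum genomic hits per tag (default 20).
#' @return `GRanges` of precursor windows with metadata columns `matureSeq`,
#'   `count`, `matureStart`, `matureEnd` (1-based positions of the mature on
#'   the window, already strand-adjusted).
#' @export
candidateLoci <- function(tags, genome, minAbundance = 10L, flank = 100L,
                          maxLoci = 20L) {
  tot <- rowSums(tags$counts)
  keep <- which(tot >= minAbundance & !grepl("[^ACGT]", tags$sequence))
  hits <- list()
  for (i in keep) {
    sq <- tags$sequence[i]
    for (ch in names(genome)) {
      for (str in c("+", "-")) {
        pat <- if (str == "+") sq else .revComp(sq)
        occ <- .occurrences(pat, as.character(genome[[ch]]))
        for (o in occ)
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = ch, start = o, end = o + nchar(sq) - 1L, strand = str,
            tag = sq, count = tot[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(GRanges())
  h <- do.call(rbind, hits)
  nHits <- table(h$tag)
  repeats <- names(nHits)[nHits > maxLoci]
  if (length(repeats)) {
    message(length(repeats), " tag(s) discarded as repeat-derived (>",
            maxLoci, " loci)")
    h <- h[!h$tag %in% repeats, , drop = FALSE]
  }
  if (!nrow(h)) return(GRanges())
  gr <- GRanges(h$chrom, IRanges(h$start, h$end), strand = h$strand,
                tag = h$tag, count = h$count)
  merged <- reduce(gr, with.revmap = TRUE)
  out <- lapply(seq_along(merged), function(k) {
    ids <- mcols(merged)$revmap[[k]]
    lead <- ids[which.max(mcols(gr)$count[ids])]
    tagGr <- gr[lead]
    chromLen <- nchar(as.character(genome[[as.character(seqnames(tagGr))]]))
    ws <- max(1L, start(tagGr) - flank)
    we <- min(chromLen, end(tagGr) + flank)
    win <- GRanges(seqnames(tagGr), IRanges(ws, we), strand = strand(tagGr))
    if (as.character(strand(tagGr)) == "+") {
      ms <- start(tagGr) - ws + 1L
    } else {
      ms <- we - end(tagGr) + 1L
    }
    mcols(win)$matureSeq <- mcols(gr)$tag[lead]
    mcols(win)$count <- mcols(gr)$count[lead]
    mcols(win)$matureStart <- ms
    mcols(win)$matureEnd <- ms + nchar(mcols(gr)$tag[lead]) - 1L
    win
  })
  do.call(c, out)
}

#' Folding engines
#'
#' A folding engine is any function taking an RNA/DNA string and returning
#' `list(structure = <dot-bracket>, mfe = <kcal/mol>)`. `stubFolder()` wraps
#' a table of pre-computed structures (deterministic; used throughout the
#' test suite); `viennaFolder()` shells out to the `RNAfold` executable when
#' one is on the `PATH`.
#'
#' @param structures named list/vector: sequence -> dot-bracket string (or
#'   `list(structure=, mfe=)`).
#' @return a folding engine function.
#' @export
stubFolder <- function(structures) {
  force(structures)
  function(seq) {
    seq <- .unifySeq(seq)
    entry <- structures[[seq]]
    if (is.null(entry)) .stopf("stub folder has no structure for sequence")
    if (is.character(entry)) entry <- list(structure = entry, mfe = NA_real_)
    entry
  }
}

#' @rdname stubFolder
#' @param exe path to the RNAfold executable.
#' @export
viennaFolder <- function(exe = Sys.which("RNAfold")) {
  if (!nzchar(exe)) .stopf("RNAfold not found on PATH")
  function(seq) {
    out <- system2(exe, c("--noPS"), input = .toRNA(seq), stdout = TRUE)
    line <- out[length(out)]
    m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1L]]
    if (length(m) != 3L) .stopf("unparseable RNAfold output: %s", line)
    list(structure = m[2L], mfe = as.numeric(m[3L]))
  }
}

#' Fold a candidate precursor
#'
#' Runs the injected folding engine and validates its contract (balanced
#' dot-bracket of the same length as the precursor). A contract violation or
#' engine failure marks the candidate failed with reason `"fold_error"`.
#'
#' @param candidate A [HairpinCandidate-class] (or construct one with
#'   `newHairpinCandidate()`).
#' @param engine a folding engine (see [stubFolder()]).
#' @return the candidate with `structure` and `mfe` filled (or failed).
#' @export
foldPrecursor <- function(candidate, engine) {
  res <- tryCatch(engine(candidate@precursor), error = function(e) NULL)
  bad <- is.null(res) || !is.character(res$structure) ||
    nchar(res$structure) != nchar(candidate@precursor) ||
    !.balancedDotBracket(res$structure)
  if (bad) {
    candidate@verdict <- FALSE
    candidate@failureReasons <- "fold_error"
    return(candidate)
  }
  candidate@structure <- res$structure
  candidate@mfe <- if (is.null(res$mfe)) NA_real_ else res$mfe
  candidate
}

#' @rdname foldPrecursor
#' @param precursor precursor sequence.
#' @param matureSpan integer length-2, 1-based closed mature span.
#' @param locus optional `GRanges` of the genomic window.
#' @param count mature tag read count.
#' @export
newHairpinCandidate <- function(precursor, matureSpan, locus = GRanges(),
                                count = NA_real_) {
  new("HairpinCandidate", locus = locus, precursor = .unifySeq(precursor),
      matureSpan = as.integer(matureSpan), count = count)
}

.balancedDotBracket <- function(s) {
  if (grepl("[^.()]", s)) return(FALSE)
  v <- cumsum(c(`(` = 1, `)` = -1, `.` = 0)[strsplit(s, "")[[1L]]])
  all(v >= 0) && v[length(v)] == 0
}

# Pair table of a dot-bracket string: p[i] = partner of i, 0 when unpaired.
.dotBracketPairs <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  p <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    }
  }
  p
}

#' Validate a folded hairpin against miRNA duplex criteria
#'
#' The three criteria: (a) the mature and its star derive from opposite stem
#' arms, forming a duplex with the canonical 2-nt 3' overhangs (the star span
#' is the interval of base-pairing partners of the mature shifted by the
#' canonical 2-nt offset; a mature pairing with itself, e.g. spanning the
#' terminal loop, or overlapping its star fails); (b) duplex base pairing is
#' extensive: at most 4 mature positions unpaired; (c) at most one
#' asymmetric bulge within the duplex, no bulge larger than 2 nt.
#'
#' Failure reasons are, respectively: `"not_opposite_arms"`,
#' `"mismatches>4"`, and `"bulge_count>1"` / `"bulge>2nt"`.
#'
#' @param candidate a folded [HairpinCandidate-class].
#' @param maxMismatch,maxBulges,maxBulgeSize criterion thresholds
#'   (defaults 4, 1, 2).
#' @return the candidate with `verdict`, `failureReasons` and `geometry`
#'   (`nMismatch`, `bulges` data.frame, `starSpan`, `overhang3`) filled.
#' @export
validateHairpin <- function(candidate, maxMismatch = 4L, maxBulges = 1L,
                            maxBulgeSize = 2L) {
  if (!nzchar(candidate@structure))
    .stopf("candidate has no structure: run foldPrecursor() first")
  p <- .dotBracketPairs(candidate@structure)
  m1 <- candidate@matureSpan[1L]; m2 <- candidate@matureSpan[2L]
  if (m2 > length(p)) .stopf("mature span not covered by structure")
  mpos <- m1:m2
  reasons <- character(0)

  partners <- p[mpos]
  paired <- partners > 0L
  selfPaired <- paired & partners >= m1 & partners <= m2
  if (!any(paired) || any(selfPaired)) {
    reasons <- c(reasons, "not_opposite_arms")
    starSpan <- c(NA_integer_, NA_integer_)
  } else {
    pr <- range(partners[paired])
    starSpan <- pr + 2L
    starSpan[2L] <- min(starSpan[2L], length(p))
    if (starSpan[1L] <= m2 && starSpan[2L] >= m1)
      reasons <- c(reasons, "not_opposite_arms")
  }

  nMismatch <- sum(!paired)
  if (nMismatch > maxMismatch) reasons <- c(reasons, "mismatches>4")

  # Asymmetric bulges between consecutive paired mature positions.
  bulges <- data.frame(arm = character(0), size = integer(0),
                       stringsAsFactors = FALSE)
  pi <- mpos[paired]
  if (length(pi) >= 2L && !any(selfPaired)) {
    for (k in seq_len(length(pi) - 1L)) {
      i <- pi[k]; j <- pi[k + 1L]
      gm <- j - i - 1L
      gs <- abs(p[i] - p[j]) - 1L
      if (gm != gs)
        bulges <- rbind(bulges, data.frame(
          arm = if (gm > gs) "mature" else "star",
          size = abs(gm - gs), stringsAsFactors = FALSE))
    }
  }
  if (nrow(bulges) > maxBulges) reasons <- c(reasons, "bulge_count>1")
  if (any(bulges$size > maxBulgeSize)) reasons <- c(reasons, "bulge>2nt")

  candidate@verdict <- length(reasons) == 0L
  candidate@failureReasons <- reasons
  candidate@geometry <- list(nMismatch = nMismatch, bulges = bulges,
                             starSpan = starSpan, overhang3 = 2L)
  candidate
}

#' Genomic origin of candidate loci
#'
#' Labels each locus by overlap of its mature span with gene models: `exonic`
#' when any exon overlaps (any-overlap rule), else `intronic` when inside a
#' gene, else `intergenic`.
#'
#' @param loci `GRanges` (use the mature positions, e.g. shift candidate
#'   windows to their `matureStart`/`matureEnd`).
#' @param geneModels a `GRanges` with a `type` metadata column containing
#'   `gene` and `exon` features, or a path to a GFF3 file.
#' @return character vector of labels, one per locus.
#' @export
annotateOrigin <- function(loci, geneModels) {
  if (is.character(geneModels))
    geneModels <- rtracklayer::import(geneModels)
  type <- as.character(mcols(geneModels)$type)
  exons <- geneModels[type == "exon"]
  genes <- geneModels[type == "gene"]
  inExon <- overlapsAny_(loci, exons)
  inGene <- overlapsAny_(loci, genes)
  ifelse(inExon, "exonic", ifelse(inGene, "intronic", "intergenic"))
}

overlapsAny_ <- function(q, s) {
  if (!length(s)) return(rep(FALSE, length(q)))
  lengths(as(findOverlaps(q, s, ignore.strand = TRUE), "List")) > 0
}

#' Discover and validate novel hairpins end to end
#'
#' [candidateLoci()] then fold + validate each window with the injected
#' engine, and annotate genomic origin when gene models are given.
#'
#' @param tags clean unassigned tag `DataFrame`.
#' @param genome `DNAStringSet`.
#' @param engine folding engine.
#' @param geneModels optional GFF3 path or `GRanges`.
#' @inheritParams candidateLoci
#' @return data.frame: locus coordinates, mature sequence and count,
#'   precursor length, mfe, verdict, reasons, origin.
#' @export
novelHairpins <- function(tags, genome, engine, geneModels = NULL,
                          minAbundance = 10L, flank = 100L, maxLoci = 20L) {
  wins <- candidateLoci(tags, genome, minAbundance = minAbundance,
                        flank = flank, maxLoci = maxLoci)
  if (!length(wins)) return(data.frame())
  rows <- lapply(seq_along(wins), function(k) {
    w <- wins[k]
    ch <- as.character(genome[[as.character(seqnames(w))]])
    prec <- substr(ch, start(w), end(w))
    if (as.character(strand(w)) == "-") prec <- .revComp(prec)
    cand <- newHairpinCandidate(prec,
                                c(mcols(w)$matureStart, mcols(w)$matureEnd),
                                locus = w, count = mcols(w)$count)
    cand <- foldPrecursor(cand, engine)
    if (is.na(cand@verdict) || !identical(cand@failureReasons, "fold_error"))
      cand <- validateHairpin(cand)
    data.frame(chrom = as.character(seqnames(w)), start = start(w),
               end = end(w), strand = as.character(strand(w)),
               matureSeq = mcols(w)$matureSeq, count = mcols(w)$count,
               precursorLength = nchar(prec), mfe = cand@mfe,
               verdict = isTRUE(cand@verdict),
               reasons = paste(cand@failureReasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(geneModels)) {
    plus <- as.character(strand(wins)) != "-"
    gs <- ifelse(plus, start(wins) + mcols(wins)$matureStart - 1L,
                 end(wins) - mcols(wins)$matureEnd + 1L)
    ge <- ifelse(plus, start(wins) + mcols(wins)$matureEnd - 1L,
                 end(wins) - mcols(wins)$matureStart + 1L)
    out$origin <- annotateOrigin(GRanges(out$chrom, IRanges(gs, ge)),
                                 geneModels)
  }
  out
}
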