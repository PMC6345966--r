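#' Adapter, quality and size filtering of raw small RNA reads
#'
#' Removes the 3' sequencing adapter, drops low-quality reads and reads whose
#' insert falls outside the retained size range, and collapses surviving
#' inserts into unique tags with per-library counts.
#'
#' The adapter is located by the leftmost occurrence of its first `seedLen`
#' bases allowing at most `seedMismatch` mismatches; everything from that
#' position on is removed. Reads where the adapter starts at position one
#' (empty insert) are dropped and counted separately. Reads with no adapter
#' hit keep their full length (and are then usually removed by the size
#' filter). Quality filtering uses the mean Phred score over the insert.
#'
#' @param files named character vector of FASTQ paths; names are library ids.
#' @param adapter 3' adapter sequence (non-empty).
#' @param minLen,maxLen retained insert size range in nt (default 18-28).
#' @param minQual minimum mean Phred quality of the insert (default 20).
#' @param seedLen,seedMismatch adapter seed length and mismatch tolerance.
#' @return A list with `tags`, a [S4Vectors::DataFrame] with a `sequence`
#'   column and a `counts` matrix column (one column per library), and
#'   `totals`, a data.frame of per-library read accounting (`raw`,
#'   `dropped_empty`, `dropped_quality`, `dropped_size`, `kept`).
#' @export
trimAndFilter <- function(files, adapter, minLen = 18L, maxLen = 28L,
                          minQual = 20, seedLen = 8L, seedMismatch = 1L) {
  if (!is.character(adapter) || !nzchar(adapter))
    .stopf("adapter must be a non-empty sequence")
  if (is.null(names(files)) || any(!nzchar(names(files))))
    .stopf("FASTQ files must be named by library id")
  adapter <- .unifySeq(adapter)
  seed <- DNAString(substr(adapter, 1L, min(seedLen, nchar(adapter))))

  libs <- names(files)
  perLib <- vector("list", length(libs))
  totals <- data.frame(library = libs, raw = 0L, dropped_empty = 0L,
                       dropped_quality = 0L, dropped_size = 0L, kept = 0L,
                       stringsAsFactors = FALSE)
  for (k in seq_along(files)) {
    reads <- readDNAStringSet(files[[k]], format = "fastq",
                              with.qualities = TRUE)
    totals$raw[k] <- length(reads)
    if (!length(reads)) { perLib[[k]] <- integer(0); next }
    mi <- vmatchPattern(seed, reads, max.mismatch = seedMismatch)
    pos <- vapply(startIndex(mi), function(s)
      if (length(s)) min(s) else NA_integer_, 1L)
    insertLen <- ifelse(is.na(pos), Biostrings::width(reads), pos - 1L)
    empty <- !is.na(pos) & pos == 1L

    q <- as(PhredQuality(mcols(reads)$qualities), "IntegerList")
    headLen <- pmax(insertLen, 0L)
    meanQ <- sum(heads(q, n = pmin(headLen, lengths(q)))) / pmax(headLen, 1L)
    lowQ <- !empty & meanQ < minQual
    badSize <- !empty & !lowQ & (insertLen < minLen | insertLen > maxLen)
    keep <- !empty & !lowQ & !badSize

    totals$dropped_empty[k] <- sum(empty)
    totals$dropped_quality[k] <- sum(lowQ)
    totals$dropped_size[k] <- sum(badSize)
    totals$kept[k] <- sum(keep)
    inserts <- as.character(subseq(reads[keep], 1L, insertLen[keep]))
    perLib[[k]] <- table(inserts)
  }
  allTags <- sort(unique(unlist(lapply(perLib, names))))
  counts <- matrix(0L, nrow = length(allTags), ncol = length(libs),
                   dimnames = list(NULL, libs))
  for (k in seq_along(libs)) {
    tb <- perLib[[k]]
    if (length(tb)) counts[match(names(tb), allTags), k] <- as.integer(tb)
  }
  tags <- DataFrame(sequence = allTags)
  tags$counts <- counts
  list(tags = tags, totals = totals)
}

#' Hierarchical (sequential) classification of small RNA tags
#'
#' Implements first-match-wins classification: tags absent from the genome are
#' `unmapped_genome`; genome-mapped tags are tested against each contaminant
#' class pool in the fixed order given by the [ReferencePools-class] (first
#' matching pool wins and the tag is discarded from miRNA analysis); remaining
#' "clean" tags matching a collapsed mature sequence are labeled `miRNA`; the
#' rest are `clean_unassigned` (candidate input for novel miRNA discovery).
#'
#' Matching is ungapped exact substring search: both strands for the genome,
#' sense strand only for class pools, and full-length sequence identity (with
#' at most `maxMismatch` substitutions) against collapsed matures. Tags that
#' match several distinct collapsed matures (possible only when
#' `maxMismatch > 0`) are assigned to all of them and flagged ambiguous.
#'
#' @param tags [S4Vectors::DataFrame] from [trimAndFilter()] (columns
#'   `sequence`, `counts`), or a character vector of tag sequences.
#' @param pools A [ReferencePools-class].
#' @param index An [AnnotationIndex-class].
#' @param maxMismatch substitutions allowed in the mature match (default 0).
#' @return The input `DataFrame` with added columns `label`, `assigned`
#'   (comma-separated unit ids, `""` otherwise) and `ambiguous`.
#' @export
classifyHierarchical <- function(tags, pools, index, maxMismatch = 0L) {
  if (is.character(tags)) {
    x <- DataFrame(sequence = tags)
    x$counts <- matrix(1L, nrow = length(tags), ncol = 1L,
                       dimnames = list(NULL, "lib1"))
    tags <- x
  }
  if (!is(pools, "ReferencePools")) .stopf("pools must be a ReferencePools")
  if (!length(pools@pools)) .stopf("empty class pools")
  sq <- tags$sequence
  n <- length(sq)
  label <- rep("unmapped_genome", n)
  assigned <- rep("", n)
  ambiguous <- rep(FALSE, n)

  genomeBoth <- c(pools@genome, reverseComplement(pools@genome))
  inGenome <- .tagHits(sq, genomeBoth)
  remaining <- inGenome
  for (pn in names(pools@pools)) {
    if (!any(remaining)) break
    hit <- remaining
    hit[remaining] <- .tagHits(sq[remaining], pools@pools[[pn]])
    label[hit] <- pn
    remaining <- remaining & !hit
  }
  # Clean tags vs collapsed mature units.
  units <- index@units
  if (any(remaining) && nrow(units)) {
    idx <- which(remaining)
    if (maxMismatch == 0L) {
      m <- match(sq[idx], units$sequence)
      ok <- !is.na(m)
      label[idx[ok]] <- "miRNA"
      assigned[idx[ok]] <- units$unit[m[ok]]
    } else {
      uw <- nchar(units$sequence)
      uraw <- lapply(units$sequence, charToRaw)
      for (i in idx) {
        ti <- charToRaw(sq[i])
        cand <- which(uw == length(ti))
        hits <- cand[vapply(cand, function(j)
          sum(uraw[[j]] != ti) <= maxMismatch, TRUE)]
        if (length(hits)) {
          label[i] <- "miRNA"
          assigned[i] <- paste(units$unit[hits], collapse = ",")
          ambiguous[i] <- length(hits) > 1L
        }
      }
    }
    remaining[label == "miRNA"] <- FALSE
  }
  label[remaining] <- "clean_unassigned"
  tags$label <- label
  tags$assigned <- assigned
  tags$ambiguous <- ambiguous
  tags
}

#' Read length distribution of a library
#'
#' @param tags classified or raw tag `DataFrame` (columns `sequence`,
#'   `counts`).
#' @param library library id (a column of the counts matrix).
#' @param range lengths to report (default 18:28).
#' @return named integer vector, one bin per length; sums to the library's
#'   size-filtered read total.
#' @export
lengthDistribution <- function(tags, library, range = 18:28) {
  if (!library %in% colnames(tags$counts))
    .stopf("unknown library '%s'", library)
  len <- nchar(tags$sequence)
  cnt <- tags$counts[, library]
  out <- setNames(integer(length(range)), as.character(range))
  agg <- tapply(cnt, factor(len, levels = range), sum, default = 0L)
  out[names(agg)] <- as.integer(agg)
  out
}

#' Per-library classification summary
#'
#' Tallies read counts by classification label: raw totals, genome-mapped,
#' contaminant classes, cleaned reads (genome-mapped minus contaminants) and
#' miRNA-assigned reads. Ambiguously assigned tags count once.
#'
#' @param classified output of [classifyHierarchical()].
#' @param totals the `totals` data.frame from [trimAndFilter()] (optional).
#' @return data.frame, one row per library.
#' @export
classificationSummary <- function(classified, totals = NULL) {
  libs <- colnames(classified$counts)
  lab <- classified$label
  byLab <- function(l) colSums(classified$counts[lab %in% l, , drop = FALSE])
  contam <- setdiff(unique(lab),
                    c("unmapped_genome", "miRNA", "clean_unassigned"))
  out <- data.frame(
    library = libs,
    size_filtered = colSums(classified$counts),
    genome_mapped = colSums(
      classified$counts[lab != "unmapped_genome", , drop = FALSE]),
    contaminant = if (length(contam)) byLab(contam) else 0,
    cleaned = byLab(c("miRNA", "clean_unassigned")),
    mirna = byLab("miRNA"),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(totals))
    out <- merge(totals, out, by = "library", sort = FALSE)
  out
}
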