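#' Seven-class isomiR classification of one tag against one mature
#'
#' Classifies a small RNA tag relative to a canonical mature miRNA located on
#' its hairpin. Offsets are tag ends minus canonical ends on hairpin
#' coordinates (negative = upstream/shorter at that end). Categories:
#'
#' * `canonical` — exact annotated mature sequence.
#' * `shifted` — tag is the mature window shifted intact along the precursor
#'   (`offset5 == offset3 != 0`).
#' * `template_3p` — 5' end canonical, 3' end trimmed or extended with
#'   precursor-templated bases (`offset5 == 0`, `offset3 != 0`, no tail).
#' * `nontemplate_3p` — 5' end canonical, 3' tail of bases absent from the
#'   precursor template (non-templated addition; tail recorded).
#' * `start_site` — 3' end canonical, variant 5' start (`offset3 == 0`,
#'   `offset5 != 0`).
#' * `both_end` — both ends vary (`offset5 != 0`, `offset3 != 0`,
#'   `offset5 != offset3`), templated or with a non-templated tail.
#' * `substitution` — same length and ends as the canonical with 1 to
#'   `maxSub` internal mismatches (not at the first or last position).
#'
#' The decision tree applies in that order (first match wins): exact
#' canonical; exact occurrence in the hairpin with both offsets within
#' `window`, preferring the smallest `|offset5| + |offset3|`; non-templated
#' 3' tail with canonical 5' start (the longest hairpin-templated prefix is
#' extended; tail length and templated 3' end offset are bounded by
#' `maxTail`); the same with a 5' start shifted within `window`
#' (`both_end`); internal substitutions; otherwise unassigned. A
#' length-preserving tag whose final base mismatches the template is
#' therefore called `nontemplate_3p`, not `substitution`, matching the
#' prevalence of nucleotidyl-transferase tailing. Keeping the tail bound a
#' constant separate from `window` makes enlarging `window` purely
#' permissive: it can rescue unassigned tags but never re-categorize an
#' assigned one.
#'
#' @param tag tag sequence (DNA alphabet; 18-28 nt).
#' @param hairpin hairpin precursor sequence.
#' @param start,end 1-based closed coordinates of the canonical mature on the
#'   hairpin.
#' @param window maximum absolute end offset for templated variants
#'   (default 5).
#' @param maxTail maximum non-templated tail length and templated-end offset
#'   in the tail clauses (constant, default 5).
#' @param maxSub maximum internal substitutions (default 2).
#' @return list with `category` (`"unassigned"` when no clause matches),
#'   `offset5`, `offset3`, `tail` (RNA alphabet, `""` when none) and
#'   `mismatches` (integer positions within the tag).
#' @export
classifyIsomiR <- function(tag, hairpin, start, end, window = 5L,
                           maxTail = 5L, maxSub = 2L) {
  tag <- .unifySeq(tag); hairpin <- .unifySeq(hairpin)
  tl <- nchar(tag)
  if (tl < 18L || tl > 28L)
    .stopf("tag length %d outside 18-28: upstream size filter violated", tl)
  canonical <- substr(hairpin, start, end)
  res <- function(category, o5 = 0L, o3 = 0L, tail = "",
                  mism = integer(0)) {
    list(category = category, offset5 = as.integer(o5),
         offset3 = as.integer(o3), tail = .toRNA(tail), mismatches = mism)
  }
  # (1) canonical
  if (tag == canonical) return(res("canonical"))

  # (2) exact occurrence within the offset window
  occ <- .occurrences(tag, hairpin)
  if (length(occ)) {
    o5 <- occ - start
    o3 <- (occ + tl - 1L) - end
    ok <- abs(o5) <= window & abs(o3) <= window
    if (any(ok)) {
      i <- which(ok)[order(abs(o5[ok]) + abs(o3[ok]), occ[ok])][1L]
      cat <- if (o5[i] == o3[i]) "shifted"
      else if (o5[i] == 0L) "template_3p"
      else if (o3[i] == 0L) "start_site"
      else "both_end"
      return(res(cat, o5[i], o3[i]))
    }
  }

  hpLen <- nchar(hairpin)
  # (3)/(4) non-templated 3' tail: longest templated prefix anchored at a 5'
  # start (canonical first, then shifts within the window, nearest first);
  # the remaining suffix is the tail.
  ds <- seq(-window, window)
  for (o5 in ds[order(abs(ds), ds)]) {
    s <- start + o5
    if (s < 1L || s > hpLen) next
    p <- .commonPrefixLen(tag, substr(hairpin, s, hpLen))
    tailLen <- tl - p
    if (p == 0L || tailLen < 1L || tailLen > maxTail) next
    o3t <- (s + p - 1L) - end        # offset of the templated 3' end
    if (abs(o3t) > maxTail) next
    tail <- substr(tag, p + 1L, tl)
    if (o5 == 0L) return(res("nontemplate_3p", 0L, o3t, tail))
    return(res("both_end", o5, o3t, tail))
  }

  # (5) internal substitutions at the canonical position
  if (tl == nchar(canonical)) {
    ta <- charToRaw(tag); ca <- charToRaw(canonical)
    mm <- which(ta != ca)
    if (length(mm) >= 1L && length(mm) <= maxSub &&
        !(1L %in% mm) && !(tl %in% mm))
      return(res("substitution", mism = as.integer(mm)))
  }
  res("unassigned")
}

# Candidate (tag, mature) pairs by exact 8-mer anchors: every category keeps
# either its first or last 8 bases fully templated near the mature, so a tag
# is only scored against hairpins containing one of those 8-mers.
.isomirCandidates <- function(sequences, index) {
  hp <- index@hairpins
  m <- index@matures
  m <- m[order(m$arm != "5p", m$name), , drop = FALSE]  # 5p-first tie order
  anchors <- unique(c(substr(sequences, 1L, 8L),
                      substr(sequences, nchar(sequences) - 7L,
                             nchar(sequences))))
  clean <- !grepl("[^ACGT]", anchors) & nchar(anchors) == 8L
  pd <- PDict(DNAStringSet(anchors[clean]))
  hpHit <- lapply(seq_along(hp), function(j) {
    hits <- countPDict(pd, hp[[j]]) > 0L
    anchors[clean][hits]
  })
  names(hpHit) <- names(hp)
  list(matures = m, hpHit = hpHit)
}

#' Assign tags to matures with isomiR categories
#'
#' Scores every tag against every mature whose hairpin shares an exact 8-mer
#' anchor with the tag, classifies with [classifyIsomiR()], and resolves ties
#' (a tag classifiable against several matures) by the smallest
#' `|offset5| + |offset3|`, then the 5p arm, then mature name. Orphan matures
#' are skipped. Contaminant-labeled tags should be excluded upstream.
#'
#' @param tags [S4Vectors::DataFrame] with `sequence` and `counts` columns
#'   (e.g. the non-contaminant subset of [classifyHierarchical()] output).
#' @param index An [AnnotationIndex-class].
#' @param window,maxTail,maxSub passed to [classifyIsomiR()].
#' @return [S4Vectors::DataFrame]: `sequence`, `mature`, `unit`, `category`,
#'   `offset5`, `offset3`, `tail`, plus the `counts` matrix. Unassignable
#'   tags are omitted (they stay in the residual bin).
#' @export
assignIsomiRs <- function(tags, index, window = 5L, maxTail = 5L,
                          maxSub = 2L) {
  sq <- tags$sequence
  keep <- !grepl("[^ACGT]", sq) & nchar(sq) >= 18L & nchar(sq) <= 28L
  emptyOut <- function() {
    out <- DataFrame(sequence = character(), mature = character(),
                     unit = character(), category = character(),
                     offset5 = integer(), offset3 = integer(),
                     tail = character())
    out$counts <- tags$counts[integer(0), , drop = FALSE]
    out
  }
  if (!any(keep)) return(emptyOut())
  cand <- .isomirCandidates(sq[keep], index)
  m <- cand$matures
  hpSeq <- as.character(index@hairpins)
  rows <- vector("list", length(sq))
  for (ii in which(keep)) {
    s <- sq[ii]
    a1 <- substr(s, 1L, 8L); a2 <- substr(s, nchar(s) - 7L, nchar(s))
    best <- NULL; bestKey <- NULL
    for (j in seq_len(nrow(m))) {
      hits <- cand$hpHit[[m$hairpin[j]]]
      if (!(a1 %in% hits) && !(a2 %in% hits)) next
      cl <- classifyIsomiR(s, hpSeq[[m$hairpin[j]]], m$start[j], m$end[j],
                           window = window, maxTail = maxTail,
                           maxSub = maxSub)
      if (cl$category == "unassigned") next
      key <- abs(cl$offset5) + abs(cl$offset3)
      if (is.null(best) || key < bestKey) {
        best <- c(cl, list(mature = m$name[j], unit = m$unit[j]))
        bestKey <- key
      }
    }
    if (!is.null(best))
      rows[[ii]] <- data.frame(
        sequence = s, mature = best$mature, unit = best$unit,
        category = best$category, offset5 = best$offset5,
        offset3 = best$offset3, tail = best$tail,
        stringsAsFactors = FALSE)
  }
  hit <- !vapply(rows, is.null, TRUE)
  if (!any(hit)) return(emptyOut())
  out <- DataFrame(do.call(rbind, rows[hit]))
  out$counts <- tags$counts[hit, , drop = FALSE]
  out
}

.ISOMIR_CATEGORIES <- c("canonical", "shifted", "substitution", "both_end",
                        "template_3p", "nontemplate_3p", "start_site")

#' Per-mature isomiR summary for one library
#'
#' Per-category read proportions, the number of distinct isomiR sequences,
#' and isomiR diversity expressed as dominance: the read count of the single
#' most abundant isomiR sequence (canonical or not) over the miRNA's total.
#' Matures with zero assigned reads in the library are omitted.
#'
#' @param assigned output of [assignIsomiRs()].
#' @param library library id.
#' @return data.frame: `mature`, `total`, one `prop_<category>` column per
#'   category, `n_distinct`, `dominance`.
#' @export
isomirSummary <- function(assigned, library) {
  cnt <- assigned$counts[, library]
  keepMat <- tapply(cnt, assigned$mature, sum)
  keepMat <- names(keepMat)[keepMat > 0]
  out <- lapply(keepMat, function(mt) {
    i <- assigned$mature == mt & cnt > 0
    tot <- sum(cnt[i])
    props <- vapply(.ISOMIR_CATEGORIES, function(cg)
      sum(cnt[i & assigned$category == cg]) / tot, 0)
    df <- data.frame(mature = mt, total = tot, stringsAsFactors = FALSE)
    for (cg in .ISOMIR_CATEGORIES) df[[paste0("prop_", cg)]] <- props[[cg]]
    df$n_distinct <- sum(i)
    df$dominance <- max(cnt[i]) / tot
    df
  })
  do.call(rbind, out)
}

#' 3' non-templated addition base composition
#'
#' Read-count-weighted proportions of the first non-templated tail base over
#' `{A, C, G, U}` across all `nontemplate_3p` records of a library.
#'
#' @param assigned output of [assignIsomiRs()].
#' @param library library id.
#' @return named numeric vector over A, C, G, U summing to 1; empty (with a
#'   warning) when the library has no NTA reads.
#' @export
ntaBaseComposition <- function(assigned, library) {
  i <- assigned$category == "nontemplate_3p" &
    assigned$counts[, library] > 0
  if (!any(i)) {
    .warnf("no 3' NTA reads in library '%s'", library)
    return(setNames(numeric(0), character(0)))
  }
  base <- substr(assigned$tail[i], 1L, 1L)
  w <- assigned$counts[i, library]
  tot <- tapply(w, factor(base, levels = c("A", "C", "G", "U")), sum,
                default = 0)
  as.vector(tot / sum(tot)) -> pr
  setNames(pr, c("A", "C", "G", "U"))
}

#' 5p/3p arm usage of a hairpin
#'
#' Compares raw canonical read counts of the 5p and 3p matures of one
#' hairpin in one library. The log2 ratio guards zero counts by the 0.01-RPM
#' convention (a zero count enters the ratio as 0.01 reads-per-million of the
#' library total). Significance is a two-sided exact binomial test of the 5p
#' count against proportion 0.5 of the arm total.
#'
#' @param x normalized [MirExperiment-class].
#' @param index An [AnnotationIndex-class].
#' @param hairpin hairpin id with both arms annotated.
#' @param library library id.
#' @return list: `count5p`, `count3p`, `log2Ratio`, `p`.
#' @export
armUsage <- function(x, index, hairpin, library) {
  m <- index@matures[index@matures$hairpin == hairpin, , drop = FALSE]
  u5 <- unique(m$unit[m$arm == "5p"]); u3 <- unique(m$unit[m$arm == "3p"])
  if (!length(u5) || !length(u3))
    .stopf("hairpin '%s' lacks an annotated arm", hairpin)
  raw <- assay(x, "raw")
  c5 <- sum(raw[u5, library]); c3 <- sum(raw[u3, library])
  tot <- libraryTotals(x)[[library]]
  toRpm <- function(k) if (k == 0) 0.01 else k / tot * 1e6
  ratio <- log2(toRpm(c5) / toRpm(c3))
  p <- if (c5 + c3 > 0) binom.test(c5, c5 + c3, p = 0.5)$p.value else NA_real_
  list(count5p = c5, count3p = c3, log2Ratio = ratio, p = p)
}

#' Arm-usage table over hairpins and libraries
#'
#' [armUsage()] applied to every both-arm hairpin that has expression of both
#' arms in every requested library (hairpins failing that filter are
#' skipped, mirroring the "expressed in all populations" rule).
#'
#' @param x normalized [MirExperiment-class].
#' @param index An [AnnotationIndex-class].
#' @param libraries library ids (default all).
#' @param requireExpressed keep only hairpins with both arms expressed
#'   (raw count > 0) in every library (default `TRUE`).
#' @return data.frame: `hairpin`, `library`, `count5p`, `count3p`,
#'   `log2Ratio`, `p`.
#' @export
armUsageTable <- function(x, index, libraries = colnames(x),
                          requireExpressed = TRUE) {
  hps <- unique(index@matures$hairpin)
  hps <- hps[armCategory(hps, index) == "both_arms"]
  rows <- list()
  for (h in hps) {
    us <- lapply(libraries, function(l) armUsage(x, index, h, l))
    if (requireExpressed &&
        !all(vapply(us, function(u) u$count5p > 0 && u$count3p > 0, TRUE)))
      next
    for (k in seq_along(libraries))
      rows[[length(rows) + 1L]] <- data.frame(
        hairpin = h, library = libraries[k], count5p = us[[k]]$count5p,
        count3p = us[[k]]$count3p, log2Ratio = us[[k]]$log2Ratio,
        p = us[[k]]$p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows) %||% data.frame(
    hairpin = character(), library = character(), count5p = numeric(),
    count3p = numeric(), log2Ratio = numeric(), p = numeric())
}
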