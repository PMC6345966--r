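#' Extract the miRNA family from a miRBase-style mature name
#'
#' Strips the species prefix (e.g. `ath-`), the `-5p`/`-3p` arm suffix, a
#' numeric locus variant (e.g. `-2`), and trailing lowercase locus letters, so
#' that `ath-miR160a-5p`, `ath-miR160b` and `ath-miR160c-3p` all map to
#' `miR160`.
#'
#' @param name character vector of mature miRNA names.
#' @return character vector of family names.
#' @examples
#' mirFamily(c("ath-miR160a-5p", "ath-miR168a", "ath-miR8183"))
#' @export
mirFamily <- function(name) {
  x <- sub("^[a-z]{3,4}-", "", name)
  x <- sub("[-_.](5p|3p)\\*?$", "", x)
  x <- sub("-[0-9]+$", "", x)
  sub("(?<=[0-9])[a-z]+$", "", x, perl = TRUE)
}

.armFromName <- function(name) {
  ifelse(grepl("[-_.]5p\\*?$", name), "5p",
         ifelse(grepl("[-_.]3p\\*?$", name), "3p", "unlabeled"))
}

# Hairpin name stem shared with a mature name: drop arm suffix and locus
# variant number, then match against hairpin ids case-insensitively (miRBase
# hairpins are MIR-cased).
.nameStem <- function(name) {
  tolower(sub("[-_.](5p|3p)\\*?$", "", name))
}

#' Load and index a miRBase-style annotation
#'
#' Reads mature and hairpin FASTA files (RNA or DNA alphabet; `U` and `T` are
#' unified), locates each mature on its hairpin by exact substring search, and
#' collapses identical mature sequences into single expression units so that
#' multi-locus matures are never counted twice.
#'
#' Hairpin assignment prefers a hairpin whose identifier shares the mature's
#' name stem; if none matches by name, any hairpin containing the sequence is
#' used. When a mature occurs at several positions in its hairpin the leftmost
#' is taken and a warning is issued. Matures with no matching hairpin are
#' recorded as orphans (excluded from isomiR analysis) with a warning.
#'
#' @param matureFasta,hairpinFasta paths to FASTA files, or `DNAStringSet`
#'   objects already in memory.
#' @return An [AnnotationIndex-class].
#' @export
loadAnnotation <- function(matureFasta, hairpinFasta) {
  readFa <- function(x, what) {
    if (is.character(x) && length(x) == 1L) {
      if (!file.exists(x)) .stopf("%s FASTA not found: %s", what, x)
      x <- tryCatch(readDNAStringSet(x),
                    error = function(e) .stopf("malformed %s FASTA: %s",
                                               what, conditionMessage(e)))
    }
    s <- setNames(.unifySeq(x), sub("\\s.*$", "", names(x)))
    if (any(!nzchar(names(s)))) .stopf("%s FASTA has unnamed records", what)
    s
  }
  mat <- readFa(matureFasta, "mature")
  hp  <- readFa(hairpinFasta, "hairpin")
  hpSet <- DNAStringSet(hp)

  hpStem <- tolower(names(hp))
  rows <- vector("list", length(mat))
  orphans <- character(0)
  for (i in seq_along(mat)) {
    nm <- names(mat)[i]
    sq <- mat[[i]]
    stem <- .nameStem(nm)
    cand <- which(startsWith(hpStem, stem) | startsWith(stem, hpStem))
    if (!length(cand)) cand <- seq_along(hp)
    hit <- NA_integer_; pos <- NA_integer_
    for (j in cand) {
      occ <- .occurrences(sq, hp[[j]])
      if (length(occ)) {
        if (length(occ) > 1L)
          .warnf("mature '%s' occurs %d times in hairpin '%s'; using leftmost",
                 nm, length(occ), names(hp)[j])
        hit <- j; pos <- occ[1L]
        break
      }
    }
    if (is.na(hit)) {
      orphans <- c(orphans, nm)
      next
    }
    rows[[i]] <- data.frame(
      name = nm, family = mirFamily(nm), arm = .armFromName(nm),
      hairpin = names(hp)[hit], start = pos,
      end = pos + nchar(sq) - 1L, sequence = sq,
      stringsAsFactors = FALSE)
  }
  if (length(orphans))
    .warnf("%d mature(s) with no matching hairpin recorded as orphans: %s",
           length(orphans), paste(orphans, collapse = ", "))
  matures <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(matures))
    matures <- data.frame(name = character(), family = character(),
                          arm = character(), hairpin = character(),
                          start = integer(), end = integer(),
                          sequence = character(), stringsAsFactors = FALSE)

  # Collapse identical mature sequences into expression units.
  uidx <- !duplicated(matures$sequence)
  units <- data.frame(
    unit = matures$name[uidx],
    sequence = matures$sequence[uidx],
    family = matures$family[uidx],
    stringsAsFactors = FALSE)
  units$members <- vapply(units$sequence, function(s)
    paste(matures$name[matures$sequence == s], collapse = ","), "")
  matures$unit <- units$unit[match(matures$sequence, units$sequence)]

  new("AnnotationIndex", hairpins = hpSet, matures = matures,
      units = units, orphans = orphans)
}

#' Arm-annotation category of a hairpin
#'
#' Classifies a hairpin by which arms carry annotated matures: `both_arms`
#' when 5p- and 3p-labeled matures both exist, `one_arm_5p`/`one_arm_3p` when
#' exactly one labeled arm exists, and `no_arm` when all matures are
#' unlabeled.
#'
#' @param hairpinId hairpin identifier(s) present in the index.
#' @param index An [AnnotationIndex-class].
#' @return character vector of categories.
#' @export
armCategory <- function(hairpinId, index) {
  vapply(hairpinId, function(h) {
    if (!h %in% names(index@hairpins)) .stopf("unknown hairpin '%s'", h)
    arms <- index@matures$arm[index@matures$hairpin == h]
    has5 <- "5p" %in% arms
    has3 <- "3p" %in% arms
    if (has5 && has3) "both_arms"
    else if (has5) "one_arm_5p"
    else if (has3) "one_arm_3p"
    else "no_arm"
  }, "", USE.NAMES = FALSE)
}

#' Write / read the annotation report
#'
#' The TSV report carries one row per mature: name, family, arm, hairpin,
#' start, end (1-based, closed) and sequence. Reading it back together with
#' the hairpin sequences reproduces the index exactly.
#'
#' @param index An [AnnotationIndex-class].
#' @param file path of the TSV report.
#' @return `writeAnnotationTable()` the file path, invisibly;
#'   `readAnnotationTable()` a rebuilt [AnnotationIndex-class].
#' @export
writeAnnotationTable <- function(index, file) {
  cols <- c("name", "family", "arm", "hairpin", "start", "end", "sequence")
  .writeTsv(index@matures[, cols], file)
}

#' @rdname writeAnnotationTable
#' @param hairpins `DNAStringSet` of precursor sequences (DNA or RNA).
#' @export
readAnnotationTable <- function(file, hairpins) {
  m <- read.delim(file, stringsAsFactors = FALSE)
  hp <- DNAStringSet(setNames(.unifySeq(hairpins), names(hairpins)))
  uidx <- !duplicated(m$sequence)
  units <- data.frame(unit = m$name[uidx], sequence = m$sequence[uidx],
                      family = m$family[uidx], stringsAsFactors = FALSE)
  units$members <- vapply(units$sequence, function(s)
    paste(m$name[m$sequence == s], collapse = ","), "")
  m$unit <- units$unit[match(m$sequence, units$sequence)]
  new("AnnotationIndex", hairpins = hp, matures = m, units = units,
      orphans = character(0))
}
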