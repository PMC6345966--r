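# Internal helpers shared across modules.

# Unify the alphabet: RNA -> DNA (U -> T), uppercase. miRBase mature files are
# RNA while genomes are DNA; everything internal is DNA.
.unifySeq <- function(x) {
  x <- toupper(as.character(x))
  gsub("U", "T", x, fixed = TRUE)
}

# Report a DNA string on the RNA alphabet (for user-facing base labels).
.toRNA <- function(x) gsub("T", "U", toupper(as.character(x)), fixed = TRUE)

.revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# Length of the common prefix of two strings.
.commonPrefixLen <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq)) neq[1L] - 1L else n
}

# All exact occurrence start positions of `pattern` in `subject` (characters).
.occurrences <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(integer(0))
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Concatenate a DNAStringSet into one subject with an N spacer long enough
# that no ACGT-only tag can match across a boundary.
.concatSpacer <- function(seqs, spacer = 40L) {
  sep <- strrep("N", spacer)
  DNAString(paste(as.character(seqs), collapse = sep))
}

# Which tags (character vector) occur as exact substrings of any sequence in
# `subjects` (DNAStringSet)? Tags containing non-ACGT letters never match.
.tagHits <- function(tags, subjects) {
  hit <- logical(length(tags))
  if (!length(tags) || !length(subjects)) return(hit)
  subj <- .concatSpacer(subjects)
  clean <- !grepl("[^ACGT]", tags)
  w <- nchar(tags)
  for (wi in unique(w[clean])) {
    idx <- which(clean & w == wi)
    pd <- PDict(DNAStringSet(tags[idx]))
    hit[idx] <- countPDict(pd, subj) > 0L
  }
  hit
}

.writeTsv <- function(df, file) {
  write.table(df, file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
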