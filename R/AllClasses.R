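#' AnnotationIndex: hairpin and mature miRNA annotation
#'
#' Holds hairpin precursor sequences, mature miRNA records located on their
#' hairpins (1-based closed coordinates), and the collapsed expression units
#' (identical mature sequences from different loci count as one unit, so reads
#' are never double-assigned).
#'
#' @slot hairpins [Biostrings::DNAStringSet] of precursor sequences.
#' @slot matures data.frame with columns `name`, `family`, `arm` (one of
#'   `"5p"`, `"3p"`, `"unlabeled"`), `hairpin`, `start`, `end` (1-based,
#'   closed), `sequence`, `unit`.
#' @slot units data.frame with one row per distinct mature sequence: `unit`,
#'   `sequence`, `family`, `members` (comma-separated mature names).
#' @slot orphans character; mature names with no matching hairpin, excluded
#'   from isomiR analysis.
#'
#' @seealso [loadAnnotation()]
#' @export
setClass("AnnotationIndex",
  representation(
    hairpins = "DNAStringSet",
    matures  = "data.frame",
    units    = "data.frame",
    orphans  = "character"
  )
)

setValidity("AnnotationIndex", function(object) {
  m <- object@matures
  need <- c("name", "family", "arm", "hairpin", "start", "end", "sequence", "unit")
  if (!all(need %in% names(m)))
    return(paste("matures must have columns:", paste(need, collapse = ", ")))
  if (nrow(m)) {
    if (!all(m$hairpin %in% names(object@hairpins)))
      return("every mature must map to a known hairpin")
    hp <- as.character(object@hairpins[m$hairpin])
    ok <- substr(hp, m$start, m$end) == m$sequence
    if (!all(ok))
      return("hairpin[start:end] must equal the mature sequence")
    if (!all(m$arm %in% c("5p", "3p", "unlabeled")))
      return("arm must be 5p, 3p or unlabeled")
  }
  if (anyDuplicated(object@units$sequence))
    return("expression units must have distinct sequences")
  TRUE
})

#' @describeIn AnnotationIndex-class number of mature records
#' @param x,object An `AnnotationIndex`.
#' @export
setMethod("length", "AnnotationIndex", function(x) nrow(x@matures))

setMethod("show", "AnnotationIndex", function(object) {
  cat("AnnotationIndex with", length(object@hairpins), "hairpins,",
      nrow(object@matures), "matures,", nrow(object@units),
      "expression units\n")
  if (length(object@orphans))
    cat("  orphans (no hairpin):", paste(object@orphans, collapse = ", "), "\n")
})

#' Accessors for AnnotationIndex
#'
#' @param x An [AnnotationIndex-class] object.
#' @return `hairpinSequences()` the precursor `DNAStringSet`; `matureTable()`
#'   the per-mature data.frame; `expressionUnits()` the collapsed-unit
#'   data.frame.
#' @export
hairpinSequences <- function(x) x@hairpins

#' @rdname hairpinSequences
#' @export
matureTable <- function(x) x@matures

#' @rdname hairpinSequences
#' @export
expressionUnits <- function(x) x@units

#' ReferencePools: ordered contaminant reference pools
#'
#' The genome plus the ordered list of RNA class pools used for sequential
#' (hierarchical) read classification. The pool order is fixed and explicit
#' because classification is first-match-wins.
#'
#' @slot genome [Biostrings::DNAStringSet].
#' @slot pools named list of `DNAStringSet`, in classification order.
#' @export
setClass("ReferencePools",
  representation(genome = "DNAStringSet", pools = "list")
)

setValidity("ReferencePools", function(object) {
  if (!length(object@genome)) return("genome must be non-empty")
  if (!length(object@pools)) return("at least one class pool is required")
  if (is.null(names(object@pools)) || any(names(object@pools) == ""))
    return("pools must be named")
  if (!all(vapply(object@pools, is, TRUE, class2 = "DNAStringSet")))
    return("each pool must be a DNAStringSet")
  TRUE
})

setMethod("show", "ReferencePools", function(object) {
  cat("ReferencePools:", length(object@genome), "genome sequence(s); pools:",
      paste(sprintf("%s(%d)", names(object@pools),
                    lengths(object@pools)), collapse = ", "), "\n")
})

#' Build a ReferencePools object
#'
#' @param genome `DNAStringSet` (or path to a FASTA file) of the genome.
#' @param ... named `DNAStringSet`s (or FASTA paths), in the order reads
#'   should be tested against them, e.g. `cDNA=`, `t_rRNA=`, `sno_snRNA=`,
#'   `tasiRNA=`.
#' @return A [ReferencePools-class] object.
#' @export
referencePools <- function(genome, ...) {
  load1 <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
      x <- readDNAStringSet(x)
    DNAStringSet(.unifySeq(x))
  }
  pools <- lapply(list(...), load1)
  new("ReferencePools", genome = load1(genome), pools = pools)
}

#' MirExperiment: miRNA expression container
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are collapsed
#' mature miRNA units and whose columns are sequencing libraries. Carries a
#' `"raw"` integer count assay and, after [normalizeRpm()], an `"rpm"` assay.
#' Library totals used as normalization denominators live in `colData`.
#'
#' @export
setClass("MirExperiment", contains = "SummarizedExperiment")

setValidity("MirExperiment", function(object) {
  if (!"raw" %in% assayNames(object)) return("assay 'raw' is required")
  raw <- assay(object, "raw")
  if (any(raw < 0)) return("raw counts must be non-negative")
  if ("rpm" %in% assayNames(object)) {
    if (any(assay(object, "rpm") < 0)) return("rpm must be non-negative")
  }
  TRUE
})

#' Accessors for MirExperiment
#'
#' @param x A [MirExperiment-class].
#' @return `rawCounts()` the integer count matrix; `rpm()` the
#'   reads-per-million matrix (error if [normalizeRpm()] has not been run);
#'   `libraryTotals()` the per-library denominator totals.
#' @export
rawCounts <- function(x) assay(x, "raw")

#' @rdname rawCounts
#' @export
rpm <- function(x) {
  if (!"rpm" %in% assayNames(x))
    .stopf("no 'rpm' assay: run normalizeRpm() first")
  assay(x, "rpm")
}

#' @rdname rawCounts
#' @export
libraryTotals <- function(x) {
  lt <- colData(x)$library_total
  if (is.null(lt)) .stopf("library totals not set: run normalizeRpm() first")
  setNames(lt, colnames(x))
}

setMethod("show", "MirExperiment", function(object) {
  callNextMethod()
  if ("rpm" %in% assayNames(object))
    cat("normalized: rpm (denominator:",
        metadata(object)$rpm_denominator %||% "?", ")\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' HairpinCandidate: a folded candidate miRNA precursor
#'
#' A genomic window around an abundant unannotated small RNA tag, folded into
#' a secondary structure and judged against miRNA duplex criteria.
#'
#' @slot locus `GRanges` of length one (the precursor window, strand-aware).
#' @slot precursor character; precursor sequence, 5' to 3'.
#' @slot matureSpan integer length-2; 1-based closed span of the putative
#'   mature on the precursor.
#' @slot structure character; dot-bracket string (empty until folded).
#' @slot mfe numeric; minimum free energy in kcal/mol (`NA` until folded).
#' @slot count numeric; summed read count of the mature tag.
#' @slot verdict logical; `NA` until validated.
#' @slot failureReasons character; violated criteria, empty when passing.
#' @slot geometry list; duplex geometry from [validateHairpin()].
#' @export
setClass("HairpinCandidate",
  representation(
    locus = "GRanges", precursor = "character", matureSpan = "integer",
    structure = "character", mfe = "numeric", count = "numeric",
    verdict = "logical", failureReasons = "character", geometry = "list"
  ),
  prototype(structure = "", mfe = NA_real_, verdict = NA,
            failureReasons = character(0), geometry = list())
)

setValidity("HairpinCandidate", function(object) {
  if (nzchar(object@structure) &&
      nchar(object@structure) != nchar(object@precursor))
    return("structure and precursor must have equal length")
  if (length(object@matureSpan) != 2L)
    return("matureSpan must be length 2")
  sp <- object@matureSpan
  if (sp[1L] < 1L || sp[2L] > nchar(object@precursor) || sp[1L] >= sp[2L])
    return("matureSpan out of precursor bounds")
  TRUE
})

setMethod("show", "HairpinCandidate", function(object) {
  cat("HairpinCandidate (", nchar(object@precursor), " nt precursor, mature ",
      object@matureSpan[1L], "-", object@matureSpan[2L], ", count ",
      object@count, ")\n", sep = "")
  if (nzchar(object@structure))
    cat("  mfe:", object@mfe, "kcal/mol\n")
  if (!is.na(object@verdict))
    cat("  verdict:", if (object@verdict) "pass" else
        paste("fail:", paste(object@failureReasons, collapse = ", ")), "\n")
})
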