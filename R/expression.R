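#' Build the miRNA x library count matrix
#'
#' Sums the counts of all miRNA-labeled tags assigned to each collapsed
#' expression unit, per library. Ambiguous tags (matching several units)
#' contribute once to each matched unit but are flagged so library totals can
#' be computed without double counting.
#'
#' Per-library totals are recorded in `colData`: `mirna_total` (miRNA-assigned
#' reads, ambiguous tags counted once) and `cleaned_total` (genome-mapped
#' reads surviving contaminant removal, i.e. miRNA + clean unassigned).
#'
#' @param classified output of [classifyHierarchical()].
#' @param index An [AnnotationIndex-class].
#' @param libraries library ids (default: all columns of the count matrix).
#' @return A [MirExperiment-class] with a `"raw"` assay.
#' @export
countMatrix <- function(classified, index, libraries = NULL) {
  libs <- libraries %||% colnames(classified$counts)
  units <- index@units
  raw <- matrix(0L, nrow = nrow(units), ncol = length(libs),
                dimnames = list(units$unit, libs))
  isMir <- classified$label == "miRNA"
  anyAmbig <- FALSE
  if (any(isMir)) {
    cc <- classified$counts[isMir, libs, drop = FALSE]
    asg <- strsplit(classified$assigned[isMir], ",", fixed = TRUE)
    for (i in seq_along(asg)) {
      u <- asg[[i]]
      raw[u, ] <- raw[u, ] + matrix(rep(cc[i, ], each = length(u)),
                                    nrow = length(u))
      if (length(u) > 1L) anyAmbig <- TRUE
    }
  }
  mirnaTotal <- colSums(
    classified$counts[isMir, libs, drop = FALSE])
  cleanedTotal <- colSums(
    classified$counts[classified$label %in% c("miRNA", "clean_unassigned"),
                      libs, drop = FALSE])
  se <- SummarizedExperiment(
    assays = list(raw = raw),
    rowData = DataFrame(unit = units$unit, family = units$family,
                        members = units$members, row.names = units$unit),
    colData = DataFrame(library = libs, mirna_total = mirnaTotal,
                        cleaned_total = cleanedTotal, row.names = libs))
  out <- new("MirExperiment", se)
  metadata(out)$has_ambiguous <- anyAmbig
  out
}

#' Construct a MirExperiment directly from a count matrix
#'
#' Convenience constructor for workflows that start from a pre-computed
#' unit x library count table (e.g. public tag-count files).
#'
#' @param raw integer matrix, units x libraries.
#' @param cleanedTotal optional per-library cleaned-read totals; defaults to
#'   the column sums of `raw`.
#' @param rowData optional per-unit annotation.
#' @return A [MirExperiment-class].
#' @export
mirExperiment <- function(raw, cleanedTotal = NULL, rowData = NULL) {
  raw <- as.matrix(raw)
  storage.mode(raw) <- "integer"
  cd <- DataFrame(library = colnames(raw),
                  mirna_total = colSums(raw),
                  cleaned_total = cleanedTotal %||% colSums(raw),
                  row.names = colnames(raw))
  se <- SummarizedExperiment(assays = list(raw = raw), colData = cd)
  if (!is.null(rowData)) rowData(se) <- rowData
  new("MirExperiment", se)
}

#' Reads-per-million normalization with the 0.01 zero rule
#'
#' Fills the `"rpm"` assay: `rpm = raw / library_total * 1e6`. Cells with a
#' raw count of zero are set to exactly 0.01 after normalization, so that
#' log2 fold changes are always defined.
#'
#' @param x A [MirExperiment-class].
#' @param denominator which per-library total to divide by: `"cleaned"`
#'   (genome-mapped minus contaminants; the default) or `"mirna"`
#'   (miRNA-assigned reads).
#' @param totals optional named numeric vector overriding the denominators.
#' @return `x` with the `"rpm"` assay and `colData$library_total` filled.
#' @export
normalizeRpm <- function(x, denominator = c("cleaned", "mirna"),
                         totals = NULL) {
  denominator <- match.arg(denominator)
  if (is.null(totals)) {
    col <- paste0(denominator, "_total")
    totals <- setNames(as.numeric(colData(x)[[col]]), colnames(x))
  } else {
    totals <- totals[colnames(x)]
  }
  bad <- which(!is.finite(totals) | totals <= 0)
  if (length(bad))
    .stopf("zero or missing %s denominator for library: %s", denominator,
           paste(colnames(x)[bad], collapse = ", "))
  raw <- assay(x, "raw")
  rpmv <- sweep(raw, 2L, totals, "/") * 1e6
  rpmv[raw == 0L] <- 0.01
  assays(x, withDimnames = FALSE)$rpm <- rpmv
  colData(x)$library_total <- totals
  metadata(x)$rpm_denominator <- denominator
  validObject(x)
  x
}

#' Detected miRNA set under the minimum-read rule
#'
#' A unit is detected within a scope of libraries when its summed raw count
#' over those libraries reaches `minReads` (default 10, the "at least ten
#' reads" rule).
#'
#' @param x A [MirExperiment-class].
#' @param libraries scope; default all libraries.
#' @param minReads detection threshold on pooled raw counts.
#' @return character vector of detected unit ids.
#' @export
detectedSet <- function(x, libraries = colnames(x), minReads = 10L) {
  raw <- assay(x, "raw")[, libraries, drop = FALSE]
  tot <- rowSums(raw)
  if (minReads <= 0L) rownames(x)[tot > 0] else rownames(x)[tot >= minReads]
}

#' Common / unique membership partition across populations
#'
#' Computes the Venn-style partition of detected units across named sets.
#' "Uniquely expressed" means present in exactly one set and absent from all
#' others.
#'
#' @param sets named list of character vectors (detected units per
#'   population).
#' @return list with `regions` (named counts per non-empty intersection
#'   region, names like `"A&B"`), `unique` (per-set unique counts), `common`
#'   (count present in every set) and `total` (size of the union).
#' @export
membershipPartition <- function(sets) {
  if (length(sets) < 2L) .stopf("need at least two sets")
  all <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) all %in% s, logical(length(all)))
  if (length(all) == 1L) memb <- matrix(memb, nrow = 1L,
                                        dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  regions <- table(key)
  uniq <- vapply(names(sets), function(nm) sum(key == nm), 0L)
  list(regions = setNames(as.integer(regions), names(regions)),
       unique = uniq,
       common = sum(rowSums(memb) == length(sets)),
       total = length(all))
}

#' Write the expression matrix report
#'
#' @param x A normalized [MirExperiment-class].
#' @param file output TSV path.
#' @return the file path, invisibly.
#' @export
writeExpressionTable <- function(x, file) {
  raw <- assay(x, "raw")
  df <- data.frame(unit = rownames(x),
                   family = rowData(x)$family %||% NA_character_,
                   stringsAsFactors = FALSE)
  for (l in colnames(x)) df[[paste0("raw_", l)]] <- raw[, l]
  if ("rpm" %in% assayNames(x)) {
    r <- assay(x, "rpm")
    for (l in colnames(x)) df[[paste0("rpm_", l)]] <- r[, l]
  }
  .writeTsv(df, file)
}
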