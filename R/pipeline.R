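#' Validate a pipeline configuration
#'
#' A configuration is a named list of input paths and thresholds. Required:
#' `fastq` (named vector, library id -> path), `matureFasta`, `hairpinFasta`,
#' `genomeFasta`, `pools` (named vector of FASTA paths in classification
#' order), `adapter`, `design` (data.frame or TSV path with `library`,
#' `population`, `condition`), `outDir`. Optional thresholds with their
#' defaults: `minLen` 18, `maxLen` 28, `minQual` 20, `maxMismatch` 0,
#' `minReads` 10, `deAlpha` 0.05, `fcGate` 1, `window` 5, `maxSub` 2,
#' `flank` 100, `minAbundance` 10, `nBoot` 1000, `seed` 1,
#' `rpmDenominator` "cleaned". Optional inputs: `climateTsv`, `gff3`,
#' `folder` (a folding engine; defaults to [viennaFolder()] when RNAfold is
#' available, otherwise novel-hairpin validation is skipped).
#'
#' @param config named list.
#' @return the config with defaults filled (validation errors otherwise).
#' @export
pipelineConfig <- function(config) {
  required <- c("fastq", "matureFasta", "hairpinFasta", "genomeFasta",
                "pools", "adapter", "design", "outDir")
  miss <- setdiff(required, names(config))
  if (length(miss))
    .stopf("config missing required key(s): %s", paste(miss, collapse = ", "))
  if (!nzchar(config$adapter)) .stopf("config: adapter must be non-empty")
  defaults <- list(minLen = 18L, maxLen = 28L, minQual = 20,
                   maxMismatch = 0L, minReads = 10L, deAlpha = 0.05,
                   fcGate = 1, window = 5L, maxSub = 2L, flank = 100L,
                   minAbundance = 10L, nBoot = 1000L, seed = 1L,
                   rpmDenominator = "cleaned")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.character(config$design))
    config$design <- read.delim(config$design, stringsAsFactors = FALSE)
  for (f in c("matureFasta", "hairpinFasta", "genomeFasta"))
    if (!file.exists(config[[f]])) .stopf("config: %s not found", f)
  config
}

#' Run the full small RNA pipeline
#'
#' Executes the stages in dependency order — annotation loading, trimming
#' and size filtering, hierarchical classification, quantification and RPM
#' normalization, detection and membership partition, pairwise differential
#' expression per population pair within condition, isomiR assignment and
#' summaries, arm usage, novel hairpin discovery (when a folding engine is
#' available), and climate PCA/correlation (when a climate table is given) —
#' writing one TSV per stage plus a human-readable summary into
#' `config$outDir`. The full threshold set is recorded in
#' `config_record.tsv` for reproducibility.
#'
#' @param config list accepted by [pipelineConfig()].
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config) {
  config <- pipelineConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outDir, ...)
  record <- config[!vapply(config, is.function, TRUE)]
  record <- record[vapply(record, function(x)
    is.character(x) || is.numeric(x), TRUE)]
  .writeTsv(data.frame(key = names(record),
                       value = vapply(record, function(x)
                         paste(x, collapse = ","), "")),
            out("config_record.tsv"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  index <- stage("annotation",
                 loadAnnotation(config$matureFasta, config$hairpinFasta))
  writeAnnotationTable(index, out("annotation.tsv"))

  trimmed <- stage("preprocess", trimAndFilter(
    config$fastq, config$adapter, minLen = config$minLen,
    maxLen = config$maxLen, minQual = config$minQual))

  pools <- stage("classification", do.call(referencePools, c(
    list(genome = config$genomeFasta), as.list(config$pools))))
  classified <- stage("classification", classifyHierarchical(
    trimmed$tags, pools, index, maxMismatch = config$maxMismatch))
  summ <- classificationSummary(classified, trimmed$totals)
  .writeTsv(summ, out("classification_summary.tsv"))
  cls <- data.frame(sequence = classified$sequence,
                    label = classified$label,
                    assigned = classified$assigned,
                    stringsAsFactors = FALSE)
  cls <- cbind(cls, as.data.frame(classified$counts))
  .writeTsv(cls, out("classification.tsv"))

  x <- stage("quantify", {
    m <- countMatrix(classified, index)
    normalizeRpm(m, denominator = config$rpmDenominator)
  })
  writeExpressionTable(x, out("expression.tsv"))

  design <- config$design
  pops <- unique(design$population[design$condition == "FD"])
  detected <- lapply(setNames(pops, pops), function(p) {
    libs <- design$library[design$population == p & design$condition == "FD"]
    detectedSet(x, libraries = libs, minReads = config$minReads)
  })
  partition <- if (length(detected) >= 2L) membershipPartition(detected)
  else NULL

  de <- list()
  for (cond in unique(design$condition)) {
    d <- design[design$condition == cond, , drop = FALSE]
    d <- d[!duplicated(d$population), , drop = FALSE]
    if (nrow(d) < 2L) next
    for (i in seq_len(nrow(d) - 1L)) for (j in seq((i + 1L), nrow(d))) {
      nm <- paste0(d$population[j], "_vs_", d$population[i], "_", cond)
      de[[nm]] <- diffExpression(x, d$library[i], d$library[j],
                                 minCount = config$minReads)
      .writeTsv(de[[nm]], out(paste0("de_", nm, ".tsv")))
    }
  }

  isomirs <- stage("isomir", assignIsomiRs(
    classified[classified$label %in% c("miRNA", "clean_unassigned",
                                       "unmapped_genome"), ],
    index, window = config$window, maxSub = config$maxSub))
  iso <- data.frame(sequence = isomirs$sequence, mature = isomirs$mature,
                    category = isomirs$category, offset5 = isomirs$offset5,
                    offset3 = isomirs$offset3, tail = isomirs$tail,
                    stringsAsFactors = FALSE)
  .writeTsv(cbind(iso, as.data.frame(isomirs$counts)), out("isomirs.tsv"))
  arms <- armUsageTable(x, index)
  .writeTsv(arms, out("arm_usage.tsv"))

  folder <- config$folder
  if (is.null(folder) && nzchar(Sys.which("RNAfold")))
    folder <- viennaFolder()
  novel <- NULL
  if (!is.null(folder)) {
    genome <- readDNAStringSet(config$genomeFasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    # candidate input: clean unassigned tags that are not isomiRs of an
    # annotated mature (those belong to known loci)
    novelTags <- classified[classified$label == "clean_unassigned" &
                              !classified$sequence %in% isomirs$sequence, ]
    novel <- stage("novel", novelHairpins(
      novelTags, genome, folder,
      geneModels = config$gff3, minAbundance = config$minAbundance,
      flank = config$flank))
    if (nrow(novel)) .writeTsv(novel, out("novel_candidates.tsv"))
  }

  climate <- NULL
  if (!is.null(config$climateTsv)) {
    tab <- readClimateTable(config$climateTsv)
    climate <- stage("climate", climatePCA(tab))
    .writeTsv(data.frame(site = rownames(climate$scores),
                         climate$scores), out("climate_scores.tsv"))
  }

  lines <- c(
    sprintf("libraries: %d (%d populations x %d conditions)",
            nrow(design), length(unique(design$population)),
            length(unique(design$condition))),
    sprintf("expression units: %d; detected (FD, pooled per population): %s",
            nrow(x), paste(sprintf("%s=%d", names(detected),
                                   lengths(detected)), collapse = " ")),
    if (!is.null(partition))
      sprintf("commonly expressed in all FD populations: %d; unique: %s",
              partition$common,
              paste(sprintf("%s=%d", names(partition$unique),
                            partition$unique), collapse = " ")),
    sprintf("DE comparisons: %s",
            paste(sprintf("%s=%d", names(de), vapply(de, function(d)
              nrow(significantDE(d, alpha = config$deAlpha,
                                 minLfc = config$fcGate)), 0L)),
              collapse = " ")),
    sprintf("isomiR-assigned tags: %d", nrow(isomirs)),
    if (!is.null(novel) && nrow(novel))
      sprintf("novel candidates: %d (%d pass)", nrow(novel),
              sum(novel$verdict)))
  writeLines(lines, out("summary.txt"))

  invisible(list(index = index, trimmed = trimmed, classified = classified,
                 expression = x, detected = detected, partition = partition,
                 de = de, isomirs = isomirs, arms = arms, novel = novel,
                 climate = climate, summaryLines = lines))
}
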