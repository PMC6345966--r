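#' Log2 fold change between two RPM values
#'
#' @param rpmA,rpmB normalized expression values (both strictly positive;
#'   guaranteed by the 0.01 zero rule). `rpmA` is the denominator.
#' @return `log2(rpmB / rpmA)`, vectorized.
#' @export
log2FoldChange <- function(rpmA, rpmB) {
  if (any(rpmA <= 0) || any(rpmB <= 0))
    .stopf("non-positive rpm: run normalizeRpm() (0.01 zero rule) first")
  log2(rpmB / rpmA)
}

#' Pearson chi-square test of differential expression between two libraries
#'
#' Forms the 2x2 contingency table `[[countA, totalA - countA], [countB,
#' totalB - countB]]` and computes the Pearson statistic (no continuity
#' correction by default) with a chi-square df = 1 p-value. The comparison is
#' flagged `tested = FALSE` when the read count is 10 or fewer in both
#' libraries; statistic and p are still reported.
#'
#' All arguments are vectorized and recycled.
#'
#' @param countA,countB per-library read counts of the unit.
#' @param totalA,totalB per-library total read counts.
#' @param minCount testing gate: tested only when a count exceeds `minCount`
#'   in at least one library (default 10).
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return data.frame with columns `chi2`, `p`, `tested`.
#' @examples
#' chisqDE(20, 1e6, 40, 1e6)
#' @export
chisqDE <- function(countA, totalA, countB, totalB, minCount = 10L,
                    correct = FALSE) {
  n <- max(length(countA), length(totalA), length(countB), length(totalB))
  a <- as.numeric(rep_len(countA, n)); ta <- as.numeric(rep_len(totalA, n))
  c_ <- as.numeric(rep_len(countB, n)); tb <- as.numeric(rep_len(totalB, n))
  if (any(a > ta) || any(c_ > tb)) .stopf("count exceeds library total")
  if (any(ta <= 0) || any(tb <= 0)) .stopf("library totals must be positive")
  b <- ta - a; d <- tb - c_
  N <- ta + tb
  num <- a * d - b * c_
  if (correct) num <- pmax(abs(num) - N / 2, 0)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(denom > 0, N * num^2 / denom, 0)
  p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  data.frame(chi2 = chi2, p = p,
             tested = a > minCount | c_ > minCount)
}

#' Pairwise differential expression table
#'
#' Runs [chisqDE()] and [log2FoldChange()] for every unit between two
#' libraries of a normalized [MirExperiment-class]. Library B over library A.
#'
#' @param x normalized [MirExperiment-class].
#' @param libA,libB library ids; `libA` is the denominator.
#' @param minCount testing gate passed to [chisqDE()].
#' @param correct Yates correction flag.
#' @param adjust p-adjustment method (default `"none"`; `"BH"` available).
#' @return data.frame: `unit`, `family`, `log2fc`, `chi2`, `p`, `padj`,
#'   `tested`.
#' @export
diffExpression <- function(x, libA, libB, minCount = 10L, correct = FALSE,
                           adjust = "none") {
  raw <- assay(x, "raw")
  r <- rpm(x)
  tot <- libraryTotals(x)
  de <- chisqDE(raw[, libA], tot[[libA]], raw[, libB], tot[[libB]],
                minCount = minCount, correct = correct)
  data.frame(unit = rownames(x),
             family = rowData(x)$family %||% NA_character_,
             log2fc = log2FoldChange(r[, libA], r[, libB]),
             chi2 = de$chi2, p = de$p,
             padj = p.adjust(de$p, method = adjust),
             tested = de$tested,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Significantly differentially expressed units
#'
#' Default gate: tested, `p < alpha` and `|log2fc| >= minLfc`.
#'
#' @param de output of [diffExpression()].
#' @param alpha significance level (default 0.05).
#' @param minLfc minimum absolute log2 fold change (default 1).
#' @param useAdjusted gate on `padj` instead of `p`.
#' @return the significant subset of `de`.
#' @export
significantDE <- function(de, alpha = 0.05, minLfc = 1, useAdjusted = FALSE) {
  p <- if (useAdjusted) de$padj else de$p
  de[de$tested & p < alpha & abs(de$log2fc) >= minLfc, , drop = FALSE]
}

#' Jaccard similarity of two detected-miRNA sets with a bootstrap CI
#'
#' Point estimate `|A n B| / |A u B|` on presence/absence, with a seeded
#' percentile bootstrap: the detected-unit universe (the union) is resampled
#' with replacement, the index recomputed on each resampled universe `nBoot`
#' times, and the 2.5/97.5 percentiles reported. Joint resampling keeps the
#' degenerate cases exact: identical sets give a CI of `[1, 1]`, disjoint
#' sets `[0, 0]`.
#'
#' @param setA,setB character vectors of detected units.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @return list: `point`, `ciLow`, `ciHigh`, `nBoot`.
#' @export
jaccardIndex <- function(setA, setB, nBoot = 1000L, seed = 1L) {
  setA <- unique(setA); setB <- unique(setB)
  if (!length(setA) && !length(setB))
    .stopf("Jaccard undefined: both sets empty")
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) return(NA_real_)
    length(intersect(a, b)) / u
  }
  point <- jac(setA, setB)
  universe <- union(setA, setB)
  boots <- numeric(nBoot)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)
  for (i in seq_len(nBoot)) {
    u <- unique(sample(universe, length(universe), replace = TRUE))
    boots[i] <- jac(intersect(u, setA), intersect(u, setB))
  }
  ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(point = point, ciLow = ci[1L], ciHigh = ci[2L], nBoot = nBoot)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Average-linkage clustering of libraries by expression profile
#'
#' Distance is `1 - Pearson r` between library profiles of `log2(rpm)` over
#' the chosen units; agglomeration is average linkage. Libraries are ordered
#' by id before clustering so leaf order is deterministic under ties.
#'
#' @param x normalized [MirExperiment-class] with at least 3 libraries.
#' @param units units to use (typically the commonly expressed set); default
#'   all.
#' @return an `hclust` object.
#' @export
clusterLibraries <- function(x, units = rownames(x)) {
  if (ncol(x) < 3L) .stopf("need at least 3 libraries")
  if (length(units) < 2L) .stopf("need at least 2 units")
  m <- log2(rpm(x)[units, sort(colnames(x)), drop = FALSE])
  sds <- apply(m, 2L, sd)
  if (any(sds == 0))
    .stopf("constant expression profile (zero variance) in library: %s",
           paste(colnames(m)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(m, method = "pearson"))
  hclust(d, method = "average")
}

#' Export a library dendrogram as Newick text
#'
#' @param hc `hclust` from [clusterLibraries()].
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogramNewick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Two-way ANOVA of expression by population and growing condition
#'
#' Fits `log2(rpm) ~ population * condition` per unit and reports type-II F
#' statistics and p-values for population (Pop), growing condition (TMT) and
#' their interaction. If any design cell is empty the interaction is dropped
#' with a warning. When all responses of a unit are equal, F is reported as 0
#' and p as 1 by convention.
#'
#' @param x normalized [MirExperiment-class].
#' @param design data.frame with columns `library`, `population`,
#'   `condition`; one row per library of `x` to include.
#' @param units units to test (default all).
#' @return data.frame: `unit`, `F_pop`, `p_pop`, `F_tmt`, `p_tmt`, `F_int`,
#'   `p_int`.
#' @export
anovaPopTmt <- function(x, design, units = rownames(x)) {
  need <- c("library", "population", "condition")
  if (!all(need %in% names(design)))
    .stopf("design needs columns: %s", paste(need, collapse = ", "))
  libs <- design$library
  if (!all(libs %in% colnames(x))) .stopf("design library absent from matrix")
  pop <- factor(design$population)
  tmt <- factor(design$condition)
  if (nlevels(pop) < 2L || nlevels(tmt) < 2L)
    .stopf("need at least 2 populations and 2 conditions")
  full <- !any(table(pop, tmt) == 0L)
  if (!full)
    .warnf("empty design cell: interaction dropped")
  m <- log2(rpm(x)[units, libs, drop = FALSE])
  out <- data.frame(unit = units, F_pop = NA_real_, p_pop = NA_real_,
                    F_tmt = NA_real_, p_tmt = NA_real_, F_int = NA_real_,
                    p_int = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(units)) {
    y <- m[i, ]
    if (sd(y) == 0) {
      out[i, -1L] <- c(0, 1, 0, 1, if (full) c(0, 1) else c(NA, NA))
      next
    }
    df <- data.frame(y = y, pop = pop, tmt = tmt)
    fit <- if (full) lm(y ~ pop * tmt, data = df) else
      lm(y ~ pop + tmt, data = df)
    tab <- tryCatch(car::Anova(fit, type = 2),
                    error = function(e) NULL)
    if (is.null(tab)) next
    gv <- function(term, col) {
      j <- match(term, rownames(tab))
      if (is.na(j)) NA_real_ else tab[j, col]
    }
    out$F_pop[i] <- gv("pop", "F value"); out$p_pop[i] <- gv("pop", "Pr(>F)")
    out$F_tmt[i] <- gv("tmt", "F value"); out$p_tmt[i] <- gv("tmt", "Pr(>F)")
    out$F_int[i] <- gv("pop:tmt", "F value")
    out$p_int[i] <- gv("pop:tmt", "Pr(>F)")
  }
  out
}

#' Units changing monotonically with altitude
#'
#' Given the low-to-mid and mid-to-high differential expression tables,
#' returns units with a significant positive log2 fold change in both steps
#' (increasing with altitude) and the mirrored decreasing set. "Significant"
#' uses the package's DE gate: tested, `p < alpha`, `|log2fc| >= minLfc`.
#'
#' @param deLowMid,deMidHigh outputs of [diffExpression()] for the low-vs-mid
#'   and mid-vs-high comparisons (higher-altitude library as numerator).
#' @param alpha,minLfc gate thresholds (defaults 0.05 and 1).
#' @return list with character vectors `increasing` and `decreasing`.
#' @export
altitudeMonotoneUnits <- function(deLowMid, deMidHigh, alpha = 0.05,
                                  minLfc = 1) {
  gate <- function(de, sign) {
    ok <- de$tested & de$p < alpha & sign * de$log2fc >= minLfc
    de$unit[ok]
  }
  list(
    increasing = intersect(gate(deLowMid, 1), gate(deMidHigh, 1)),
    decreasing = intersect(gate(deLowMid, -1), gate(deMidHigh, -1)))
}
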