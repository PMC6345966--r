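#' Standardized PCA of site-level bioclimatic variables
#'
#' Variables are standardized to zero mean and unit variance across sites
#' (obligatory with mixed units: degrees C, mm, radiation) and the
#' correlation-matrix PCA is computed. Constant variables are dropped with a
#' warning. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making reports reproducible.
#' With n sites at most n-1 components have nonzero variance, and variance
#' fractions over those components sum to 1.
#'
#' @param table numeric matrix or data.frame, sites x variables, no missing
#'   values; rownames are site ids.
#' @return list of class `climatePCA`: `scores` (site x component),
#'   `loadings` (variable x component), `varExplained` (fraction per
#'   retained component), `dropped` (constant variables removed).
#' @export
climatePCA <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x)) .stopf("climate table must be numeric")
  if (anyNA(x)) .stopf("climate table has missing values")
  if (nrow(x) < 2L) .stopf("need at least 2 sites")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  sds <- apply(x, 2L, sd)
  dropped <- colnames(x)[sds == 0]
  if (sum(sds == 0) == ncol(x)) .stopf("all variables are constant")
  if (length(dropped))
    .warnf("dropping constant variable(s): %s",
           paste(dropped, collapse = ", "))
  x <- x[, sds > 0, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  keep <- which(eig > max(eig) * 1e-10)
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 varExplained = eig[keep] / sum(eig[keep]),
                 dropped = dropped),
            class = "climatePCA")
}

#' @export
print.climatePCA <- function(x, ...) {
  cat("climatePCA:", nrow(x$scores), "sites,", nrow(x$loadings),
      "variables,", ncol(x$scores), "components\n")
  cat("  variance explained:",
      paste(sprintf("PC%d %.2f%%", seq_along(x$varExplained),
                    100 * x$varExplained), collapse = ", "), "\n")
  invisible(x)
}

# Average library expression per site.
.siteExpression <- function(x, siteMap) {
  r <- rpm(x)
  libs <- names(siteMap)
  if (!all(libs %in% colnames(r))) .stopf("siteMap library absent from matrix")
  sites <- unique(unname(siteMap))
  out <- sapply(sites, function(s)
    rowMeans(r[, libs[siteMap == s], drop = FALSE]))
  colnames(out) <- sites
  out
}

#' Correlate miRNA expression with principal-component scores
#'
#' Libraries are averaged within site; Pearson r and two-sided p are
#' reported per unit for the first two components. With only three sites the
#' p-values are reported but flagged low-power.
#'
#' @param pca a [climatePCA()] result.
#' @param x normalized [MirExperiment-class].
#' @param siteMap named character vector: library id -> site id (sites must
#'   match the PCA's score rownames).
#' @param units units to correlate (default all).
#' @return data.frame: `unit`, `r_pc1`, `p_pc1`, `r_pc2`, `p_pc2`,
#'   `low_power`. Zero-variance units get `NA` correlations.
#' @export
pcExpressionCorrelation <- function(pca, x, siteMap, units = rownames(x)) {
  ex <- .siteExpression(x, siteMap)[units, , drop = FALSE]
  sites <- rownames(pca$scores)
  if (!all(sites %in% colnames(ex))) .stopf("site mismatch with PCA scores")
  ex <- ex[, sites, drop = FALSE]
  n <- length(sites)
  corOne <- function(y, s) {
    if (sd(y) == 0 || sd(s) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(y, s))
    c(ct$estimate, ct$p.value)
  }
  res <- t(apply(ex, 1L, function(y) {
    c(corOne(y, pca$scores[, 1L]),
      if (ncol(pca$scores) >= 2L) corOne(y, pca$scores[, 2L])
      else c(NA_real_, NA_real_))
  }))
  data.frame(unit = units, r_pc1 = res[, 1L], p_pc1 = res[, 2L],
             r_pc2 = res[, 3L], p_pc2 = res[, 4L],
             low_power = n <= 3L, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Correlate miRNA expression with growing-season climate factors
#'
#' Pearson correlation of per-site expression with each growing-season
#' factor (average temperature AT, precipitation AP, radiation AR). A unit is
#' flagged for a factor when `|r|` exceeds `rThreshold` and the correlation
#' is significant at `alpha`; the flag records the sign (e.g. `"AT-"`).
#' `literalP = TRUE` applies the non-significance reading (`p > alpha`)
#' instead.
#'
#' @param x normalized [MirExperiment-class].
#' @param factors numeric matrix/data.frame, sites x factors.
#' @param siteMap named character vector: library -> site.
#' @param rThreshold correlation magnitude threshold (default 0.98).
#' @param alpha significance level (default 0.05).
#' @param literalP flag on `p > alpha` instead of `p < alpha`.
#' @param units units to test (default all).
#' @return data.frame with per-unit, per-factor `r_`, `p_` columns and a
#'   `flags` column (comma-separated, e.g. `"AR+,AT-"`).
#' @export
seasonFactorCorrelation <- function(x, factors, siteMap, rThreshold = 0.98,
                                    alpha = 0.05, literalP = FALSE,
                                    units = rownames(x)) {
  f <- as.matrix(factors)
  ex <- .siteExpression(x, siteMap)[units, , drop = FALSE]
  if (!all(rownames(f) %in% colnames(ex))) .stopf("site mismatch with factors")
  ex <- ex[, rownames(f), drop = FALSE]
  out <- data.frame(unit = units, stringsAsFactors = FALSE)
  flags <- rep("", length(units))
  for (fc in colnames(f)) {
    rs <- ps <- rep(NA_real_, length(units))
    for (i in seq_along(units)) {
      y <- ex[i, ]
      if (sd(y) == 0 || sd(f[, fc]) == 0) next
      ct <- suppressWarnings(cor.test(y, f[, fc]))
      rs[i] <- unname(ct$estimate); ps[i] <- ct$p.value
    }
    out[[paste0("r_", fc)]] <- rs
    out[[paste0("p_", fc)]] <- ps
    hit <- !is.na(rs) & abs(rs) > rThreshold &
      (if (literalP) ps > alpha else ps < alpha)
    fl <- paste0(fc, ifelse(rs > 0, "+", "-"))
    flags <- ifelse(hit, ifelse(nzchar(flags), paste(flags, fl, sep = ","),
                                fl), flags)
  }
  out$flags <- flags
  out
}

#' Read / write a long-format climate table
#'
#' The TSV format is long: columns `site`, `variable`, `value`.
#'
#' @param file TSV path.
#' @return `readClimateTable()` a sites x variables numeric matrix.
#' @export
readClimateTable <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  sites <- unique(d$site); vars <- unique(d$variable)
  m <- matrix(NA_real_, length(sites), length(vars),
              dimnames = list(sites, vars))
  m[cbind(match(d$site, sites), match(d$variable, vars))] <- d$value
  m
}

#' @rdname readClimateTable
#' @param table sites x variables numeric matrix.
#' @export
writeClimateTable <- function(table, file) {
  d <- data.frame(site = rep(rownames(table), ncol(table)),
                  variable = rep(colnames(table), each = nrow(table)),
                  value = as.vector(table), stringsAsFactors = FALSE)
  .writeTsv(d, file)
}
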