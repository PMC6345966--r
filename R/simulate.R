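#' Configuration for the synthetic small RNA study generator
#'
#' The defaults emulate a three-population altitudinal study: populations at
#' low/mid/high altitude sampled in the field (FD) in two years, the same
#' populations grown in a common glasshouse (GH), and one reference-accession
#' GH control — ten libraries. Hairpins are planted in a random-background
#' genome as perfect inverted repeats (27-bp stem, 8-nt loop) so that every
#' mature is an exact genome substring and every precursor is foldable.
#' Abundances are log-normal with planted population multipliers (including
#' monotone-with-altitude units), isomiR mixtures follow a seven-category
#' proportion vector, 3' tails are drawn from a base-weight vector with zero
#' guanosine by default, both-arm hairpins carry planted 5p/3p shares, and
#' contaminant and background fragments are mixed in at stated fractions.
#'
#' @param seed integer; fully determines all outputs.
#' @param nHairpins number of annotated hairpins (default 40: half no-arm,
#'   35% both-arm, the rest one-arm, mirroring typical arm-annotation
#'   frequencies).
#' @param librarySize reads per library (default 1e5, desk scale).
#' @param abundanceSdLog sd of the log-normal hairpin abundance (default
#'   0.8).
#' @param monotonePopMult per-population multipliers of the planted
#'   monotone-altitude units (default 1, 3, 9 for low, mid, high).
#' @param nMonotone number of planted monotone units (default 5).
#' @param isomirMix named category proportions (must sum to 1).
#' @param ntaWeights named base weights for 3' non-templated tails
#'   (A, C, G, U; G defaults to 0).
#' @param armShares 5p shares cycled over both-arm hairpins.
#' @param fractions named read-component fractions (`mirna`, `contaminant`,
#'   `background`, `novel`, `lowqual`, `emptyinsert`); must sum to 1.
#' @param adapter 3' adapter sequence appended to every read.
#' @param condMultGH glasshouse multipliers cycled over the planted
#'   condition-responsive both-arm hairpins (default 4 and 0.25).
#' @param nCondUnits number of condition-responsive hairpins (default 6).
#' @param populations,altitudes population labels and site altitudes (m).
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nHairpins = 40L,
                      librarySize = 1e5L,
                      abundanceSdLog = 0.8,
                      monotonePopMult = c(1, 3, 9),
                      nMonotone = 5L,
                      isomirMix = c(canonical = 0.72, shifted = 0.03,
                                    substitution = 0.01, both_end = 0.05,
                                    template_3p = 0.08,
                                    nontemplate_3p = 0.10,
                                    start_site = 0.01),
                      ntaWeights = c(A = 0.32, C = 0.30, G = 0, U = 0.38),
                      armShares = c(0.8, 0.67, 0.5, 0.33, 0.2),
                      fractions = c(mirna = 0.62, contaminant = 0.20,
                                    background = 0.13, novel = 0.02,
                                    lowqual = 0.02, emptyinsert = 0.01),
                      adapter = "TGGAATTCTCGGGTGCCAAGG",
                      condMultGH = c(4, 0.25),
                      nCondUnits = 6L,
                      populations = c("Deh", "Mun", "Chit"),
                      altitudes = c(Deh = 700, Mun = 2000, Chit = 3400)) {
  stopifnot(abs(sum(isomirMix) - 1) < 1e-9, abs(sum(fractions) - 1) < 1e-9,
            nHairpins >= 1L, all(ntaWeights >= 0), sum(ntaWeights) > 0)
  cfg <- list(seed = as.integer(seed), nHairpins = as.integer(nHairpins),
              librarySize = as.integer(librarySize),
              abundanceSdLog = abundanceSdLog,
              monotonePopMult = monotonePopMult, nMonotone = nMonotone,
              isomirMix = isomirMix, ntaWeights = ntaWeights,
              armShares = armShares, fractions = fractions,
              adapter = .unifySeq(adapter), condMultGH = condMultGH,
              nCondUnits = nCondUnits, populations = populations,
              altitudes = altitudes)
  class(cfg) <- c("simConfig", "list")
  cfg
}

.randSeq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# Perfect inverted-repeat precursor. Layout (1-based):
#   1-6 ext5 | 7-27 mature (5p) | 28-35 loop | 36-56 revcomp(mature) |
#   57-62 revcomp(ext5) | 63-74 unpaired 3' flank
# ext5[4] == "C" and loop[1] == "G" pin the template continuation after each
# arm's mature to G, so that G-free non-templated tails are never templated.
# The 12-nt 3' flank keeps any size-filtered fragment overlapping the 3p
# mature fully templated, as in real precursor annotations.
.makeHairpin <- function() {
  ext5 <- .randSeq(1L, 6L); substr(ext5, 4L, 4L) <- "C"
  mature <- .randSeq(1L, 21L)
  loop <- .randSeq(1L, 8L); substr(loop, 1L, 1L) <- "G"
  prec <- paste0(ext5, mature, loop, .revComp(mature), .revComp(ext5),
                 .randSeq(1L, 12L))
  list(precursor = prec, mature5p = mature,
       mature3p = substr(prec, 38L, 58L),
       structure = paste0(strrep("(", 27L), strrep(".", 8L),
                          strrep(")", 27L), strrep(".", 12L)))
}

#' Generate the synthetic reference: genome, annotation, pools, gene models
#'
#' @param cfg a [simConfig()].
#' @return list: `genome` (`DNAStringSet`), `hairpinFa`, `matureFa`
#'   (`DNAStringSet`s with miRBase-style names), `pools` (named list of
#'   `DNAStringSet`), `geneModels` (`GRanges` with gene/exon features),
#'   `novel` (data.frame of the two unannotated hairpins with genomic
#'   coordinates, expected origin labels and true structures), `hairpinInfo`,
#'   `unitTable` (generation units with hairpin spans and arm labels).
#' @export
simulateReference <- function(cfg) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  nH <- cfg$nHairpins
  nBoth <- max(1L, round(0.35 * nH))
  nOne5 <- max(0L, round(0.075 * nH))
  nOne3 <- max(0L, round(0.075 * nH))
  nNo <- nH - nBoth - nOne5 - nOne3
  class <- c(rep("both_arms", nBoth), rep("one_arm_5p", nOne5),
             rep("one_arm_3p", nOne3), rep("no_arm", nNo))

  hp <- replicate(nH, .makeHairpin(), simplify = FALSE)
  # one duplicated mature across the last two no-arm hairpins (collapse case)
  dupPair <- NULL
  if (nNo >= 2L) {
    i <- nH; j <- nH - 1L
    m <- hp[[j]]$mature5p
    ext5 <- .randSeq(1L, 6L); substr(ext5, 4L, 4L) <- "C"
    loop <- .randSeq(1L, 8L); substr(loop, 1L, 1L) <- "G"
    prec <- paste0(ext5, m, loop, .revComp(m), .revComp(ext5),
                   .randSeq(1L, 12L))
    hp[[i]] <- list(precursor = prec, mature5p = m,
                    mature3p = substr(prec, 38L, 58L),
                    structure = hp[[j]]$structure)
    dupPair <- c(j, i)
  }

  fam <- 1000L + seq_len(nH)
  letter <- rep("a", nH)
  if (!is.null(dupPair)) letter[dupPair[2L]] <- "b"
  if (!is.null(dupPair)) fam[dupPair[2L]] <- fam[dupPair[1L]]
  hpName <- sprintf("ath-MIR%d%s", fam, letter)
  base <- sprintf("ath-miR%d%s", fam, letter)

  matures <- list(); units <- list()
  for (k in seq_len(nH)) {
    h <- hp[[k]]
    addM <- function(nm, sq) matures[[length(matures) + 1L]] <<- c(nm, sq)
    if (class[k] == "both_arms") {
      addM(paste0(base[k], "-5p"), h$mature5p)
      addM(paste0(base[k], "-3p"), h$mature3p)
      units[[length(units) + 1L]] <- data.frame(
        unit = paste0(base[k], "-5p"), sequence = h$mature5p,
        hairpin = hpName[k], arm = "5p", start = 7L, end = 27L,
        stringsAsFactors = FALSE)
      units[[length(units) + 1L]] <- data.frame(
        unit = paste0(base[k], "-3p"), sequence = h$mature3p,
        hairpin = hpName[k], arm = "3p", start = 38L, end = 58L,
        stringsAsFactors = FALSE)
    } else if (class[k] == "one_arm_5p") {
      addM(paste0(base[k], "-5p"), h$mature5p)
      units[[length(units) + 1L]] <- data.frame(
        unit = paste0(base[k], "-5p"), sequence = h$mature5p,
        hairpin = hpName[k], arm = "5p", start = 7L, end = 27L,
        stringsAsFactors = FALSE)
    } else if (class[k] == "one_arm_3p") {
      addM(paste0(base[k], "-3p"), h$mature3p)
      units[[length(units) + 1L]] <- data.frame(
        unit = paste0(base[k], "-3p"), sequence = h$mature3p,
        hairpin = hpName[k], arm = "3p", start = 38L, end = 58L,
        stringsAsFactors = FALSE)
    } else {
      addM(base[k], h$mature5p)
      if (!is.null(dupPair) && k == dupPair[2L]) next  # collapses with pair
      units[[length(units) + 1L]] <- data.frame(
        unit = base[k], sequence = h$mature5p, hairpin = hpName[k],
        arm = "unlabeled", start = 7L, end = 27L, stringsAsFactors = FALSE)
    }
  }
  unitTable <- do.call(rbind, units)
  matureFa <- DNAStringSet(setNames(vapply(matures, `[`, "", 2L),
                                    vapply(matures, `[`, "", 1L)))
  hairpinFa <- DNAStringSet(setNames(
    vapply(hp, function(h) h$precursor, ""), hpName))

  # contaminant pools, all embedded in the genome
  pools <- list(
    cDNA = DNAStringSet(setNames(.randSeq(5L, 300L), paste0("cdna", 1:5))),
    t_rRNA = DNAStringSet(setNames(.randSeq(4L, 120L), paste0("trna", 1:4))),
    sno_snRNA = DNAStringSet(setNames(.randSeq(3L, 100L),
                                      paste0("sno", 1:3))),
    tasiRNA = DNAStringSet(setNames(.randSeq(2L, 80L), paste0("tasi", 1:2))))

  # two novel (unannotated) hairpins: one intronic, one intergenic
  nov <- replicate(2L, .makeHairpin(), simplify = FALSE)

  # genome assembly on one chromosome, tracking coordinates
  segs <- character(0); pos <- 0L
  at <- function(s) { segs <<- c(segs, s); p <- pos + 1L
                      pos <<- pos + nchar(s); p }
  # generous random spacing keeps miRNA loci sparse, as in a real genome,
  # so background fragments rarely overlap a hairpin
  at(.randSeq(1L, 500L))
  hpStart <- integer(nH)
  for (k in seq_len(nH)) {
    hpStart[k] <- at(hp[[k]]$precursor)
    at(.randSeq(1L, 1200L))
  }
  for (pl in pools) for (s in as.character(pl)) { at(s); at(.randSeq(1L, 120L)) }
  # gene with novel hairpin 1 inside its intron
  geneStart <- pos + 1L
  exon1 <- c(at(.randSeq(1L, 200L)), pos)
  at(.randSeq(1L, 60L))
  nov1Start <- at(nov[[1L]]$precursor)
  at(.randSeq(1L, 60L))
  exon2 <- c(at(.randSeq(1L, 200L)), pos)
  geneEnd <- pos
  at(.randSeq(1L, 400L))
  nov2Start <- at(nov[[2L]]$precursor)
  at(.randSeq(1L, 300L))
  genome <- DNAStringSet(setNames(paste(segs, collapse = ""), "chr1"))

  geneModels <- GRanges("chr1",
    IRanges(c(geneStart, exon1[1L], exon2[1L]),
            c(geneEnd, exon1[2L], exon2[2L])),
    type = c("gene", "exon", "exon"))

  novel <- data.frame(
    name = c("novel1", "novel2"),
    chrom = "chr1",
    start = c(nov1Start, nov2Start),
    end = c(nov1Start, nov2Start) + 73L,
    strand = "+",
    matureSeq = vapply(nov, function(h) h$mature5p, ""),
    precursor = vapply(nov, function(h) h$precursor, ""),
    structure = vapply(nov, function(h) h$structure, ""),
    origin = c("intronic", "intergenic"),
    stringsAsFactors = FALSE)

  list(genome = genome, hairpinFa = hairpinFa, matureFa = matureFa,
       pools = pools, geneModels = geneModels, novel = novel,
       hairpinInfo = data.frame(hairpin = hpName, class = class,
                                genomeStart = hpStart,
                                structure = vapply(hp, function(h)
                                  h$structure, ""),
                                stringsAsFactors = FALSE),
       unitTable = unitTable)
}

#' Generate read libraries and the ground-truth manifest
#'
#' Reads are drawn multinomially: component (miRNA / contaminant /
#' background / novel / low-quality / empty-insert), then for miRNA reads the
#' unit by abundance x population x condition multiplier, then the isomiR
#' category, then the variant sequence per category rule. Non-templated tail
#' bases follow the configured weights (never equal to the template
#' continuation). The adapter is appended to every read.
#'
#' Planted monotone-altitude units are single-arm hairpins whose abundance is
#' pinned to a moderate fixed weight so their planted fold changes dominate
#' compositional shifts; condition-responsive hairpins carry a glasshouse
#' multiplier. The manifest records every truth needed to score recovery.
#'
#' @param cfg a [simConfig()].
#' @param ref output of [simulateReference()] for the same config.
#' @return list: `reads` (per-library list of `data.frame(seq, qual)`),
#'   `manifest` (design, unit weights and multipliers, per-library true
#'   proportions, realized per-category counts, tail-base counts, component
#'   counts, planted unit ids, arm shares).
#' @export
simulateLibraries <- function(cfg, ref) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(cfg$seed + 1L)
  pops <- cfg$populations
  design <- rbind(
    data.frame(library = paste0(rep(pops, each = 2L), "_FD_",
                                rep(c(2013L, 2014L), length(pops))),
               population = rep(pops, each = 2L), condition = "FD",
               year = rep(c(2013L, 2014L), length(pops)),
               stringsAsFactors = FALSE),
    data.frame(library = paste0(pops, "_GH"), population = pops,
               condition = "GH", year = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(library = "Col0_GH", population = "Col0", condition = "GH",
               year = NA_integer_, stringsAsFactors = FALSE))

  ut <- ref$unitTable
  hpInfo <- ref$hairpinInfo
  hpSeq <- setNames(as.character(ref$hairpinFa), names(ref$hairpinFa))

  # per-hairpin abundance weights
  hw <- rlnorm(nrow(hpInfo), meanlog = 0, sdlog = cfg$abundanceSdLog)
  names(hw) <- hpInfo$hairpin
  # planted monotone units: first nMonotone no-arm hairpins, pinned weight
  noArmHp <- hpInfo$hairpin[hpInfo$class == "no_arm"]
  monotoneHp <- head(noArmHp, cfg$nMonotone)
  hw[monotoneHp] <- exp(cfg$abundanceSdLog * qnorm(0.3))
  monotoneUnits <- ut$unit[ut$hairpin %in% monotoneHp]
  # population-specific units: two only in the high-altitude population, one
  # only in the mid-altitude one (the low-altitude population has none)
  spare <- setdiff(noArmHp, monotoneHp)
  spare <- head(spare, max(0L, length(spare) - 2L))  # keep the collapse pair
  highOnlyHp <- head(spare, 2L)
  midOnlyHp <- head(setdiff(spare, highOnlyHp), 1L)
  # condition-responsive hairpins: first nCondUnits both-arm hairpins
  bothHp <- hpInfo$hairpin[hpInfo$class == "both_arms"]
  condHp <- head(bothHp, cfg$nCondUnits)
  condMult <- setNames(rep(1, nrow(hpInfo)), hpInfo$hairpin)
  condMult[condHp] <- rep_len(cfg$condMultGH, length(condHp))
  # 5p shares cycled over both-arm hairpins
  share5p <- setNames(rep_len(cfg$armShares, length(bothHp)), bothHp)

  popMult <- matrix(1, nrow(ut), length(pops) + 1L,
                    dimnames = list(ut$unit, c(pops, "Col0")))
  for (p in seq_along(pops))
    popMult[ut$hairpin %in% monotoneHp, pops[p]] <- cfg$monotonePopMult[p]
  high <- pops[length(pops)]; mid <- pops[max(1L, length(pops) - 1L)]
  popMult[ut$hairpin %in% highOnlyHp, setdiff(colnames(popMult), high)] <- 0
  popMult[ut$hairpin %in% midOnlyHp, setdiff(colnames(popMult), mid)] <- 0

  armFrac <- ifelse(ut$arm == "3p" & ut$hairpin %in% bothHp,
                    1 - share5p[ut$hairpin],
             ifelse(ut$arm == "5p" & ut$hairpin %in% bothHp,
                    share5p[ut$hairpin], 1))
  baseW <- hw[ut$hairpin] * armFrac

  libs <- design$library
  nU <- nrow(ut)
  trueProp <- matrix(0, nU, length(libs), dimnames = list(ut$unit, libs))
  for (k in seq_along(libs)) {
    w <- baseW * popMult[, design$population[k]]
    if (design$condition[k] == "GH") w <- w * condMult[ut$hairpin]
    trueProp[, k] <- w / sum(w)
  }

  mix <- cfg$isomirMix
  ntaW <- cfg$ntaWeights[c("A", "C", "G", "U")]
  bases <- c("A", "C", "G", "T")
  contBase <- vapply(seq_len(nU), function(i)
    substr(hpSeq[ut$hairpin[i]], ut$end[i] + 1L, ut$end[i] + 1L), "")

  lenProbFD <- c(.02, .03, .05, .30, .10, .12, .28, .04, .03, .02, .01)
  lenProbGH <- c(.02, .02, .04, .08, .08, .12, .52, .05, .03, .02, .02)
  genomeSeq <- as.character(ref$genome[[1L]])
  glen <- nchar(genomeSeq)
  poolSeqs <- unlist(lapply(ref$pools, as.character))

  # first tail base never equals the template continuation (that would be a
  # templated extension, not an NTA)
  drawTail <- function(k, cont) {
    first <- character(k)
    cv <- .toRNA(substr(cont, 1L, 1L))
    for (b in unique(cv)) {
      w <- ntaW
      if (b %in% names(w)) w[b] <- 0
      idx <- which(cv == b)
      first[idx] <- sample(names(w), length(idx), replace = TRUE, prob = w)
    }
    len2 <- runif(k) < 0.2
    second <- sample(names(ntaW), k, replace = TRUE, prob = ntaW)
    tail <- ifelse(len2, paste0(first, second), first)
    gsub("U", "T", tail, fixed = TRUE)
  }

  reads <- vector("list", length(libs)); names(reads) <- libs
  realized <- list(); tailBase <- list(); compCounts <- list()
  for (k in seq_along(libs)) {
    comp <- as.vector(rmultinom(1L, cfg$librarySize, cfg$fractions))
    names(comp) <- names(cfg$fractions)
    compCounts[[libs[k]]] <- comp

    # miRNA reads
    nm <- comp[["mirna"]]
    ui <- sample.int(nU, nm, replace = TRUE, prob = trueProp[, k])
    cg <- sample(names(mix), nm, replace = TRUE, prob = mix)
    hseq <- hpSeq[ut$hairpin[ui]]
    s <- ut$start[ui]; e <- ut$end[ui]
    canon <- substr(hseq, s, e)
    sq <- canon
    i <- which(cg == "shifted")
    if (length(i)) {
      d <- sample(c(-2L, -1L, 1L, 2L), length(i), replace = TRUE)
      sq[i] <- substr(hseq[i], s[i] + d, e[i] + d)
    }
    i <- which(cg == "template_3p")
    if (length(i)) {
      d <- sample(c(-2L, -1L, 1L, 2L), length(i), replace = TRUE)
      sq[i] <- substr(hseq[i], s[i], e[i] + d)
    }
    i <- which(cg == "start_site")
    if (length(i)) {
      d <- sample(c(-2L, -1L, 1L, 2L), length(i), replace = TRUE)
      sq[i] <- substr(hseq[i], s[i] + d, e[i])
    }
    i <- which(cg == "both_end")
    if (length(i)) {
      offs <- expand.grid(o5 = c(-2L, -1L, 1L, 2L), o3 = c(-2L, -1L, 1L, 2L))
      # distinct offsets, and the variant must survive the 18-nt size filter
      offs <- offs[offs$o5 != offs$o3 & 21L + offs$o3 - offs$o5 >= 18L, ]
      j <- sample.int(nrow(offs), length(i), replace = TRUE)
      sq[i] <- substr(hseq[i], s[i] + offs$o5[j], e[i] + offs$o3[j])
    }
    i <- which(cg == "nontemplate_3p")
    tb <- character(0)
    if (length(i)) {
      tails <- drawTail(length(i), contBase[ui[i]])
      sq[i] <- paste0(canon[i], tails)
      tb <- substr(.toRNA(tails), 1L, 1L)
    }
    i <- which(cg == "substitution")
    if (length(i)) {
      pos <- sample(5:15, length(i), replace = TRUE)
      orig <- substr(canon[i], pos, pos)
      newb <- bases[(match(orig, bases) - 1L +
                       sample.int(3L, length(i), replace = TRUE)) %% 4L + 1L]
      v <- canon[i]
      substr(v, pos, pos) <- newb
      sq[i] <- v
    }
    realized[[libs[k]]] <- as.data.frame(
      table(unit = ut$unit[ui], category = cg), stringsAsFactors = FALSE)
    tailBase[[libs[k]]] <- table(factor(tb, levels = c("A", "C", "G", "U")))

    # contaminants: random fragments of the class pools
    nc <- comp[["contaminant"]]
    ps <- sample(poolSeqs, nc, replace = TRUE)
    fl <- sample(18:28, nc, replace = TRUE)
    fs <- floor(runif(nc, 1, nchar(ps) - fl + 1))
    contam <- substr(ps, fs, fs + fl - 1L)

    # background: random genome fragments, condition-specific length mode
    nb <- comp[["background"]]
    lp <- if (design$condition[k] == "FD") lenProbFD else lenProbGH
    bl <- sample(18:28, nb, replace = TRUE, prob = lp)
    bs <- floor(runif(nb, 1, glen - bl + 1))
    backg <- substr(rep(genomeSeq, nb), bs, bs + bl - 1L)

    # novel-locus reads (exact mature tags, 60/40 split)
    nn <- comp[["novel"]]
    novTag <- sample(ref$novel$matureSeq, nn, replace = TRUE,
                     prob = c(0.6, 0.4))

    # low-quality reads and empty-insert (adapter-only) reads
    nl <- comp[["lowqual"]]
    lq <- .randSeq(nl, 21L)
    ne <- comp[["emptyinsert"]]
    emptyIns <- rep("", ne)

    inserts <- c(sq, contam, backg, novTag, lq, emptyIns)
    full <- paste0(inserts, cfg$adapter)
    qual <- strrep("I", nchar(full))
    lowIdx <- seq(nm + nc + nb + nn + 1L, length.out = nl)
    qual[lowIdx] <- strrep("#", nchar(full[lowIdx]))
    ord <- sample.int(length(full))
    reads[[libs[k]]] <- data.frame(seq = full[ord], qual = qual[ord],
                                   stringsAsFactors = FALSE)
  }

  manifest <- list(design = design, unitTable = ut, hairpinWeights = hw,
                   trueProp = trueProp, popMult = popMult,
                   condMult = condMult, share5p = share5p,
                   monotoneUnits = monotoneUnits, monotoneHairpins = monotoneHp,
                   uniqueUnits = list(
                     high = ut$unit[ut$hairpin %in% highOnlyHp],
                     mid = ut$unit[ut$hairpin %in% midOnlyHp]),
                   condHairpins = condHp, isomirMix = mix,
                   ntaWeights = cfg$ntaWeights, realized = realized,
                   tailBase = tailBase, componentCounts = compCounts)
  list(reads = reads, manifest = manifest)
}

#' Generate the synthetic bioclimatic table
#'
#' 22 variables over the configured sites: 19 bioclim-style variables plus
#' growing-season averages AT (temperature), AP (precipitation) and AR
#' (radiation). Temperature-like variables decrease strictly with altitude,
#' radiation-like increase strictly, precipitation-like peak at the middle
#' site.
#'
#' @param cfg a [simConfig()].
#' @return numeric matrix, sites x 22 variables.
#' @export
simulateClimate <- function(cfg) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(cfg$seed + 2L)
  alt <- cfg$altitudes / 1000
  sites <- names(cfg$altitudes)
  tempVars <- c(paste0("bio", 1:11), "AT")
  precVars <- c(paste0("bio", 12:19), "AP")
  radVars <- c("AR")
  m <- matrix(NA_real_, length(sites), 22L,
              dimnames = list(sites, c(tempVars, precVars, radVars)))
  for (v in tempVars) {
    base <- runif(1, 10, 30); slope <- runif(1, 2, 5)
    m[, v] <- base - slope * alt + runif(length(sites), -0.3, 0.3)
  }
  for (v in precVars) {
    base <- runif(1, 400, 1500); amp <- runif(1, 50, 200)
    m[, v] <- base + c(0, 1, -0.5) * amp + runif(length(sites), -10, 10)
  }
  for (v in radVars) {
    base <- runif(1, 10, 20); slope <- runif(1, 1, 3)
    m[, v] <- base + slope * alt + runif(length(sites), -0.1, 0.1)
  }
  m
}

#' Write the simulated study to disk
#'
#' Emits genome, hairpin and mature FASTA, contaminant pool FASTA, gene
#' models GFF3, one FASTQ per library, the climate TSV and the design TSV.
#'
#' @param ref [simulateReference()] output.
#' @param sim [simulateLibraries()] output.
#' @param climate [simulateClimate()] output (optional).
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
writeSimulatedData <- function(ref, sim, climate = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  writeXStringSet(ref$genome, p("genome.fa"))
  writeXStringSet(ref$hairpinFa, p("hairpin.fa"))
  writeXStringSet(ref$matureFa, p("mature.fa"))
  poolPaths <- character(0)
  for (nm in names(ref$pools)) {
    writeXStringSet(ref$pools[[nm]], p(paste0("pool_", nm, ".fa")))
    poolPaths[nm] <- p(paste0("pool_", nm, ".fa"))
  }
  gff <- ref$geneModels
  lines <- c("##gff-version 3",
             sprintf("%s\taltimiR\t%s\t%d\t%d\t.\t+\t.\tID=%s%d",
                     as.character(seqnames(gff)),
                     as.character(mcols(gff)$type),
                     start(gff), end(gff),
                     as.character(mcols(gff)$type), seq_along(gff)))
  writeLines(lines, p("genes.gff3"))
  fq <- character(0)
  for (lib in names(sim$reads)) {
    r <- sim$reads[[lib]]
    out <- character(4L * nrow(r))
    out[seq(1, length(out), 4)] <- paste0("@", lib, "_", seq_len(nrow(r)))
    out[seq(2, length(out), 4)] <- r$seq
    out[seq(3, length(out), 4)] <- "+"
    out[seq(4, length(out), 4)] <- r$qual
    writeLines(out, p(paste0(lib, ".fastq")))
    fq[lib] <- p(paste0(lib, ".fastq"))
  }
  .writeTsv(sim$manifest$design, p("design.tsv"))
  if (!is.null(climate)) writeClimateTable(climate, p("climate.tsv"))
  list(genome = p("genome.fa"), hairpin = p("hairpin.fa"),
       mature = p("mature.fa"), pools = poolPaths, gff = p("genes.gff3"),
       fastq = fq, design = p("design.tsv"),
       climate = if (!is.null(climate)) p("climate.tsv") else NULL)
}
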