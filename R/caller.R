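#' Insertion-caller parameters
#'
#' @param minTotal minimum total junction-supporting reads per call
#'   (default 4)
#' @param minSide minimum supporting reads on each side of the junction
#'   (default 2, reading the "about two reads per junction" rule as a
#'   per-side floor; set to 1 for the permissive reading)
#' @param window clustering window in bp; evidence of the same family within
#'   `window` is merged (default `insertMean + 2 * insertSd`)
#' @param crSpan half-width of the reference-read window around the junction
#'   (default: the read length)
#' @param crThreshold Coverage Ratio classification cutoff (default 2;
#'   `cr > crThreshold` is class `"gt2"`)
#' @param insertMean,insertSd library fragment-length model, used for
#'   discordant-pair geometry
#' @param excludePad evidence within this distance of an annotated
#'   pre-existing TE copy is excluded (default: `window`)
#' @return a parameter list of class `"CallerParams"`
#' @export
callerParams <- function(minTotal = 4L, minSide = 2L, window = NULL,
                         crSpan = NULL, crThreshold = 2,
                         insertMean = 250, insertSd = 30,
                         excludePad = NULL) {
  if (is.null(window)) window <- insertMean + 2 * insertSd
  if (is.null(excludePad)) excludePad <- window
  structure(list(minTotal = minTotal, minSide = minSide, window = window,
                 crSpan = crSpan, crThreshold = crThreshold,
                 insertMean = insertMean, insertSd = insertSd,
                 excludePad = excludePad),
            class = "CallerParams")
}

#' Gather junction evidence from a genome_split alignment
#'
#' Collects split-read evidence (genome-unique segment plus a clipped
#' remainder placed on a TE consensus or IGE sequence; base-precise junction
#' coordinate) and discordant-pair evidence (one mate genome-unique, the
#' other on a TE consensus, inside an annotated genomic TE copy, or inside
#' an IGE interval; insert-size-bounded interval). The side records which
#' flank of the putative insertion the genomic segment abuts. Evidence at
#' annotated pre-existing TE copies is excluded; if the bundle has no TE
#' annotation a warning is issued and nothing is excluded.
#'
#' @param aln an [AlignmentSet-class] from `genome_split` mode
#' @param bundle the [ReferenceBundle-class] used for alignment
#' @param params a [callerParams] list
#' @return a data.frame of evidence: `readId`, `chrom`, `pos` (0-based),
#'   `side`, `family`, `kind`, `vote`, `category`
#' @export
gatherEvidence <- function(aln, bundle, params = callerParams()) {
  stopifnot(aln@mode == "genome_split")
  rec <- aln@records
  w <- aln@readLength

  sp <- rec[rec$type == "split", , drop = FALSE]
  evSplit <- data.frame(readId = sp$readId, chrom = sp$target,
                        pos = sp$juncPos, side = sp$side,
                        family = sp$clipTarget, kind = "split_read",
                        vote = sp$clipStrand, category = sp$clipCategory)

  evDisc <- .discordantEvidence(aln, bundle, params)
  ev <- rbind(evSplit, evDisc)

  if (length(bundle@teAnnotation) == 0L) {
    warning("bundle has no reference TE annotation; ",
            "evidence at pre-existing copies cannot be excluded")
  } else if (nrow(ev)) {
    gr <- GenomicRanges::GRanges(ev$chrom,
                                 IRanges::IRanges(ev$pos + 1L, width = 1L))
    near <- GenomicRanges::countOverlaps(
      gr, bundle@teAnnotation + params$excludePad) > 0L
    ev <- ev[!near, , drop = FALSE]
  }
  ev[order(ev$chrom, ev$family, ev$pos), , drop = FALSE]
}

.discordantEvidence <- function(aln, bundle, params) {
  empty <- data.frame(readId = character(), chrom = character(),
                      pos = numeric(), side = character(),
                      family = character(), kind = character(),
                      vote = character(), category = character())
  rec <- aln@records
  full <- rec[rec$type == "full", , drop = FALSE]
  m1 <- full[full$mate == 1L, ]
  m2 <- full[full$mate == 2L, ]
  j <- match(m1$pairId, m2$pairId)
  ok <- !is.na(j)
  m1 <- m1[ok, ]; m2 <- m2[j[ok], ]
  if (nrow(m1) == 0L) return(empty)
  maxSpan <- params$insertMean + 4 * params$insertSd

  concord <- m1$category == "genome" & m2$category == "genome" &
    m1$target == m2$target & m1$strand != m2$strand &
    pmax(m1$start + m1$width, m2$start + m2$width) -
      pmin(m1$start, m2$start) <= maxSpan
  m1 <- m1[!concord, ]; m2 <- m2[!concord, ]
  if (nrow(m1) == 0L) return(empty)

  anno <- bundle@teAnnotation
  ige <- bundle@igeRanges
  out <- vector("list", 2L)
  for (k in 1:2) {
    anchor <- if (k == 1L) m1 else m2
    other <- if (k == 1L) m2 else m1
    isAnchor <- anchor$category == "genome"
    if (length(anno)) {
      agr <- GenomicRanges::GRanges(
        ifelse(isAnchor, anchor$target, "."),
        IRanges::IRanges(anchor$start + 1L, width = anchor$width))
      isAnchor <- isAnchor &
        GenomicRanges::countOverlaps(agr, anno) == 0L
    }
    # what does the other mate support?
    fam <- rep(NA_character_, nrow(other))
    cat <- rep(NA_character_, nrow(other))
    isTe <- other$category == "TE"
    fam[isTe] <- other$target[isTe]
    cat[isTe] <- "TE"
    isIgeEntry <- other$category == "IGE"
    fam[isIgeEntry] <- other$target[isIgeEntry]
    cat[isIgeEntry] <- "IGE"
    isGen <- other$category == "genome" & is.na(fam)
    if (any(isGen) && (length(anno) || length(ige))) {
      ogr <- GenomicRanges::GRanges(
        other$target[isGen],
        IRanges::IRanges(other$start[isGen] + 1L, width = other$width[isGen]))
      if (length(anno)) {
        ov <- GenomicRanges::findOverlaps(ogr, anno, select = "first")
        hit <- which(!is.na(ov))
        fam[which(isGen)[hit]] <- anno$family[ov[hit]]
        cat[which(isGen)[hit]] <- "TE"
      }
      if (length(ige)) {
        ov <- GenomicRanges::findOverlaps(ogr, ige, select = "first")
        hit <- which(!is.na(ov) & is.na(fam[isGen]))
        fam[which(isGen)[hit]] <- names(ige)[ov[hit]]
        cat[which(isGen)[hit]] <- "IGE"
      }
    }
    use <- isAnchor & !is.na(fam)
    if (!any(use)) next
    a <- anchor[use, ]
    side <- ifelse(a$strand == "+", "left", "right")
    pos <- ifelse(a$strand == "+", a$start + a$width, a$start)
    out[[k]] <- data.frame(readId = a$readId, chrom = a$target, pos = pos,
                           side = side, family = fam[use],
                           kind = "discordant_pair", vote = NA_character_,
                           category = cat[use])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

#' Cluster evidence and call insertions with the two-sided support rule
#'
#' Evidence of the same family within `window` bp is merged into one
#' candidate. A candidate is accepted iff its total support reaches
#' `minTotal` (default 4) AND both junction sides reach `minSide` (default
#' 2) -- the two-sided rule that suppresses one-sided artifact junctions.
#' The call position is the median split-read junction coordinate, falling
#' back to the median of discordant anchor positions; orientation is the
#' majority consensus-strand vote, `"."` on a tie.
#'
#' @param evidence data.frame from [gatherEvidence]
#' @param params a [callerParams] list
#' @return a data.frame of accepted calls (without Coverage Ratios; see
#'   [addCoverageRatio])
#' @export
clusterAndCall <- function(evidence, params = callerParams()) {
  empty <- data.frame(chrom = character(), pos = numeric(),
                      family = character(), orientation = character(),
                      iL = integer(), iR = integer(), i = integer(),
                      category = character())
  if (nrow(evidence) == 0L) return(empty)
  ev <- evidence[order(evidence$chrom, evidence$family, evidence$pos), ,
                 drop = FALSE]
  key <- paste(ev$chrom, ev$family)
  newGrp <- c(TRUE, key[-1] != key[-nrow(ev)] |
                diff(ev$pos) > params$window)
  grp <- cumsum(newGrp)
  out <- lapply(split(seq_len(nrow(ev)), grp), function(rows) {
    e <- ev[rows, , drop = FALSE]
    e <- e[!duplicated(paste(e$readId, e$side)), , drop = FALSE]
    iL <- sum(e$side == "left")
    iR <- sum(e$side == "right")
    i <- iL + iR
    if (i < params$minTotal || iL < params$minSide || iR < params$minSide)
      return(NULL)
    splitPos <- e$pos[e$kind == "split_read"]
    pos <- if (length(splitPos)) floor(median(splitPos)) else
      floor(median(e$pos))
    votes <- e$vote[!is.na(e$vote)]
    orientation <- if (length(votes) == 0L) "." else {
      np <- sum(votes == "+"); nm <- sum(votes == "-")
      if (np > nm) "+" else if (nm > np) "-" else "."
    }
    data.frame(chrom = e$chrom[1], pos = pos, family = e$family[1],
               orientation = orientation, iL = iL, iR = iR, i = i,
               category = e$category[1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Compute Coverage Ratios for accepted calls
#'
#' For each call, `r` counts the read pairs that span the junction cleanly:
#' both mates full-length on the genome, concordant, with the fragment
#' covering `[pos - crSpan, pos + crSpan]` and no TE signal. The Coverage
#' Ratio is `CR = i / (r + 1)` (insertion reads over reference reads plus a
#' pseudocount of 1); calls are classified `"gt2"` iff `CR > crThreshold`,
#' so the boundary CR = 2 is class `"le2"`.
#'
#' @param calls data.frame from [clusterAndCall]
#' @param aln the [AlignmentSet-class] the calls came from
#' @param params a [callerParams] list
#' @return `calls` with columns `r`, `cr`, `crClass` added
#' @export
addCoverageRatio <- function(calls, aln, params = callerParams()) {
  span <- if (is.null(params$crSpan)) aln@readLength else params$crSpan
  if (nrow(calls) == 0L) {
    calls$r <- integer(); calls$cr <- numeric()
    calls$crClass <- character()
    return(calls)
  }
  frags <- .concordantFragments(aln, params$insertMean + 4 * params$insertSd)
  r <- integer(nrow(calls))
  for (chrom in unique(calls$chrom)) {
    ci <- which(calls$chrom == chrom)
    fi <- frags$target == chrom
    if (!any(fi)) next
    fr <- IRanges::IRanges(frags$start0[fi] + 1L, frags$end0[fi])
    win <- IRanges::IRanges(calls$pos[ci] - span + 1L,
                            calls$pos[ci] + span)
    r[ci] <- IRanges::countOverlaps(win, fr, type = "within")
  }
  calls$r <- r
  calls$cr <- calls$i / (calls$r + 1)
  calls$crClass <- ifelse(calls$cr > params$crThreshold, "gt2", "le2")
  calls
}

#' Call TE insertions and build a sample's landscape
#'
#' Full caller pipeline: [gatherEvidence], [clusterAndCall],
#' [addCoverageRatio], wrapped into a [Landscape-class] whose normalization
#' denominator is the library's mapped reads.
#'
#' @param aln an [AlignmentSet-class] in `genome_split` mode
#' @param bundle the [ReferenceBundle-class]
#' @param sampleId sample label
#' @param params a [callerParams] list
#' @return a [Landscape-class]
#' @export
callInsertions <- function(aln, bundle, sampleId = "sample",
                           params = callerParams()) {
  ev <- gatherEvidence(aln, bundle, params)
  calls <- clusterAndCall(ev, params)
  calls <- addCoverageRatio(calls, aln, params)
  new("Landscape", sampleId = sampleId,
      mappedReads = as.numeric(mappedReads(aln)), calls = calls)
}

#' @rdname Landscape-class
#' @export
setMethod("teCalls", "Landscape", function(x)
  x@calls[x@calls$category == "TE", , drop = FALSE])
#' @rdname Landscape-class
#' @export
setMethod("igeCalls", "Landscape", function(x)
  x@calls[x@calls$category == "IGE", , drop = FALSE])
#' @rdname Landscape-class
#' @export
setMethod("insertionsPerMillion", "Landscape", function(x)
  1e6 * nrow(teCalls(x)) / x@mappedReads)
#' @rdname igeFpRate
#' @export
setMethod("igeFpRate", "Landscape", function(x) {
  nTe <- nrow(teCalls(x)); nIge <- nrow(igeCalls(x))
  if (nTe + nIge == 0L) 0 else nIge / (nTe + nIge)
})

setMethod("show", "Landscape", function(object) {
  cat("Landscape '", object@sampleId, "': ", nrow(teCalls(object)),
      " TE calls, ", nrow(igeCalls(object)), " IGE calls, ",
      format(object@mappedReads, big.mark = ","), " mapped reads (",
      round(insertionsPerMillion(object), 2), " TE insertions/M)\n",
      sep = "")
})

#' Write a landscape's calls as TSV (and a BED track)
#' @param landscape a [Landscape-class]
#' @param file TSV path; a `.bed` with the same stem is written alongside
#' @return invisibly, the TSV path
#' @export
writeLandscape <- function(landscape, file) {
  calls <- landscape@calls
  write.table(calls, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(calls)) {
    bed <- data.frame(chrom = calls$chrom, start = calls$pos,
                      end = calls$pos + 1L,
                      name = paste0(calls$family, "_", calls$crClass))
    write.table(bed, sub("\\.tsv$", ".bed", file), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}
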