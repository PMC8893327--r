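#' Circle plan for an eccDNA-enriched library
#'
#' Describes the circular molecules in a simulated eccDNA library: TE-derived
#' circles, spike-in plasmids (circular), and a residual linear background
#' emulating incomplete exonuclease digestion. The expected read share of a
#' circle is proportional to `copies * length`. Material present before gDNA
#' extraction (TE circles, the linear background and `pre_extraction`
#' plasmids) is additionally scaled by `extractionLoss`, while
#' `post_extraction` plasmids, which are added later, are not -- so the
#' post/pre spike-in ratio is a quality-control observable for recovery
#' differences between samples.
#'
#' @param circles data.frame with columns `source` (a TE family or plasmid
#'   name) and `copies` (>= 0)
#' @param linearBackgroundRate fraction of read pairs drawn from the linear
#'   genome, in [0, 1)
#' @param extractionLoss multiplicative recovery factor in (0, 1] applied to
#'   pre-extraction material
#' @return a validated list of class `"CirclePlan"`
#' @export
circlePlan <- function(circles, linearBackgroundRate = 0,
                       extractionLoss = 1) {
  stopifnot(is.data.frame(circles),
            all(c("source", "copies") %in% names(circles)),
            all(circles$copies >= 0),
            linearBackgroundRate >= 0, linearBackgroundRate < 1,
            extractionLoss > 0, extractionLoss <= 1)
  if (all(circles$copies == 0))
    stop("all-zero copy plan: at least one circle must have copies > 0")
  structure(list(circles = circles,
                 linearBackgroundRate = linearBackgroundRate,
                 extractionLoss = extractionLoss),
            class = "CirclePlan")
}

#' Default circle plan: every TE family plus the bundle's plasmid panel
#'
#' Plasmid copies are set to `relAbundance / length` (scaled) so that read
#' shares follow the manifest's relative mass, as they would for spike-ins
#' added by mass.
#'
#' @param bundle a [ReferenceBundle-class]
#' @param teCopies copies per TE family (recycled, default 50)
#' @param plasmidScale scale factor for plasmid copies
#' @param ... passed to [circlePlan]
#' @return a `"CirclePlan"`
#' @export
defaultCirclePlan <- function(bundle, teCopies = 50, plasmidScale = 2e5,
                              ...) {
  man <- bundle@plasmidManifest
  circles <- rbind(
    data.frame(source = names(bundle@teLibrary),
               copies = rep_len(teCopies, length(bundle@teLibrary))),
    data.frame(source = man$name,
               copies = plasmidScale * man$relAbundance / man$length))
  circlePlan(circles, ...)
}

#' Simulate an eccDNA-enriched paired-end library
#'
#' Fragments are drawn from circular coordinates (positions wrap, so reads
#' and mates may span the head-to-tail junction), with per-circle expected
#' read share proportional to `copies * length` after the extraction-loss
#' weighting described in [circlePlan]. A fraction `linearBackgroundRate`
#' of pairs is drawn from the linear genome instead.
#'
#' @param bundle a [ReferenceBundle-class]
#' @param plan a [circlePlan]
#' @param sp a [seqParams] (depth is ignored; `nPairs` sets library size)
#' @param nPairs number of read pairs
#' @return a [ReadPairSet-class]; truth records source circle and 0-based
#'   start on the circle
#' @export
simulateEccdna <- function(bundle, plan, sp, nPairs) {
  stopifnot(inherits(plan, "CirclePlan"), inherits(sp, "SeqParams"),
            nPairs >= 1L)
  set.seed(sp$seed)
  w <- sp$readLength

  pool <- c(bundle@teLibrary, bundle@plasmids)
  circ <- plan$circles
  if (!all(circ$source %in% names(pool)))
    stop("circle plan references unknown sources")
  clen <- Biostrings::width(pool)[match(circ$source, names(pool))]
  man <- bundle@plasmidManifest
  role <- man$role[match(circ$source, man$name)]
  pre <- is.na(role) | role == "pre_extraction"  # TE circles count as pre
  weight <- circ$copies * clen * ifelse(pre, plan$extractionLoss, 1)

  nBg <- as.integer(round(plan$linearBackgroundRate * nPairs))
  nCirc <- nPairs - nBg
  pick <- sample.int(nrow(circ), nCirc, replace = TRUE,
                     prob = weight / sum(weight))
  fl <- .fragLengths(nCirc, sp$insertMean, sp$insertSd, w)
  fl <- pmin(fl, clen[pick])
  q0 <- floor(runif(nCirc) * clen[pick])  # 0-based start on the circle

  # doubled sequences make wrap-around extraction a plain substring
  doubled <- Biostrings::DNAStringSet(paste0(as.character(pool),
                                             as.character(pool)))
  names(doubled) <- names(pool)
  frags <- Biostrings::DNAStringSet(rep("A", nCirc))
  srcIdx <- match(circ$source[pick], names(pool))
  for (si in unique(srcIdx)) {
    rows <- which(srcIdx == si)
    frags[rows] <- Biostrings::extractAt(
      doubled[[si]], IRanges::IRanges(start = q0[rows] + 1L,
                                      width = fl[rows]))
  }
  truth <- data.frame(source = circ$source[pick], start = q0, fragLen = fl,
                      circular = TRUE)

  if (nBg > 0L) {
    chroms <- names(bundle@genome)
    glen <- Biostrings::width(bundle@genome)
    ci <- sample.int(length(chroms), nBg, replace = TRUE,
                     prob = glen / sum(glen))
    bfl <- .fragLengths(nBg, sp$insertMean, sp$insertSd, w)
    bfl <- pmin(bfl, glen[ci])
    bs0 <- floor(runif(nBg) * (glen[ci] - bfl + 1L))
    bf <- Biostrings::DNAStringSet(rep("A", nBg))
    for (cc in unique(ci)) {
      rows <- which(ci == cc)
      bf[rows] <- Biostrings::extractAt(
        bundle@genome[[cc]], IRanges::IRanges(bs0[rows] + 1L,
                                              width = bfl[rows]))
    }
    frags <- c(frags, bf)
    truth <- rbind(truth, data.frame(source = chroms[ci], start = bs0,
                                     fragLen = bfl, circular = FALSE))
  }

  mates <- .fragToPairs(frags, w)
  r1 <- .addErrors(mates$r1, sp$errorRate)
  r2 <- .addErrors(mates$r2, sp$errorRate)
  ids <- sprintf("ecc%07d", seq_along(frags))
  names(r1) <- names(r2) <- ids
  truth <- data.frame(pair = ids, truth)
  ReadPairSet(r1, r2, truth)
}
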