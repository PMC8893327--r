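#' Align read pairs to the combined reference
#'
#' Maps every read against the combined reference (genome chromosomes, TE
#' consensus library, IGE sequences and plasmids) with the bundled
#' exact-match mapper. Two modes mirror the two mapping passes of a
#' TIDAL-style pipeline:
#'
#' * `"genome_split"`: full-length placement with genome priority on ties
#'   (a read matching a genomic TE copy and the consensus is placed on the
#'   genome), plus seed-and-extend recovery of soft-clipped junction reads
#'   whose genome-unique segment abuts a TE or IGE sequence. This mode feeds
#'   the insertion caller.
#' * `"consensus_end_to_end"`: full-length (end-to-end, no clipping)
#'   placement with consensus priority on ties; clipped reads count as
#'   unmapped. This mode feeds location-independent coverage profiling.
#'
#' Multi-mapping reads take a single best hit; ties break deterministically
#' by category priority, target order, then coordinate.
#'
#' @param pair a [ReadPairSet-class]
#' @param bundle a [ReferenceBundle-class]
#' @param mode `"genome_split"` or `"consensus_end_to_end"`
#' @param minClip minimum clipped-segment length for split evidence (bp)
#' @param seedLen anchor seed length for split mapping (bp)
#' @return an [AlignmentSet-class]
#' @export
alignReads <- function(pair, bundle,
                       mode = c("genome_split", "consensus_end_to_end"),
                       minClip = 15L, seedLen = 20L) {
  mode <- match.arg(mode)
  if (length(pair) == 0L) stop("empty read set")
  targets <- c(bundle@genome, bundle@teLibrary, bundle@igeSeqs,
               bundle@plasmids)
  categories <- c(rep("genome", length(bundle@genome)),
                  rep("TE", length(bundle@teLibrary)),
                  rep("IGE", length(bundle@igeSeqs)),
                  rep("plasmid", length(bundle@plasmids)))
  idx <- .buildIndex(targets, categories)

  reads <- c(firstReads(pair), secondReads(pair))
  n <- length(pair)
  readIds <- c(paste0(names(firstReads(pair)), "/1"),
               paste0(names(secondReads(pair)), "/2"))
  names(reads) <- readIds
  w <- unique(Biostrings::width(reads))
  if (length(w) != 1L)
    stop("the bundled mapper requires a constant read length")

  priority <- if (mode == "genome_split")
    c(genome = 1L, TE = 2L, IGE = 3L, plasmid = 4L)
  else
    c(TE = 1L, IGE = 2L, plasmid = 3L, genome = 4L)

  hits <- .allHits(reads, idx)
  best <- .bestHits(hits, idx, priority)
  full <- data.frame(readId = readIds[best$read],
                     pairId = rep(names(firstReads(pair)), 2L)[best$read],
                     mate = rep(1:2, each = n)[best$read],
                     target = idx$names[best$tIdx],
                     category = idx$category[best$tIdx],
                     start = best$local0, width = w,
                     strand = best$strand, type = "full",
                     juncPos = NA_integer_, side = NA_character_,
                     clipLen = NA_integer_, clipTarget = NA_character_,
                     clipCategory = NA_character_,
                     clipStrand = NA_character_)

  records <- full
  if (mode == "genome_split") {
    unmatchedIdx <- setdiff(seq_along(reads), best$read)
    if (length(unmatchedIdx)) {
      clipIdx <- .buildIndex(c(bundle@teLibrary, bundle@igeSeqs),
                             c(rep("TE", length(bundle@teLibrary)),
                               rep("IGE", length(bundle@igeSeqs))))
      sp <- .splitMap(reads[unmatchedIdx], idx, clipIdx,
                      minClip = minClip, seedLen = seedLen)
      if (nrow(sp)) {
        split <- data.frame(
          readId = sp$readId,
          pairId = sub("/[12]$", "", sp$readId),
          mate = as.integer(sub("^.*/", "", sp$readId)),
          target = idx$names[sp$tIdx], category = sp$clipCategory,
          start = ifelse(sp$side == "left", sp$juncPos - sp$segLen,
                         sp$juncPos),
          width = sp$segLen, strand = "+", type = "split",
          juncPos = sp$juncPos, side = sp$side, clipLen = sp$clipLen,
          clipTarget = sp$clipTarget, clipCategory = sp$clipCategory,
          clipStrand = sp$clipStrand)
        records <- rbind(records, split)
      }
    }
  }
  new("AlignmentSet", records = records, totalReads = 2L * n,
      mode = mode,
      targets = data.frame(name = idx$names, category = idx$category,
                           length = idx$lens),
      readLength = w)
}

#' @rdname AlignmentSet-class
#' @export
setMethod("alignmentRecords", "AlignmentSet", function(x) x@records)

#' @rdname AlignmentSet-class
#' @export
setMethod("mappedReads", "AlignmentSet", function(x) nrow(x@records))

#' @rdname AlignmentSet-class
#' @export
setMethod("categoryCounts", "AlignmentSet", function(x) {
  cats <- c("genome", "TE", "IGE", "plasmid")
  out <- setNames(integer(length(cats)), cats)
  tab <- table(x@records$category)
  out[names(tab)] <- as.integer(tab)
  out
})

setMethod("show", "AlignmentSet", function(object) {
  cat("AlignmentSet (", object@mode, "): ", nrow(object@records), " of ",
      object@totalReads, " reads mapped\n", sep = "")
  print(categoryCounts(object))
})

# concordant genome fragments (both mates full-length on the same
# chromosome, inward-facing, plausible span); used for reference-allele
# counting. Returns data.frame(target, start0, end0) half-open.
.concordantFragments <- function(aln, maxSpan) {
  rec <- aln@records
  fullGen <- rec[rec$type == "full" & rec$category == "genome", ,
                 drop = FALSE]
  m1 <- fullGen[fullGen$mate == 1L, ]
  m2 <- fullGen[fullGen$mate == 2L, ]
  j <- match(m1$pairId, m2$pairId)
  ok <- !is.na(j)
  m1 <- m1[ok, ]; m2 <- m2[j[ok], ]
  same <- m1$target == m2$target & m1$strand != m2$strand
  m1 <- m1[same, ]; m2 <- m2[same, ]
  s <- pmin(m1$start, m2$start)
  e <- pmax(m1$start + m1$width, m2$start + m2$width)
  span <- e - s
  # inward orientation: the leftmost mate must be on "+"
  leftPlus <- ifelse(m1$start <= m2$start, m1$strand, m2$strand) == "+"
  keep <- span <= maxSpan & leftPlus
  data.frame(target = m1$target[keep], start0 = s[keep], end0 = e[keep],
             pairId = m1$pairId[keep])
}
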