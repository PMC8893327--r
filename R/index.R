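# Internal exact-match read mapping engine.
#
# The bundled mapper places reads by exact substring matching (Aho-Corasick
# via Biostrings::PDict) against a concatenated reference padded with N
# spacers, on both strands, and recovers junction (split) reads by
# seed-and-extend from either read end. Exact matching is sufficient for the
# package's error-free simulations; with substitution errors enabled,
# error-bearing reads are reported unmapped (a documented limitation).

.SPACER <- 500L

# targets: DNAStringSet; categories: parallel character vector
.buildIndex <- function(targets, categories) {
  stopifnot(length(targets) == length(categories),
            !is.null(names(targets)))
  lens <- Biostrings::width(targets)
  pad <- strrep("N", .SPACER)
  chunks <- as.character(targets)
  subject <- Biostrings::DNAString(
    paste0(pad, paste(chunks, collapse = pad), pad))
  starts0 <- .SPACER + c(0L, cumsum(lens[-length(lens)] + .SPACER))
  list(targets = targets, category = categories, names = names(targets),
       lens = lens, starts0 = starts0, subject = subject,
       subjectRC = Biostrings::reverseComplement(subject),
       totalLen = length(subject))
}

# all exact full-width hits of constant-width reads on both strands;
# returns data.frame(read, tIdx, local0, strand)
.allHits <- function(reads, idx, strands = c("+", "-")) {
  w <- unique(Biostrings::width(reads))
  stopifnot(length(w) == 1L)
  pd <- Biostrings::PDict(reads)
  out <- vector("list", 2L)
  if ("+" %in% strands) {
    m <- Biostrings::matchPDict(pd, idx$subject)
    cnt <- S4Vectors::elementNROWS(m)
    concat0 <- IRanges::start(unlist(m)) - 1L
    out[[1]] <- data.frame(read = rep(seq_along(cnt), cnt),
                           concat0 = concat0, strand = "+")
  }
  if ("-" %in% strands) {
    m <- Biostrings::matchPDict(pd, idx$subjectRC)
    cnt <- S4Vectors::elementNROWS(m)
    p1 <- IRanges::start(unlist(m))
    out[[2]] <- data.frame(read = rep(seq_along(cnt), cnt),
                           concat0 = idx$totalLen - p1 - w + 1L,
                           strand = "-")
  }
  hits <- do.call(rbind, out)
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(read = integer(), tIdx = integer(),
                      local0 = integer(), strand = character()))
  tIdx <- findInterval(hits$concat0, idx$starts0)
  local0 <- hits$concat0 - idx$starts0[tIdx]
  keep <- tIdx >= 1L & local0 >= 0L & local0 + w <= idx$lens[tIdx]
  data.frame(read = hits$read[keep], tIdx = tIdx[keep],
             local0 = local0[keep], strand = hits$strand[keep])
}

# best hit per read under a category priority; ties broken by target order,
# coordinate, then strand, for determinism
.bestHits <- function(hits, idx, priority) {
  if (nrow(hits) == 0L) return(hits)
  prio <- priority[idx$category[hits$tIdx]]
  ord <- order(hits$read, prio, hits$tIdx, hits$local0, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$read), , drop = FALSE]
}

# length of common prefix between rows of two equal-dim character matrices
.commonPrefixLen <- function(a, b) {
  eq <- a == b
  w <- ncol(eq)
  firstBad <- apply(eq, 1L, function(row) {
    bad <- which(!row)
    if (length(bad)) bad[1] - 1L else w
  })
  as.integer(firstBad)
}

# seed-and-extend split mapping of unmatched reads.
# Returns data.frame(readId, tIdx (genome target), juncPos (0-based local),
# side, segLen, clipLen, clipTarget, clipCategory, clipStrand)
.splitMap <- function(reads, idx, clipIdx, minClip = 15L, seedLen = 20L) {
  empty <- data.frame(readId = character(), tIdx = integer(),
                      juncPos = integer(), side = character(),
                      segLen = integer(), clipLen = integer(),
                      clipTarget = character(), clipCategory = character(),
                      clipStrand = character())
  if (length(reads) == 0L) return(empty)
  w <- unique(Biostrings::width(reads))
  stopifnot(length(w) == 1L)
  if (w < seedLen + minClip) return(empty)
  readIds <- names(reads)

  cands <- list()
  for (orient in c("+", "-")) {
    o <- if (orient == "+") reads else Biostrings::reverseComplement(reads)
    ochar <- as.matrix(o)
    for (end in c("L", "R")) {
      seed <- if (end == "L") Biostrings::subseq(o, 1L, seedLen) else
        Biostrings::subseq(o, w - seedLen + 1L, w)
      hits <- .allHits(seed, idx, strands = "+")
      if (nrow(hits) == 0L) next
      # genome-unique anchors: exactly one genome hit, no repeat/plasmid hit;
      # IGE-entry hits are genome duplicates, not ambiguity
      cat <- idx$category[hits$tIdx]
      nGen <- tabulate(hits$read[cat == "genome"], nbins = length(o))
      nAmb <- tabulate(hits$read[cat %in% c("TE", "plasmid")],
                       nbins = length(o))
      hits <- hits[cat == "genome" & nGen[hits$read] == 1L &
                   nAmb[hits$read] == 0L, , drop = FALSE]
      if (nrow(hits) == 0L) next
      s0 <- idx$starts0[hits$tIdx] + hits$local0  # concat0 of seed start
      winStart0 <- if (end == "L") s0 else s0 + seedLen - w
      win <- Biostrings::extractAt(idx$subject,
                                   IRanges::IRanges(winStart0 + 1L,
                                                    width = w))
      winChar <- as.matrix(win)
      rChar <- ochar[hits$read, , drop = FALSE]
      if (end == "L") {
        segLen <- .commonPrefixLen(winChar, rChar)
      } else {
        segLen <- .commonPrefixLen(winChar[, w:1, drop = FALSE],
                                   rChar[, w:1, drop = FALSE])
      }
      keep <- segLen < w & (w - segLen) >= minClip
      if (!any(keep)) next
      hits <- hits[keep, , drop = FALSE]
      segLen <- segLen[keep]
      if (end == "L") {
        juncPos <- hits$local0 + segLen
        clip <- substr(apply(ochar[hits$read, , drop = FALSE], 1L, paste,
                             collapse = ""), segLen + 1L, w)
        side <- "left"
      } else {
        juncPos <- hits$local0 + seedLen - segLen
        clip <- substr(apply(ochar[hits$read, , drop = FALSE], 1L, paste,
                             collapse = ""), 1L, w - segLen)
        side <- "right"
      }
      cands[[length(cands) + 1L]] <-
        data.frame(read = hits$read, tIdx = hits$tIdx, juncPos = juncPos,
                   side = side, segLen = segLen, clipSeq = clip,
                   orient = orient)
    }
  }
  if (length(cands) == 0L) return(empty)
  cand <- do.call(rbind, cands)
  # one candidate per read: the longest genome anchor wins
  cand <- cand[order(cand$read, -cand$segLen, cand$side, cand$orient), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand$read), , drop = FALSE]

  hit <- .matchClips(cand$clipSeq, clipIdx, minClip)
  ok <- !is.na(hit$target)
  data.frame(readId = readIds[cand$read[ok]], tIdx = cand$tIdx[ok],
             juncPos = cand$juncPos[ok], side = cand$side[ok],
             segLen = cand$segLen[ok],
             clipLen = nchar(cand$clipSeq[ok]),
             clipTarget = hit$target[ok], clipCategory = hit$category[ok],
             clipStrand = hit$strand[ok])
}

# place variable-width clipped remainders on the TE/IGE library (both
# strands) requiring a full-length exact match; seeded by the first minClip
# bases. Returns target/category/strand per clip (NA when unplaced).
.matchClips <- function(clips, clipIdx, minClip) {
  n <- length(clips)
  res <- data.frame(target = rep(NA_character_, n),
                    category = rep(NA_character_, n),
                    strand = rep(NA_character_, n))
  if (n == 0L) return(res)
  wr <- nchar(clips)
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") clips else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(clips)))
    seeds <- Biostrings::DNAStringSet(substr(seqs, 1L, minClip))
    hits <- .allHits(seeds, clipIdx, strands = "+")
    if (nrow(hits) == 0L) next
    # verify the full remainder, not just the seed
    okLen <- hits$local0 + wr[hits$read] <= clipIdx$lens[hits$tIdx]
    hits <- hits[okLen, , drop = FALSE]
    if (nrow(hits) == 0L) next
    full <- as.character(Biostrings::extractAt(
      clipIdx$subject,
      IRanges::IRanges(clipIdx$starts0[hits$tIdx] + hits$local0 + 1L,
                       width = wr[hits$read])))
    hits <- hits[full == seqs[hits$read], , drop = FALSE]
    if (nrow(hits) == 0L) next
    prio <- match(clipIdx$category[hits$tIdx], c("TE", "IGE", "plasmid"))
    ord <- order(hits$read, prio, hits$tIdx, hits$local0)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits$read), , drop = FALSE]
    new <- is.na(res$target[hits$read])
    rows <- hits$read[new]
    res$target[rows] <- clipIdx$names[hits$tIdx[new]]
    res$category[rows] <- clipIdx$category[hits$tIdx[new]]
    res$strand[rows] <- strand
  }
  res
}
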