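#' Sequencing simulation parameters
#'
#' @param readLength read length in bp (>= 30)
#' @param insertMean,insertSd fragment-length mean and SD in bp; fragment
#'   lengths are truncated-normal with lower bound `readLength`
#' @param depth target per-base read depth X
#' @param errorRate per-base substitution error rate in [0, 1)
#' @param chimeraRate fraction of fragments that are artifactual chimeric
#'   molecules (see [simulateWGS])
#' @param seed RNG seed
#' @return a validated parameter list of class `"SeqParams"`
#' @export
seqParams <- function(readLength = 75L, insertMean = 250, insertSd = 30,
                      depth = 20, errorRate = 0, chimeraRate = 0,
                      seed = 1L) {
  stopifnot(readLength >= 30L, depth > 0,
            errorRate >= 0, errorRate < 1,
            chimeraRate >= 0, chimeraRate < 1,
            insertMean >= readLength)
  structure(list(readLength = as.integer(readLength),
                 insertMean = insertMean, insertSd = insertSd,
                 depth = depth, errorRate = errorRate,
                 chimeraRate = chimeraRate, seed = as.integer(seed)),
            class = "SeqParams")
}

# substitution errors over a constant-width DNAStringSet
.addErrors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  m <- as.matrix(reads)
  hit <- which(runif(length(m)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(m[hit], function(b) sample(setdiff(bases, b), 1L),
                   character(1))
    m[hit] <- repl
    reads <- Biostrings::DNAStringSet(apply(m, 1L, paste, collapse = ""))
  }
  reads
}

# mate sequences from fragment strings (R1 = 5' readLength bases,
# R2 = reverse complement of the 3' readLength bases)
.fragToPairs <- function(frags, w) {
  fl <- Biostrings::width(frags)
  r1 <- Biostrings::subseq(frags, start = 1L, width = w)
  r2 <- Biostrings::reverseComplement(
    Biostrings::subseq(frags, start = fl - w + 1L, width = w))
  list(r1 = r1, r2 = r2)
}

#' Simulate paired-end WGS of a pooled sample
#'
#' Draws `round(depth * genomeLength / (2 * readLength))` fragments, each
#' from a uniformly chosen haplotype (chromosome weighted by length, start
#' uniform), and reports both mates with a per-pair truth table. With
#' `chimeraRate > 0`, that fraction of fragments come from artifactual
#' chimeric molecules: recurrent fusion events joining a random genomic locus
#' to a random TE or IGE sequence. Chimeras recur at a seeded set of fusion
#' hotspots (as PCR-mediated chimeras do), so they can accumulate enough
#' junction reads to be called and thereby drive the IGE false-positive rate
#' above zero; the hotspot count scales with `chimeraRate`.
#'
#' @param sample a [SampleModel-class]
#' @param sp a [seqParams] object
#' @return a [ReadPairSet-class]; the truth table records the source
#'   haplotype/chromosome, fragment start (0-based) and length, and chimera
#'   provenance
#' @export
simulateWGS <- function(sample, sp) {
  stopifnot(inherits(sp, "SeqParams"))
  set.seed(sp$seed)
  w <- sp$readLength
  bundle <- sample@bundle
  glen <- sum(Biostrings::width(bundle@genome))
  nPairs <- as.integer(round(sp$depth * glen / (2 * w)))

  hapNames <- names(sample@haplotypes)
  hapLen <- Biostrings::width(sample@haplotypes)
  hapOf <- sub("\\..*$", "", hapNames)
  nHap <- length(unique(hapOf))
  chromW <- hapLen / rep(tapply(hapLen, hapOf, sum)[hapOf], 1L)

  nChim <- as.integer(round(sp$chimeraRate * nPairs))
  nReal <- nPairs - nChim

  # real fragments: haplotype uniform, chromosome by length, start uniform
  hapPick <- sample.int(nHap, nReal, replace = TRUE)
  seqIdx <- integer(nReal)
  for (h in unique(hapPick)) {
    rows <- which(hapPick == h)
    cand <- which(hapOf == sprintf("h%02d", h))
    seqIdx[rows] <- if (length(cand) == 1L) cand else
      cand[sample.int(length(cand), length(rows), replace = TRUE,
                      prob = chromW[cand])]
  }
  fl <- .fragLengths(nReal, sp$insertMean, sp$insertSd, w)
  fl <- pmin(fl, hapLen[seqIdx])
  start0 <- floor(runif(nReal) * (hapLen[seqIdx] - fl + 1L))  # 0-based
  ord <- order(seqIdx)
  frags <- Biostrings::DNAStringSet(rep("A", nReal))
  for (si in unique(seqIdx[ord])) {
    rows <- which(seqIdx == si)
    frags[rows] <- Biostrings::extractAt(
      sample@haplotypes[[si]],
      IRanges::IRanges(start = start0[rows] + 1L, width = fl[rows]))
  }

  truth <- data.frame(pair = seq_len(nReal),
                      source = hapNames[seqIdx],
                      start = start0, fragLen = fl,
                      chimeric = FALSE, hotspot = NA_character_)

  if (nChim > 0L) {
    ch <- .simChimeras(bundle, nChim, sp)
    frags <- c(frags, ch$frags)
    truth <- rbind(truth,
                   data.frame(pair = nReal + seq_len(nChim),
                              source = ch$hotspot, start = ch$start,
                              fragLen = Biostrings::width(ch$frags),
                              chimeric = TRUE, hotspot = ch$hotspot))
  }

  mates <- .fragToPairs(frags, w)
  r1 <- .addErrors(mates$r1, sp$errorRate)
  r2 <- .addErrors(mates$r2, sp$errorRate)
  ids <- sprintf("wgs%07d", seq_along(frags))
  names(r1) <- names(r2) <- ids
  truth$pair <- ids
  ReadPairSet(r1, r2, truth)
}

# chimeric molecules: a seeded panel of fusion hotspots, each emulating a
# spurious insertion of a TE or IGE sequence at a random genomic locus
.simChimeras <- function(bundle, nChim, sp, hotspotDensity = 1000) {
  w <- sp$readLength
  nHot <- max(1L, as.integer(round(sp$chimeraRate * hotspotDensity)))
  chroms <- names(bundle@genome)
  glen <- Biostrings::width(bundle@genome)
  partners <- c(names(bundle@teLibrary), names(bundle@igeSeqs))
  partnerIsIge <- c(rep(FALSE, length(bundle@teLibrary)),
                    rep(TRUE, length(bundle@igeSeqs)))
  # alternate TE/IGE partners so both categories are represented
  pick <- integer(nHot)
  teIdx <- which(!partnerIsIge); igIdx <- which(partnerIsIge)
  pick[seq_len(nHot) %% 2L == 1L] <-
    sample(teIdx, sum(seq_len(nHot) %% 2L == 1L), replace = TRUE)
  if (length(igIdx))
    pick[seq_len(nHot) %% 2L == 0L] <-
      sample(igIdx, sum(seq_len(nHot) %% 2L == 0L), replace = TRUE)
  else
    pick[pick == 0L] <- sample(teIdx, sum(pick == 0L), replace = TRUE)

  pad <- 1000L
  hotSeq <- vector("list", nHot)
  hotName <- character(nHot)
  for (k in seq_len(nHot)) {
    ci <- sample.int(length(chroms), 1L)
    pos <- sample.int(glen[ci] - 2L * pad, 1L) + pad
    pseq <- c(bundle@teLibrary, bundle@igeSeqs)[[partners[pick[k]]]]
    left <- Biostrings::extractAt(bundle@genome[[ci]],
                                  IRanges::IRanges(pos - pad + 1L, pos))
    right <- Biostrings::extractAt(bundle@genome[[ci]],
                                   IRanges::IRanges(pos + 1L, pos + pad))
    hotSeq[[k]] <- Biostrings::DNAString(paste0(
      as.character(left[[1]]), as.character(pseq), as.character(right[[1]])))
    hotName[k] <- sprintf("hot%03d:%s:%d:%s", k, chroms[ci], pos,
                          partners[pick[k]])
  }
  hotPick <- sample.int(nHot, nChim, replace = TRUE)
  fl <- .fragLengths(nChim, sp$insertMean, sp$insertSd, w)
  hl <- vapply(hotSeq, length, integer(1))[hotPick]
  fl <- pmin(fl, hl)
  start0 <- floor(runif(nChim) * (hl - fl + 1L))
  frags <- Biostrings::DNAStringSet(vapply(seq_len(nChim), function(i)
    as.character(Biostrings::subseq(hotSeq[[hotPick[i]]],
                                    start = start0[i] + 1L,
                                    width = fl[i])), character(1)))
  list(frags = frags, hotspot = hotName[hotPick], start = start0)
}
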