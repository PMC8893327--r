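evRow <- function(n, side, pos = 1000, family = "TEfam1",
                  kind = "split_read") {
  if (n == 0L) return(NULL)
  data.frame(readId = paste0(side, seq_len(n)), chrom = "chr1", pos = pos,
             side = side, family = family, kind = kind, vote = "+",
             category = "TE")
}

test_that("two-sided support rule gates acceptance", {
  p <- callerParams()
  accept <- rbind(evRow(2, "left"), evRow(2, "right"))
  expect_equal(nrow(clusterAndCall(accept, p)), 1L)     # 2 + 2 accepted
  tooFew <- rbind(evRow(2, "left"), evRow(1, "right"))
  expect_equal(nrow(clusterAndCall(tooFew, p)), 0L)     # 3 total rejected
  oneSided <- evRow(4, "left")
  expect_equal(nrow(clusterAndCall(oneSided, p)), 0L)   # 4 + 0 rejected
  # evidence of the same family within the window merges; outside it splits
  twoLoci <- rbind(evRow(3, "left", pos = 1000), evRow(3, "right", 1010),
                   evRow(3, "left", pos = 9000), evRow(3, "right", 9010))
  calls <- clusterAndCall(twoLoci, p)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$i, c(6L, 6L))
})

test_that("lowering thresholds never removes an accepted call", {
  ev <- gatherEvidence(tinyAln(), tinyBundle())
  strict <- clusterAndCall(ev, callerParams(minTotal = 4, minSide = 2))
  loose <- clusterAndCall(ev, callerParams(minTotal = 3, minSide = 1))
  key <- function(x) paste(x$chrom, x$pos, x$family)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("Coverage Ratio formula, pseudocount and boundary class", {
  # no concordant fragments at all -> r = 0, CR = i
  bareAln <- new("AlignmentSet",
                 records = data.frame(readId = character(),
                                      pairId = character(),
                                      mate = integer(), target = character(),
                                      category = character(),
                                      start = integer(), width = integer(),
                                      strand = character(),
                                      type = character(),
                                      juncPos = integer(),
                                      side = character(),
                                      clipLen = integer(),
                                      clipTarget = character(),
                                      clipCategory = character(),
                                      clipStrand = character()),
                 totalReads = 0L, mode = "genome_split",
                 targets = data.frame(name = "chr1", category = "genome",
                                      length = 100000L),
                 readLength = 75L)
  calls <- data.frame(chrom = "chr1", pos = 5000, family = "TEfam1",
                      orientation = "+", iL = 4L, iR = 4L, i = 8L,
                      category = "TE")
  out <- addCoverageRatio(calls, bareAln)
  expect_equal(out$r, 0L)
  expect_equal(out$cr, 8)
  expect_equal(out$crClass, "gt2")

  # fabricate exactly 4 clean spanning pairs -> CR = 10 / (4 + 1) = 2,
  # and the boundary CR = 2 is class le2 (cutoff is strictly greater-than)
  mk <- function(pid, s) rbind(
    data.frame(readId = paste0(pid, "/1"), pairId = pid, mate = 1L,
               target = "chr1", category = "genome", start = s,
               width = 75L, strand = "+", type = "full",
               juncPos = NA_integer_, side = NA_character_,
               clipLen = NA_integer_, clipTarget = NA_character_,
               clipCategory = NA_character_, clipStrand = NA_character_),
    data.frame(readId = paste0(pid, "/2"), pairId = pid, mate = 2L,
               target = "chr1", category = "genome", start = s + 175L,
               width = 75L, strand = "-", type = "full",
               juncPos = NA_integer_, side = NA_character_,
               clipLen = NA_integer_, clipTarget = NA_character_,
               clipCategory = NA_character_, clipStrand = NA_character_))
  rec <- do.call(rbind, lapply(1:4, function(k)
    mk(paste0("p", k), 4880L + k)))
  spanAln <- new("AlignmentSet", records = rec, totalReads = 8L,
                 mode = "genome_split", targets = bareAln@targets,
                 readLength = 75L)
  calls$i <- 10L
  out <- addCoverageRatio(calls, spanAln)
  expect_equal(out$r, 4L)
  expect_equal(out$cr, 2)
  expect_equal(out$crClass, "le2")
})

test_that("caller recovers planted insertions with no IGE calls", {
  ls <- tinyLandscape()
  tc <- teCalls(ls)
  plan <- tinyPlan()
  hit <- vapply(seq_len(nrow(plan)), function(i)
    any(tc$chrom == plan$chrom[i] & tc$family == plan$family[i] &
        abs(tc$pos - plan$pos[i]) <= 100), logical(1))
  expect_true(all(hit))
  expect_equal(nrow(tc), nrow(plan))       # no false positives
  expect_equal(nrow(igeCalls(ls)), 0L)
  expect_equal(igeFpRate(ls), 0)
  # orientation votes match the plan
  ord <- order(tc$pos); pord <- order(plan$pos)
  expect_equal(tc$orientation[ord], plan$orientation[pord])
  # determinism: identical alignments give identical call tables
  ls2 <- callInsertions(tinyAln(), tinyBundle(), sampleId = "tiny")
  expect_identical(ls2@calls, ls@calls)
  # no call sits at a pre-existing reference TE copy
  anno <- teAnnotation(tinyBundle())
  gr <- GenomicRanges::GRanges(tc$chrom,
                               IRanges::IRanges(tc$pos + 1L, width = 1L))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, anno + 300)), 0L)
})

test_that("split-read channel agrees with a brute-force junction scanner", {
  b <- tinyBundle()
  plan <- tinyPlan()[1:8, ]
  plan$penetrance <- c(1, 1, 1, 0.05, 1, 0.05, 0.05, 1)
  sm <- plantInsertions(b, plan, nIndividuals = 10, seed = 55)
  rp <- simulateWGS(sm, seqParams(depth = 15, seed = 56))
  aln <- alignReads(rp, b)
  ev <- gatherEvidence(aln, b)
  calls <- clusterAndCall(ev[ev$kind == "split_read", ], callerParams())

  # oracle: count reads (either mate, either strand) containing the exact
  # junction string with >= 20 bases of genome and >= 15 bases of TE
  reads <- c(firstReads(rp), secondReads(rp))
  g <- b@genome[[1]]
  countHits <- function(pat) {
    pat <- Biostrings::DNAString(pat)
    sum(Biostrings::vcountPattern(pat, reads)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                    reads))
  }
  for (i in seq_len(nrow(plan))) {
    te <- teLibrary(b)[[plan$family[i]]]
    if (plan$orientation[i] == "-") te <- Biostrings::reverseComplement(te)
    pos <- plan$pos[i]
    leftPat <- paste0(
      as.character(Biostrings::subseq(g, pos - 19, pos)),
      as.character(Biostrings::subseq(te, 1, 15)))
    rightPat <- paste0(
      as.character(Biostrings::subseq(te, length(te) - 14, length(te))),
      as.character(Biostrings::subseq(g, pos + 1, pos + 20)))
    nL <- countHits(leftPat); nR <- countHits(rightPat)
    oracleAccept <- (nL + nR >= 4) && nL >= 2 && nR >= 2
    callerAccept <- any(calls$chrom == plan$chrom[i] &
                        calls$family == plan$family[i] &
                        abs(calls$pos - pos) <= 100)
    expect_equal(callerAccept, oracleAccept,
                 info = paste("locus", pos, plan$family[i]))
  }
})

test_that("CR is non-decreasing in planted penetrance at fixed depth", {
  b <- tinyBundle()
  pen <- c(0.05, 0.25, 0.5, 1.0)
  plan <- randomInsertionPlan(b, 8, penetrance = rep(pen, each = 2),
                              seed = 66)
  sm <- plantInsertions(b, plan, nIndividuals = 10, seed = 67)
  rp <- simulateWGS(sm, seqParams(depth = 20, seed = 68))
  aln <- alignReads(rp, b)
  ev <- gatherEvidence(aln, b)
  # permissive clustering so every planted locus yields a candidate
  cand <- clusterAndCall(ev, callerParams(minTotal = 1, minSide = 0))
  cand <- addCoverageRatio(cand, aln)
  crOf <- vapply(seq_len(nrow(plan)), function(i) {
    row <- which(cand$chrom == plan$chrom[i] &
                 cand$family == plan$family[i] &
                 abs(cand$pos - plan$pos[i]) <= 150)
    if (length(row)) max(cand$cr[row]) else 0
  }, numeric(1))
  meanCr <- tapply(crOf, plan$penetrance, mean)
  expect_true(all(diff(meanCr[order(as.numeric(names(meanCr)))]) >= 0))
  # and the pooled-sample semantics: full penetrance scores deep (CR > 2),
  # rare insertions score shallow (CR <= 2)
  expect_true(all(crOf[plan$penetrance == 1] > 2))
  expect_true(all(crOf[plan$penetrance == 0.05] <= 2))
})

test_that("IGE false-positive rate formula", {
  ls <- makeLandscape(data.frame(
    pos = seq(1000, by = 2000, length.out = 100),
    category = rep(c("TE", "IGE"), c(88, 12)),
    family = rep(c("TEfam1", "IGE001"), c(88, 12))))
  expect_equal(igeFpRate(ls), 0.12)
  expect_equal(igeFpRate(makeLandscape(data.frame(pos = numeric(0)))), 0)
  expect_equal(insertionsPerMillion(ls), 88)
})
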