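test_that("reference builder is deterministic and validates its inputs", {
  b1 <- buildReference(1e5, nTeFamilies = 2L, nIge = 5L, seed = 7)
  b2 <- buildReference(1e5, nTeFamilies = 2L, nIge = 5L, seed = 7)
  expect_identical(as.character(b1@genome), as.character(b2@genome))
  expect_identical(as.character(b1@teLibrary), as.character(b2@teLibrary))
  d <- withr::local_tempdir()
  writeReferenceBundle(b1, d)
  writeReferenceBundle(b2, file.path(d, "b2"))
  expect_identical(readLines(file.path(d, "genome.fa")),
                   readLines(file.path(d, "b2", "genome.fa")))
  expect_equal(nrow(read.table(file.path(d, "ige.bed"))), 5L)

  b3 <- buildReference(1e5, nTeFamilies = 2L, nIge = 5L, seed = 8)
  expect_false(identical(as.character(b1@genome), as.character(b3@genome)))

  expect_error(buildReference(50), "100 kb")
  # IGEs are genome substrings at their recorded intervals
  ir <- igeRanges(b1)
  expect_identical(
    as.character(Biostrings::extractAt(
      b1@genome[[1]], IRanges::ranges(ir))[[2]]),
    as.character(b1@igeSeqs[[2]]))
  # each family has a pre-existing full-length genomic copy
  anno <- teAnnotation(b1)
  expect_setequal(anno$family, names(teLibrary(b1)))
  copy <- Biostrings::extractAt(b1@genome[[1]],
                                IRanges::ranges(anno[1]))[[1]]
  expect_identical(as.character(copy),
                   as.character(teLibrary(b1)[[anno$family[1]]]))
})

test_that("planted penetrance is exactly round(p * 2N) / 2N", {
  b <- tinyBundle()
  plan <- data.frame(chrom = "chr1", pos = c(20000, 50000),
                     family = c("TEfam1", "TEfam2"),
                     penetrance = c(1.0, 0.05))
  sm <- plantInsertions(b, plan, nIndividuals = 10, seed = 1)
  tt <- truthTable(sm)
  expect_equal(tt$nCarriers, c(20L, 1L))
  # carrier haplotypes really contain the insertion sequence
  carrier <- as.integer(strsplit(tt$carriers[2], ",")[[1]])
  hap <- haplotypes(sm)[[sprintf("h%02d.chr1", carrier)]]
  # the p = 1 insertion is in every haplotype; only carriers add entry 2
  expect_equal(length(hap), 1e5 + sum(tt$teLength))
  noncarrier <- setdiff(1:20, carrier)[1]
  expect_equal(length(haplotypes(sm)[[sprintf("h%02d.chr1", noncarrier)]]),
               1e5 + tt$teLength[1])
})

test_that("insertion plans violating spacing or bounds are rejected", {
  b <- tinyBundle()
  close <- data.frame(chrom = "chr1", pos = c(1000, 1050),
                      family = "TEfam1", penetrance = 1)
  expect_error(plantInsertions(b, close, 10), "closer than")
  outside <- data.frame(chrom = "chr1", pos = 2e5, family = "TEfam1",
                        penetrance = 1)
  expect_error(plantInsertions(b, outside, 10), "within their chromosome")
  badFam <- data.frame(chrom = "chr1", pos = 1000, family = "nope",
                       penetrance = 1)
  expect_error(plantInsertions(b, badFam, 10), "unknown TE families")
})

test_that("WGS simulator: pair-count arithmetic, determinism, closure", {
  # pair count = depth * L / (2 * readLength), within 1%
  expected <- 15 * 1e5 / (2 * 75)
  expect_lt(abs(length(tinyWgs()) - expected) / expected, 0.01)

  sp <- seqParams(depth = 2, seed = 42)
  rpA <- simulateWGS(tinySample(), sp)
  rpB <- simulateWGS(tinySample(), sp)
  expect_identical(as.character(firstReads(rpA)),
                   as.character(firstReads(rpB)))
  d <- withr::local_tempdir()
  writeFastqPair(rpA, file.path(d, "a"))
  writeFastqPair(rpB, file.path(d, "b"))
  expect_identical(readLines(file.path(d, "a_1.fastq")),
                   readLines(file.path(d, "b_1.fastq")))

  # error-free reads substring-match their source haplotype (R2 is the
  # reverse complement of the fragment 3' end)
  tr <- truthTable(rpA)
  for (k in c(1L, 11L, 101L)) {
    src <- haplotypes(tinySample())[[tr$source[k]]]
    frag <- Biostrings::extractAt(
      src, IRanges::IRanges(tr$start[k] + 1L, width = tr$fragLen[k]))[[1]]
    expect_identical(as.character(firstReads(rpA)[[k]]),
                     as.character(Biostrings::subseq(frag, 1, 75)))
    expect_identical(
      as.character(secondReads(rpA)[[k]]),
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(frag, length(frag) - 74, length(frag)))))
  }
})

test_that("eccDNA simulator: read share tracks copies x length", {
  b <- tinyBundle()
  sp <- seqParams(readLength = 36, insertMean = 150, insertSd = 20,
                  seed = 31)
  mk <- function(copies1, seed) {
    plan <- circlePlan(data.frame(
      source = names(teLibrary(b)), copies = c(copies1, 50, 50)))
    simulateEccdna(b, plan, seqParams(readLength = 36, insertMean = 150,
                                      insertSd = 20, seed = seed), 20000)
  }
  e1 <- mk(50, 31); e2 <- mk(100, 32)
  share <- function(e, fam) mean(truthTable(e)$source == fam)
  lens <- Biostrings::width(teLibrary(b))
  w <- lens * c(50, 50, 50) / sum(lens * c(50, 50, 50))
  expect_lt(abs(share(e1, "TEfam1") - w[1]), 3 * sqrt(w[1] / 20000))
  # doubling family-1 copies roughly doubles its raw read count
  ratio <- (share(e2, "TEfam1") / (1 - share(e2, "TEfam1"))) /
    (share(e1, "TEfam1") / (1 - share(e1, "TEfam1")))
  expect_gt(ratio, 1.8); expect_lt(ratio, 2.2)

  expect_error(circlePlan(data.frame(source = "TEfam1", copies = 0)),
               "all-zero")
  # zero background -> no genome-derived pairs at all
  expect_true(all(truthTable(e1)$circular))
})
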