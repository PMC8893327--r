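test_that("spike-in normalization formula and its guards", {
  expect_equal(spikeinNormalize(500, 1e6, 10), 50)
  expect_equal(spikeinNormalize(0, 1e6, 10), 0)
  # doubling y with x, z fixed halves v
  expect_equal(spikeinNormalize(500, 2e6, 10),
               spikeinNormalize(500, 1e6, 10) / 2)
  expect_true(is.na(spikeinNormalize(500, 1e6, 0)))
  expect_error(spikeinNormalize(500, 0, 10))
})

test_that("circular-junction reads are detected by boundary overhang", {
  b <- tinyBundle()
  te <- teLibrary(b)[[1]]
  L <- length(te)
  doubled <- Biostrings::DNAString(paste0(as.character(te),
                                          as.character(te)))
  w <- 36L
  grab <- function(q0) Biostrings::subseq(doubled, q0 + 1L, q0 + w)
  # q = L - 26 covers the boundary by 26 left / 10 right (m = 10 -> junction)
  # q = L - 9 covers only 9 on the left -> not a junction read
  # q = 50 is fully internal
  qs <- c(L - 26L, L - 9L, 50L)
  r1 <- Biostrings::DNAStringSet(lapply(qs, grab))
  names(r1) <- paste0("p", seq_along(qs))
  pair <- ReadPairSet(r1, Biostrings::reverseComplement(r1))
  prof <- eccdnaQuant(pair, b, m = 10)
  tab <- eccTable(prof)
  fam1 <- tab[tab$family == names(teLibrary(b))[1], ]
  expect_equal(fam1$x, 6)            # both mates of all three pairs
  expect_equal(fam1$j, 2)            # only the q = L - 26 pair (both mates)
  # junction detection requires reads of at least 2m bases
  expect_warning(eccdnaQuant(pair, b, m = 20), "junction detection")
})

test_that("junction fraction matches the wrap-probability oracle", {
  b <- tinyBundle()
  plan <- defaultCirclePlan(b, teCopies = 60)
  sp <- seqParams(readLength = 36, insertMean = 150, insertSd = 20,
                  seed = 77)
  rp <- simulateEccdna(b, plan, sp, nPairs = 30000)
  prof <- eccdnaQuant(rp, b, m = 10, sampleId = "s")
  tab <- eccTable(prof)
  lens <- Biostrings::width(teLibrary(b))
  for (i in seq_along(lens)) {
    pWrap <- (36 - 2 * 10 + 1) / lens[i]
    x <- tab$x[i]
    expect_lt(abs(tab$j[i] - x * pWrap), 3 * sqrt(x * pWrap * (1 - pWrap)),
              label = paste("family", tab$family[i]))
  }
  # fully digested library: no genome background, so zero IGE reads
  expect_equal(prof@igeReads, 0)
  # residual background shows up as IGE reads
  bg <- simulateEccdna(b, defaultCirclePlan(b, linearBackgroundRate = 0.3),
                       sp, nPairs = 5000)
  expect_gt(eccdnaQuant(bg, b)@igeReads, 0)
})

test_that("between-sample v ratios are stable under library subsampling", {
  # v itself scales inversely with the spike-in read count, so the
  # depth-robust quantity is the between-sample ratio: subsampling both
  # libraries to 50% leaves every aging ratio unchanged within noise
  b <- tinyBundle()
  sp <- function(seed) seqParams(readLength = 36, insertMean = 150,
                                 insertSd = 20, seed = seed)
  young <- simulateEccdna(b, defaultCirclePlan(b,
                                               teCopies = c(30, 150, 150)),
                          sp(78), 30000)
  aged <- simulateEccdna(b, defaultCirclePlan(b,
                                              teCopies = c(60, 150, 150)),
                         sp(79), 30000)
  full <- eccdnaAgingRatio(eccdnaQuant(aged, b), eccdnaQuant(young, b))
  half <- eccdnaAgingRatio(
    eccdnaQuant(downsamplePairs(aged, 0.5, seed = 5), b),
    eccdnaQuant(downsamplePairs(young, 0.5, seed = 6), b))
  expect_equal(half$ratioSpikein, full$ratioSpikein, tolerance = 0.1)
  expect_equal(half$ratioRpm, full$ratioRpm, tolerance = 0.1)
})

test_that("shared-backbone reads split 1/k and z sums post plasmids", {
  b <- tinyBundle()
  # reads unique to the pUC19 insert versus on the 5-plasmid backbone
  uniq <- Biostrings::subseq(b@plasmids[["pUC19"]], 2201, 2236)
  back <- Biostrings::subseq(b@plasmids[["pUC19"]], 101, 136)
  r1 <- Biostrings::DNAStringSet(list(uniq, back))
  names(r1) <- c("u", "s")
  prof <- eccdnaQuant(ReadPairSet(r1, Biostrings::reverseComplement(r1)),
                      b)
  sc <- spikeinCounts(prof)
  expect_equal(sc$siteNorm[sc$plasmid == "pUC19"], 2 + 2 / 5)
  expect_equal(sc$siteNorm[sc$plasmid == "pMaxGFP"], 2 / 5)
  expect_equal(sum(sc$siteNorm), 4)          # one unit per read
  expect_equal(prof@z, sum(sc$siteNorm[sc$role == "post_extraction"]))
})

test_that("site-normalized frequencies track planted plasmid mass", {
  # proportionality to copies x length (mass) is exact when plasmids share
  # no sequence (every read is plasmid-specific, k = 1)
  man <- data.frame(name = paste0("pDistinct", 1:4),
                    role = c(rep("post_extraction", 3), "pre_extraction"),
                    length = c(3000L, 4000L, 5000L, 6000L),
                    relAbundance = c(1, 0.5, 0.25, 0.25))
  b <- buildReference(1e5, nTeFamilies = 2, nIge = 4, seed = 201,
                      plasmidManifest = man, backboneLength = 0L)
  rp <- simulateEccdna(b, defaultCirclePlan(b, teCopies = 20,
                                            plasmidScale = 1e4),
                       seqParams(readLength = 36, insertMean = 150,
                                 insertSd = 20, seed = 202), 40000)
  sc <- spikeinCounts(eccdnaQuant(rp, b))
  obs <- sc$siteNorm / sum(sc$siteNorm)
  expected <- man$relAbundance / sum(man$relAbundance)
  expect_equal(obs, expected, tolerance = 0.1)
  expect_equal(sc$uniqueReads, sc$raw)   # no sharing, all reads unique
})

test_that("aging ratios: identity, spike-in correction, over-spiking", {
  b <- tinyBundle()
  sp <- function(seed) seqParams(readLength = 36, insertMean = 150,
                                 insertSd = 20, seed = seed)
  # the doubled family is a minor library component (as a single TE family
  # is of a genome-mapped total), so its doubling barely moves y and the
  # spike-in share and the v ratio recovers ~2
  young <- eccdnaQuant(simulateEccdna(
    b, defaultCirclePlan(b, teCopies = c(30, 150, 150)), sp(80), 40000),
    b, sampleId = "young")
  same <- eccdnaAgingRatio(young, young)
  expect_true(all(abs(same$ratioRpm - 1) < 1e-12))
  expect_true(all(abs(same$ratioSpikein - 1) < 1e-12))
  expect_true(all(abs(same$ratioPreextraction - 1) < 1e-12))

  # family 1 circles doubled, spike-ins constant: the spike-in-normalized
  # ratio recovers the doubling, the RPM-only ratio under-reports it
  aged <- eccdnaQuant(simulateEccdna(
    b, defaultCirclePlan(b, teCopies = c(60, 150, 150)), sp(81), 40000),
    b, sampleId = "aged")
  r <- eccdnaAgingRatio(aged, young, mode = "spikein")
  expect_gt(r$ratioSpikein[1], 1.8)
  expect_lt(r$ratioSpikein[1], 2.2)
  expect_lt(r$ratioRpm[1], r$ratioSpikein[1])

  # over-spiked aged sample: RPM-mode ratio of the unchanged family stays
  # near 1 while the spike-in-mode ratio collapses
  over <- eccdnaQuant(simulateEccdna(
    b, defaultCirclePlan(b, teCopies = c(30, 150, 150),
                         plasmidScale = 8e5),
    sp(82), 40000), b, sampleId = "over")
  ov <- eccdnaAgingRatio(over, young)
  expect_equal(ov$ratioRpm[2], 1, tolerance = 0.25)
  expect_lt(ov$ratioSpikein[2], 0.65 * ov$ratioRpm[2])
})

test_that("spike-in QC flags extraction loss and missing pre-reference", {
  b <- tinyBundle()
  sp <- function(seed) seqParams(readLength = 36, insertMean = 150,
                                 insertSd = 20, seed = seed)
  mk <- function(seed, loss = 1) eccdnaQuant(simulateEccdna(
    b, defaultCirclePlan(b, teCopies = 60, extractionLoss = loss),
    sp(seed), 30000), b)
  s1 <- mk(90); s2 <- mk(91); s3 <- mk(92)
  qc <- spikeinQc(list(a = s1, b = s2, c = s3))
  # identically prepared samples: ratios agree within counting noise
  # (rare plasmids in the 1000x dilution series carry few reads, so the
  # tolerable CV scales with their Poisson noise)
  expect_lt(qc$cv[["pUC19"]], 0.15)
  expect_lt(qc$cv[["pMaxGFP"]], 0.25)
  expect_false(any(qc$failed))

  lossy <- mk(93, loss = 0.1)
  qc2 <- spikeinQc(list(a = s1, lossy = lossy))
  # 10x extraction loss shifts the post/pre ratio about tenfold
  expect_gt(qc2$ratios["lossy", 1] / qc2$ratios["a", 1], 5)

  noPre <- s1
  noPre@spikeins$uniqueReads[noPre@spikeins$role == "pre_extraction"] <- 0
  qc3 <- spikeinQc(list(a = s1, noPre = noPre))
  expect_true(qc3$failed["noPre"])
})
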