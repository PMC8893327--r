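#' Bootstrap a landscape by seeded downsampling
#'
#' For permutation k = 1..nPerm, the library is downsampled pair-atomically
#' at `fraction` with seed k (seeds equal the iteration index, so reruns
#' are bit-identical), re-aligned and re-called. Two normalized values are
#' recorded per permutation: `ipm`, the TE insertions per million mapped
#' reads of the downsampled library itself, and `ipmParent`, the same call
#' count normalized to the parent-library depth equivalent
#' (`mapped / fraction`), which estimates the full-library insertions per
#' million and stabilizes when call support is high enough to survive
#' downsampling. The summary reports mean, SD, a percentile 95% CI
#' (2.5/97.5), and the cumulative-average curve.
#'
#' @param pair the library's [ReadPairSet-class]
#' @param bundle the [ReferenceBundle-class]
#' @param nPerm number of permutations (default 20)
#' @param fraction downsampling fraction (default 0.5)
#' @param params a [callerParams] list
#' @param ciType `"percentile"` (default) or `"normal"`
#' @return list with `perPermutation` data.frame, `mean`, `sd`, `ci`,
#'   `meanParent`, and `cumulativeMean`
#' @export
bootstrapLandscape <- function(pair, bundle, nPerm = 20L, fraction = 0.5,
                               params = callerParams(),
                               ciType = c("percentile", "normal")) {
  ciType <- match.arg(ciType)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  res <- vector("list", nPerm)
  for (k in seq_len(nPerm)) {
    dp <- downsamplePairs(pair, fraction, seed = k)
    aln <- alignReads(dp, bundle, mode = "genome_split")
    ls <- callInsertions(aln, bundle, sampleId = paste0("perm", k),
                         params = params)
    res[[k]] <- data.frame(perm = k, calls = nrow(teCalls(ls)),
                           mapped = mappedReads(aln),
                           ipm = insertionsPerMillion(ls),
                           ipmParent = 1e6 * nrow(teCalls(ls)) /
                             (mappedReads(aln) / fraction))
  }
  per <- do.call(rbind, res)
  mu <- mean(per$ipm)
  sdv <- if (nPerm > 1L) sd(per$ipm) else 0
  ci <- if (ciType == "percentile")
    unname(quantile(per$ipm, c(0.025, 0.975), type = 7)) else
    mu + c(-1.96, 1.96) * sdv
  list(perPermutation = per, mean = mu, sd = sdv, ci = ci,
       meanParent = mean(per$ipmParent),
       cumulativeMean = cumsum(per$ipm) / seq_len(nPerm),
       fraction = fraction, nPerm = nPerm)
}

#' Partition two landscapes into common and unique insertions
#'
#' Calls match iff same chromosome, same family, and positions within
#' `matchWindow` bp; matching is greedy nearest-first and each call matches
#' at most once, so `|common| + |uniqueA| = |A|` and `|common| + |uniqueB| =
#' |B|` always hold. `matchWindow = 0` gives exact locus matching.
#'
#' @param landscapeA,landscapeB [Landscape-class] objects from depth-matched
#'   libraries (conventionally A = young, B = aged)
#' @param matchWindow positional slop in bp (default 100)
#' @return a [LandscapeComparison-class]
#' @export
classifyCommonUnique <- function(landscapeA, landscapeB,
                                 matchWindow = 100L) {
  a <- teCalls(landscapeA)
  b <- teCalls(landscapeB)
  a$idx <- seq_len(nrow(a)); b$idx <- seq_len(nrow(b))
  matches <- NULL
  for (key in intersect(paste(a$chrom, a$family),
                        paste(b$chrom, b$family))) {
    ai <- a[paste(a$chrom, a$family) == key, ]
    bi <- b[paste(b$chrom, b$family) == key, ]
    cand <- expand.grid(i = seq_len(nrow(ai)), j = seq_len(nrow(bi)))
    cand$d <- abs(ai$pos[cand$i] - bi$pos[cand$j])
    cand <- cand[cand$d <= matchWindow, , drop = FALSE]
    cand <- cand[order(cand$d, ai$pos[cand$i]), , drop = FALSE]
    usedI <- usedJ <- logical(0)
    for (rr in seq_len(nrow(cand))) {
      i <- cand$i[rr]; j <- cand$j[rr]
      if (i %in% usedI || j %in% usedJ) next
      usedI <- c(usedI, i); usedJ <- c(usedJ, j)
      matches <- rbind(matches,
                       data.frame(idxA = ai$idx[i], idxB = bi$idx[j]))
    }
  }
  if (is.null(matches)) matches <- data.frame(idxA = integer(),
                                              idxB = integer())
  common <- data.frame(
    chrom = a$chrom[matches$idxA], family = a$family[matches$idxA],
    posA = a$pos[matches$idxA], posB = b$pos[matches$idxB],
    crA = a$cr[matches$idxA], crB = b$cr[matches$idxB])
  new("LandscapeComparison",
      idA = landscapeA@sampleId, idB = landscapeB@sampleId,
      common = common,
      uniqueA = a[!(a$idx %in% matches$idxA),
                  setdiff(names(a), "idx"), drop = FALSE],
      uniqueB = b[!(b$idx %in% matches$idxB),
                  setdiff(names(b), "idx"), drop = FALSE],
      matchWindow = as.numeric(matchWindow))
}

#' @rdname LandscapeComparison-class
#' @export
setMethod("commonCalls", "LandscapeComparison", function(x) x@common)
#' @rdname LandscapeComparison-class
#' @param which `"A"` or `"B"`
#' @export
setMethod("uniqueCalls", "LandscapeComparison", function(x, which = "A")
  if (which == "A") x@uniqueA else x@uniqueB)

setMethod("show", "LandscapeComparison", function(object) {
  cat("LandscapeComparison (", object@idA, " vs ", object@idB, "): ",
      nrow(object@common), " common, ", nrow(object@uniqueA),
      " unique to ", object@idA, ", ", nrow(object@uniqueB),
      " unique to ", object@idB, "\n", sep = "")
})

#' Per-family composition of a landscape with an "Others" bucket
#'
#' Families holding less than `minFraction` of the TE calls are lumped into
#' `"Others"`; percentages sum to 100.
#'
#' @param landscape a [Landscape-class]
#' @param minFraction lump threshold (default 0.01, i.e. 1%)
#' @return data.frame with `family`, `count`, `percent`
#' @export
familyComposition <- function(landscape, minFraction = 0.01) {
  calls <- teCalls(landscape)
  if (nrow(calls) == 0L)
    return(data.frame(family = character(), count = integer(),
                      percent = numeric()))
  tab <- sort(table(calls$family), decreasing = TRUE)
  share <- as.numeric(tab) / sum(tab)
  fam <- names(tab)
  fam[share < minFraction] <- "Others"
  out <- stats::aggregate(count ~ family,
                          data.frame(family = fam,
                                     count = as.integer(tab)), sum)
  out <- out[order(out$family == "Others", -out$count), , drop = FALSE]
  out$percent <- 100 * out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

#' Per-family aged/young comparison table
#'
#' Normalized (per million mapped reads) TE call counts per family in each
#' landscape and their aged/young ratio. Families absent from one sample
#' get an infinite or undefined ratio and are flagged; with
#' `pseudocount = TRUE` a +1 count is added to both sides instead.
#'
#' @param landscapeYoung,landscapeAged [Landscape-class] objects
#' @param pseudocount add 1 call to both numerator and denominator
#' @return data.frame with per-family counts, normalized counts and ratios
#' @export
familyRatios <- function(landscapeYoung, landscapeAged,
                         pseudocount = FALSE) {
  fams <- sort(union(teCalls(landscapeYoung)$family,
                     teCalls(landscapeAged)$family))
  ny <- table(factor(teCalls(landscapeYoung)$family, levels = fams))
  na <- table(factor(teCalls(landscapeAged)$family, levels = fams))
  cy <- as.numeric(ny); ca <- as.numeric(na)
  if (pseudocount) { cy <- cy + 1; ca <- ca + 1 }
  ipmY <- 1e6 * cy / landscapeYoung@mappedReads
  ipmA <- 1e6 * ca / landscapeAged@mappedReads
  data.frame(family = fams, countYoung = as.integer(ny),
             countAged = as.integer(na), ipmYoung = ipmY, ipmAged = ipmA,
             ratio = ifelse(cy > 0, ipmA / ipmY, NA_real_),
             flagged = as.integer(ny) == 0L | as.integer(na) == 0L)
}

#' Aging statistics over per-family unique-insertion counts
#'
#' Paired Wilcoxon signed-rank over per-family (uniqueAged, uniqueYoung)
#' pairs, plus a one-tailed rank-sum option for grouped cohort differences.
#' The exact null is used at small n (see [signedRankTest]). Fewer than 3
#' informative (non-tied) pairs refuses the test.
#'
#' @param comparison a [LandscapeComparison-class] (A = young, B = aged) or
#'   a data.frame with columns `uniqueYoung` and `uniqueAged` per family
#' @param alternative passed to [signedRankTest]; `"greater"` tests for a
#'   gain of unique insertions in the aged sample
#' @return list with the signed-rank `htest`, the per-family table, and
#'   direction
#' @export
agingTests <- function(comparison, alternative = "two.sided") {
  if (is(comparison, "LandscapeComparison")) {
    fams <- sort(union(comparison@uniqueA$family, comparison@uniqueB$family))
    tab <- data.frame(
      family = fams,
      uniqueYoung = as.integer(table(factor(comparison@uniqueA$family,
                                            levels = fams))),
      uniqueAged = as.integer(table(factor(comparison@uniqueB$family,
                                           levels = fams))))
  } else tab <- comparison
  if (nrow(tab) < 3L)
    stop("fewer than 3 informative family pairs; test refused")
  ht <- signedRankTest(tab$uniqueAged, tab$uniqueYoung,
                       alternative = alternative)
  direction <- sign(sum(sign(tab$uniqueAged - tab$uniqueYoung)))
  list(signedRank = ht, table = tab,
       direction = c("young-biased", "none", "aged-biased")[direction + 2L])
}
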