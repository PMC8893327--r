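#' Quantify TE-derived eccDNA in a library with spike-in normalization
#'
#' Maps an eccDNA-enriched library against a circular-aware index: each TE
#' consensus and each plasmid is concatenated head-to-tail with itself
#' ("doubled"), so a read crossing the circular junction maps contiguously;
#' the linear genome is included for residual-background accounting.
#' Ties resolve in favor of consensus/plasmid entries (location-independent
#' counting), and alignments on the doubled sequences are canonicalized to
#' start position mod consensus length. Per family, `x` counts all family
#' reads and `j` counts circular-junction reads covering the head-to-tail
#' boundary by at least `m` bases on each side. Spike-in reads mapping to
#' backbone regions shared by k plasmids contribute 1/k to each
#' (mapping-site normalization); the aggregate `z` sums site-normalized
#' post-extraction counts, and the normalized value per family is
#' `v = ((x / y) * 1e6) / z` with `y` the library's total genome-derived
#' aligned reads (genome plus TE consensus placements; plasmid reads are
#' excluded from the denominator, as spike-in amounts must not dilute the
#' sample normalization).
#'
#' @param pair the eccDNA library's [ReadPairSet-class]
#' @param bundle a [ReferenceBundle-class]
#' @param m minimum junction overhang on each side in bp (default 10);
#'   junction detection is disabled with a warning when reads are shorter
#'   than `2 * m`
#' @param sampleId sample label
#' @return an [EccProfile-class]
#' @export
eccdnaQuant <- function(pair, bundle, m = 10L, sampleId = "sample") {
  if (length(pair) == 0L) stop("empty read set")
  reads <- c(firstReads(pair), secondReads(pair))
  names(reads) <- c(paste0(names(firstReads(pair)), "/1"),
                    paste0(names(secondReads(pair)), "/2"))
  w <- unique(Biostrings::width(reads))
  stopifnot(length(w) == 1L)
  junctionOn <- TRUE
  if (w < 2L * m) {
    warning("read length < 2m; junction detection disabled")
    junctionOn <- FALSE
  }

  circNames <- c(names(bundle@teLibrary), names(bundle@plasmids))
  circLen <- c(Biostrings::width(bundle@teLibrary),
               Biostrings::width(bundle@plasmids))
  doubled <- Biostrings::DNAStringSet(setNames(paste0(
    as.character(c(bundle@teLibrary, bundle@plasmids)),
    as.character(c(bundle@teLibrary, bundle@plasmids))), circNames))
  targets <- c(doubled, bundle@genome)
  categories <- c(rep("TE", length(bundle@teLibrary)),
                  rep("plasmid", length(bundle@plasmids)),
                  rep("genome", length(bundle@genome)))
  idx <- .buildIndex(targets, categories)
  hits <- .allHits(reads, idx)
  best <- .bestHits(hits, idx,
                    c(TE = 1L, plasmid = 2L, genome = 3L, IGE = 4L))
  if (nrow(best) == 0L) stop("no reads aligned")
  cat <- idx$category[best$tIdx]
  tname <- idx$names[best$tIdx]
  y <- sum(cat != "plasmid")  # genome-derived aligned reads

  # per-family x and junction reads j (canonical start = start mod L)
  te <- cat == "TE"
  famLevels <- names(bundle@teLibrary)
  x <- table(factor(tname[te], levels = famLevels))
  L <- circLen[match(tname[te], circNames)]
  q <- best$local0[te] %% L
  isJ <- junctionOn & (q <= L - m) & (q + w >= L + m)
  j <- tapply(isJ, factor(tname[te], levels = famLevels), sum)
  j[is.na(j)] <- 0L

  # spike-ins: k = number of distinct plasmids a read matches
  plasmidRows <- idx$category[hits$tIdx] == "plasmid"
  ph <- hits[plasmidRows, , drop = FALSE]
  ph <- ph[!duplicated(paste(ph$read, ph$tIdx)), , drop = FALSE]
  kPerRead <- table(ph$read)
  man <- bundle@plasmidManifest
  spikeRaw <- setNames(numeric(nrow(man)), man$name)
  spikeNorm <- setNames(numeric(nrow(man)), man$name)
  spikeUnique <- setNames(numeric(nrow(man)), man$name)
  if (nrow(ph)) {
    # only reads whose best placement is a plasmid count as spike-in reads
    bestPlasmid <- best$read[cat == "plasmid"]
    ph <- ph[ph$read %in% bestPlasmid, , drop = FALSE]
    pn <- idx$names[ph$tIdx]
    kk <- as.numeric(kPerRead[as.character(ph$read)])
    raw <- table(factor(pn, levels = man$name))
    nrm <- tapply(1 / kk, factor(pn, levels = man$name), sum)
    nrm[is.na(nrm)] <- 0
    uni <- table(factor(pn[kk == 1], levels = man$name))
    spikeRaw[] <- as.numeric(raw)
    spikeNorm[] <- as.numeric(nrm)
    spikeUnique[] <- as.numeric(uni)
  }
  z <- sum(spikeNorm[man$role == "post_extraction"])
  spikeins <- data.frame(plasmid = man$name, role = man$role,
                         raw = as.numeric(spikeRaw),
                         siteNorm = as.numeric(spikeNorm),
                         uniqueReads = as.numeric(spikeUnique),
                         meanBaseCoverage = as.numeric(spikeNorm) * w /
                           man$length)

  igeReads <- 0L
  gen <- cat == "genome"
  if (any(gen) && length(bundle@igeRanges)) {
    gr <- GenomicRanges::GRanges(
      tname[gen], IRanges::IRanges(best$local0[gen] + 1L, width = w))
    igeReads <- sum(GenomicRanges::countOverlaps(gr,
                                                 bundle@igeRanges) > 0L)
  }

  rpm <- if (y > 0) 1e6 * as.numeric(x) / y else rep(NA_real_, length(x))
  tab <- data.frame(family = famLevels, x = as.numeric(x),
                    j = as.numeric(j), y = y, z = z, rpm = rpm,
                    v = if (z > 0) rpm / z else NA_real_)
  new("EccProfile", table = tab, spikeins = spikeins,
      mappedReads = as.numeric(y), z = z, igeReads = as.numeric(igeReads),
      sampleId = sampleId)
}

#' @rdname EccProfile-class
#' @export
setMethod("eccTable", "EccProfile", function(x) x@table)
#' @rdname EccProfile-class
#' @export
setMethod("spikeinCounts", "EccProfile", function(x) x@spikeins)

setMethod("show", "EccProfile", function(object) {
  cat("EccProfile '", object@sampleId, "': ", nrow(object@table),
      " families, y = ", object@mappedReads, " aligned reads, z = ",
      round(object@z, 2), ", IGE reads = ", object@igeReads, "\n",
      sep = "")
})

#' Spike-in normalization formula
#'
#' `v = ((x / y) * 1e6) / z`: family read count over library total, per
#' million, over the spike-in count. With `z = 0` the normalized value is
#' withheld (NA) while the RPM-only value remains available.
#'
#' @param x family read count
#' @param y total aligned reads of the library (> 0)
#' @param z spike-in read count
#' @return the normalized value v (NA if z is 0)
#' @export
spikeinNormalize <- function(x, y, z) {
  stopifnot(y > 0, z >= 0)
  if (z == 0) return(NA_real_)
  ((x / y) * 1e6) / z
}

#' Aged/young eccDNA ratio table
#'
#' Per-family ratios in three modes, always emitted side by side: `rpm`
#' (library-size normalization only), `spikein` (v ratio, i.e. RPM ratio
#' additionally divided by the spike-in ratio), and `preextraction_plasmid`
#' (RPM ratio divided by the pre-extraction reference plasmid's mean base
#' coverage ratio). Families with a missing denominator in the chosen mode
#' are flagged.
#'
#' @param eccAged,eccYoung [EccProfile-class] objects over the same family
#'   universe
#' @param mode which ratio fills the `ratio` column
#' @param preRef pre-extraction reference plasmid (default: the manifest's
#'   first `pre_extraction` entry)
#' @return data.frame of per-family ratios
#' @export
eccdnaAgingRatio <- function(eccAged, eccYoung,
                             mode = c("spikein", "rpm",
                                      "preextraction_plasmid"),
                             preRef = NULL) {
  mode <- match.arg(mode)
  a <- eccAged@table; yo <- eccYoung@table
  if (!identical(a$family, yo$family))
    stop("family universes differ between samples")
  ratioRpm <- ifelse(yo$rpm > 0, a$rpm / yo$rpm, NA_real_)
  ratioSpike <- ifelse(!is.na(a$v) & !is.na(yo$v) & yo$v > 0,
                       a$v / yo$v, NA_real_)
  sa <- eccAged@spikeins; sy <- eccYoung@spikeins
  if (is.null(preRef)) {
    preIdx <- which(sa$role == "pre_extraction")[1]
  } else preIdx <- match(preRef, sa$plasmid)
  preRatio <- if (!is.na(preIdx) && sy$meanBaseCoverage[preIdx] > 0)
    sa$meanBaseCoverage[preIdx] / sy$meanBaseCoverage[preIdx] else NA_real_
  ratioPre <- ratioRpm / preRatio
  chosen <- switch(mode, rpm = ratioRpm, spikein = ratioSpike,
                   preextraction_plasmid = ratioPre)
  data.frame(family = a$family, ratio = chosen, mode = mode,
             ratioRpm = ratioRpm, ratioSpikein = ratioSpike,
             ratioPreextraction = ratioPre,
             flagged = is.na(chosen))
}

#' Spike-in quality control across samples
#'
#' Per sample and post-extraction plasmid: the ratio of the plasmid's
#' plasmid-specific (unique-region) read count to the pre-extraction
#' reference plasmid's unique-region count -- an extraction-recovery
#' control -- with the coefficient of variation of each ratio across
#' samples. Unique-region counts are used because backbone reads shared
#' with an abundant plasmid would otherwise mask recovery shifts of the
#' rarer reference. Also reports each library's IGE read total,
#' which should be near zero after complete exonuclease digestion of linear
#' DNA. QC is marked failed for samples with no pre-extraction reads.
#'
#' @param profiles a named list of [EccProfile-class] objects
#' @param preRef pre-extraction reference plasmid name (default: first
#'   `pre_extraction` manifest entry)
#' @return list with `ratios` (per sample x plasmid), `cv` (per plasmid),
#'   `igeReads` (per sample) and `failed` (per sample)
#' @export
spikeinQc <- function(profiles, preRef = NULL) {
  stopifnot(length(profiles) >= 1L)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("sample", seq_along(profiles))
  s1 <- profiles[[1]]@spikeins
  if (is.null(preRef)) preRef <- s1$plasmid[s1$role == "pre_extraction"][1]
  post <- s1$plasmid[s1$role == "post_extraction"]
  ratios <- t(vapply(profiles, function(p) {
    s <- p@spikeins
    pre <- s$uniqueReads[s$plasmid == preRef]
    if (length(pre) == 0L || pre == 0)
      return(setNames(rep(NA_real_, length(post)), post))
    setNames(s$uniqueReads[match(post, s$plasmid)] / pre, post)
  }, numeric(length(post))))
  cv <- apply(ratios, 2L, function(v)
    if (all(is.na(v)) || mean(v, na.rm = TRUE) == 0) NA_real_
    else sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE))
  if (length(profiles) == 1L) cv[] <- NA_real_
  list(ratios = as.data.frame(ratios),
       cv = cv,
       igeReads = vapply(profiles, function(p) p@igeReads, numeric(1)),
       failed = apply(ratios, 1L, function(v) all(is.na(v))))
}
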