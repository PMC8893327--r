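#' Reference bundle: genome, TE consensus library, IGEs and spike-in plasmids
#'
#' Container for every reference sequence the pipeline maps against: the
#' (synthetic or real) genome, the TE family consensus library, the immobile
#' gene elements (IGEs; arbitrarily selected protein-coding genes used to
#' benchmark false-positive insertion calls), and the spike-in plasmids used
#' for eccDNA quantitation. Pre-existing full-length TE copies embedded in the
#' genome are recorded in `teAnnotation` so junction evidence at reference
#' copies can be excluded by the caller.
#'
#' @slot genome a [Biostrings::DNAStringSet] of chromosomes
#' @slot teLibrary a [Biostrings::DNAStringSet] of TE family consensus
#'   sequences
#' @slot igeSeqs a [Biostrings::DNAStringSet] of IGE gene sequences (verbatim
#'   genome substrings)
#' @slot igeRanges a [GenomicRanges::GRanges] of the IGE genomic intervals
#' @slot plasmids a [Biostrings::DNAStringSet] of spike-in plasmid sequences
#' @slot plasmidManifest a data.frame with columns `name`, `role`
#'   (`"pre_extraction"` or `"post_extraction"`), `length`, `relAbundance`
#'   (relative mass)
#' @slot teAnnotation a [GenomicRanges::GRanges] of pre-existing genomic TE
#'   copies with a `family` metadata column
#' @export
setClass("ReferenceBundle", representation(
  genome = "DNAStringSet",
  teLibrary = "DNAStringSet",
  igeSeqs = "DNAStringSet",
  igeRanges = "GRanges",
  plasmids = "DNAStringSet",
  plasmidManifest = "data.frame",
  teAnnotation = "GRanges"
))

setValidity("ReferenceBundle", function(object) {
  msg <- NULL
  nm <- c(names(object@genome), names(object@teLibrary),
          names(object@igeSeqs), names(object@plasmids))
  if (anyDuplicated(nm))
    msg <- c(msg, "sequence names must be unique across all categories")
  allseq <- c(object@genome, object@teLibrary, object@igeSeqs,
              object@plasmids)
  if (any(Biostrings::width(allseq) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(allseq, collapse = TRUE)
  if (sum(freq[c("A", "C", "G", "T")]) != sum(freq))
    msg <- c(msg, "sequences must use the {A,C,G,T} alphabet only")
  glen <- setNames(Biostrings::width(object@genome), names(object@genome))
  ir <- object@igeRanges
  if (length(ir)) {
    chr <- as.character(GenomicRanges::seqnames(ir))
    if (!all(chr %in% names(glen)) ||
        any(GenomicRanges::end(ir) > glen[chr]) ||
        any(GenomicRanges::start(ir) < 1L))
      msg <- c(msg, "IGE intervals must lie within genome bounds")
  }
  if (length(object@igeRanges) != length(object@igeSeqs))
    msg <- c(msg, "igeRanges and igeSeqs must be parallel")
  if (is.null(msg)) TRUE else msg
})

#' Pooled sample: a bag of 2N haplotypes with a truth table
#'
#' Models a pooled sequencing sample (for instance 10 whole flies, i.e. 20
#' haplotypes). Each planted insertion is carried by `round(penetrance * 2N)`
#' haplotypes chosen by a seeded draw; penetrance is therefore a haplotype
#' frequency, matching pooled-sample semantics, with no diploid pairing logic.
#'
#' @slot bundle the [ReferenceBundle-class] the haplotypes derive from
#' @slot nIndividuals number of pooled individuals N (haplotypes = 2N)
#' @slot haplotypes a [Biostrings::DNAStringSet] named `"h<i>.<chrom>"`
#' @slot truth a data.frame, one row per planted insertion: `chrom`, `pos`
#'   (0-based genomic base of the 5' junction), `family`, `orientation`,
#'   `penetrance`, `nCarriers`, `carriers` (comma-separated haplotype
#'   indices), `teLength`
#' @export
setClass("SampleModel", representation(
  bundle = "ReferenceBundle",
  nIndividuals = "integer",
  haplotypes = "DNAStringSet",
  truth = "data.frame"
))

#' A set of simulated or loaded read pairs
#'
#' @slot first,second mate sequences as [Biostrings::DNAStringSet]; parallel
#'   and equal length
#' @slot truth per-pair provenance table (may have zero rows for loaded data)
#' @export
setClass("ReadPairSet", representation(
  first = "DNAStringSet",
  second = "DNAStringSet",
  truth = "data.frame"
))

setValidity("ReadPairSet", function(object) {
  if (length(object@first) != length(object@second))
    return("mates must be parallel")
  TRUE
})

#' Constructor for ReadPairSet
#' @param first,second mate [Biostrings::DNAStringSet]s
#' @param truth optional provenance data.frame
#' @return a [ReadPairSet-class]
#' @export
ReadPairSet <- function(first, second, truth = data.frame()) {
  new("ReadPairSet", first = first, second = second, truth = truth)
}

#' Alignment set produced by the bundled exact-seed mapper
#'
#' Holds one record per mapped read with standard alignment semantics:
#' target, 0-based start, strand, and for junction (split) reads the
#' soft-clipped remainder's placement on a TE consensus or IGE sequence.
#' Every mapped read is assigned to exactly one category
#' (genome/TE/IGE/plasmid), so category counts partition the mapped reads.
#'
#' @slot records data.frame of per-read placements (see [alignReads])
#' @slot totalReads number of input reads
#' @slot mode mapping mode used
#' @slot targets target metadata (name, category, length)
#' @slot readLength read length of the library
#' @export
setClass("AlignmentSet", representation(
  records = "data.frame",
  totalReads = "integer",
  mode = "character",
  targets = "data.frame",
  readLength = "integer"
))

#' A sample's TE landscape: accepted insertion calls plus depth normalization
#'
#' @slot sampleId sample label
#' @slot mappedReads mapped reads of the library (normalization denominator)
#' @slot calls data.frame of accepted calls: `chrom`, `pos` (0-based
#'   junction), `family`, `orientation`, `iL`, `iR`, `i`, `r`, `cr`,
#'   `crClass`, `category` (`"TE"` or `"IGE"`). IGE-category calls estimate
#'   the false-positive rate and are excluded from TE counts.
#' @export
setClass("Landscape", representation(
  sampleId = "character",
  mappedReads = "numeric",
  calls = "data.frame"
))

#' Comparison of two depth-matched TE landscapes
#'
#' @slot idA,idB sample labels (conventionally young = A, aged = B)
#' @slot common data.frame of matched call pairs
#' @slot uniqueA,uniqueB calls present in only one landscape
#' @slot matchWindow positional slop (bp) used for locus matching
#' @export
setClass("LandscapeComparison", representation(
  idA = "character",
  idB = "character",
  common = "data.frame",
  uniqueA = "data.frame",
  uniqueB = "data.frame",
  matchWindow = "numeric"
))

#' Location-independent per-target coverage profile
#'
#' One row per TE family and per IGE gene with mapped read count, RPM
#' (reads per million mapped library reads) and mean per-base coverage
#' (count * readLength / targetLength).
#'
#' @slot table the per-target data.frame
#' @slot mappedReads mapped reads of the library
#' @export
setClass("CoverageProfile", representation(
  table = "data.frame",
  mappedReads = "numeric"
))

#' eccDNA quantitation result for one library
#'
#' @slot table per-family data.frame: `family`, `x` (reads), `j`
#'   (circular-junction reads), `rpm` = (x/y)*1e6, `v` = rpm/z
#' @slot spikeins per-plasmid data.frame: `plasmid`, `role`, `raw`,
#'   `siteNorm` (reads weighted 1/k over k plasmids sharing the site),
#'   `uniqueReads` (reads mapping that plasmid only, a plasmid-specific
#'   molarity proxy), `meanBaseCoverage`
#' @slot mappedReads total aligned reads y
#' @slot z aggregate post-extraction spike-in count (site-normalized)
#' @slot igeReads reads placed inside IGE intervals (exonuclease QC)
#' @slot sampleId sample label
#' @export
setClass("EccProfile", representation(
  table = "data.frame",
  spikeins = "data.frame",
  mappedReads = "numeric",
  z = "numeric",
  igeReads = "numeric",
  sampleId = "character"
))
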