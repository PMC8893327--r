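#' @rdname ReferenceBundle-class
#' @param x,object an object
#' @export
setGeneric("teLibrary", function(x) standardGeneric("teLibrary"))
#' @rdname ReferenceBundle-class
#' @export
setGeneric("igeRanges", function(x) standardGeneric("igeRanges"))
#' @rdname ReferenceBundle-class
#' @export
setGeneric("teAnnotation", function(x) standardGeneric("teAnnotation"))
#' @rdname ReferenceBundle-class
#' @export
setGeneric("plasmidManifest", function(x) standardGeneric("plasmidManifest"))

#' @rdname SampleModel-class
#' @param x an object
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname SampleModel-class
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname ReadPairSet-class
#' @param x an object
#' @export
setGeneric("firstReads", function(x) standardGeneric("firstReads"))
#' @rdname ReadPairSet-class
#' @export
setGeneric("secondReads", function(x) standardGeneric("secondReads"))

#' @rdname AlignmentSet-class
#' @param x an object
#' @export
setGeneric("alignmentRecords", function(x) standardGeneric("alignmentRecords"))
#' @rdname AlignmentSet-class
#' @export
setGeneric("mappedReads", function(x) standardGeneric("mappedReads"))
#' @rdname AlignmentSet-class
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname Landscape-class
#' @param x an object
#' @export
setGeneric("teCalls", function(x) standardGeneric("teCalls"))
#' @rdname Landscape-class
#' @export
setGeneric("igeCalls", function(x) standardGeneric("igeCalls"))
#' @rdname Landscape-class
#' @export
setGeneric("insertionsPerMillion",
           function(x) standardGeneric("insertionsPerMillion"))
#' Fraction of calls that are IGE-category (false-positive proxy)
#' @param x a [Landscape-class]
#' @return |IGE calls| / (|TE calls| + |IGE calls|); 0 when no calls
#' @export
setGeneric("igeFpRate", function(x) standardGeneric("igeFpRate"))

#' @rdname LandscapeComparison-class
#' @param x an object
#' @export
setGeneric("commonCalls", function(x) standardGeneric("commonCalls"))
#' @rdname LandscapeComparison-class
#' @export
setGeneric("uniqueCalls", function(x, which) standardGeneric("uniqueCalls"))

#' @rdname CoverageProfile-class
#' @param x an object
#' @export
setGeneric("coverageTable", function(x) standardGeneric("coverageTable"))

#' @rdname EccProfile-class
#' @param x an object
#' @export
setGeneric("eccTable", function(x) standardGeneric("eccTable"))
#' @rdname EccProfile-class
#' @export
setGeneric("spikeinCounts", function(x) standardGeneric("spikeinCounts"))
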