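#' Location-independent consensus coverage table
#'
#' Per TE family and per IGE gene: full-length (end-to-end) mapped read
#' count, RPM (reads per million mapped library reads) and mean per-base
#' coverage (`count * readLength / targetLength`). Mean per-base coverage
#' and mean read count are distinct summaries; both are derivable from the
#' returned columns.
#'
#' @param aln an [AlignmentSet-class] in `consensus_end_to_end` mode
#' @return a [CoverageProfile-class]
#' @export
consensusCoverageTable <- function(aln) {
  stopifnot(aln@mode == "consensus_end_to_end")
  if (nrow(aln@records) == 0L) stop("empty alignment set")
  tg <- aln@targets
  tg <- tg[tg$category %in% c("TE", "IGE"), , drop = FALSE]
  cnt <- table(factor(aln@records$target, levels = tg$name))
  mapped <- mappedReads(aln)
  tab <- data.frame(target = tg$name, category = tg$category,
                    length = tg$length,
                    count = as.integer(cnt),
                    rpm = 1e6 * as.integer(cnt) / mapped,
                    meanCoverage = as.integer(cnt) * aln@readLength /
                      tg$length)
  rownames(tab) <- NULL
  new("CoverageProfile", table = tab, mappedReads = as.numeric(mapped))
}

#' @rdname CoverageProfile-class
#' @export
setMethod("coverageTable", "CoverageProfile", function(x) x@table)

setMethod("show", "CoverageProfile", function(object) {
  cat("CoverageProfile:", nrow(object@table), "targets,",
      format(object@mappedReads, big.mark = ","), "mapped reads\n")
  print(head(object@table, 5L))
})

#' Aged/young coverage-ratio table with Wilcoxon rank-sum tests
#'
#' Per-target ratio `RPM_aged / RPM_young` (targets with zero young RPM are
#' flagged and excluded from testing), plus Wilcoxon rank-sum comparisons of
#' the aged versus young RPM distributions, run separately across TE
#' families and across IGE genes. When the profiles are identical every
#' ratio is 1 and both p-values are 1.
#'
#' @param profileAged,profileYoung [CoverageProfile-class] objects over the
#'   same target universe
#' @param ... passed to [rankSumTest]
#' @return list with `ratios` (data.frame) and `tests` (p-values for TE and
#'   IGE groups)
#' @export
coverageRatioTest <- function(profileAged, profileYoung, ...) {
  a <- profileAged@table
  y <- profileYoung@table
  if (!identical(sort(a$target), sort(y$target)))
    stop("profiles cover different target sets")
  y <- y[match(a$target, y$target), ]
  ratios <- data.frame(target = a$target, category = a$category,
                       rpmAged = a$rpm, rpmYoung = y$rpm,
                       ratio = ifelse(y$rpm > 0, a$rpm / y$rpm, NA_real_),
                       flagged = y$rpm == 0)
  tests <- lapply(c(TE = "TE", IGE = "IGE"), function(cat) {
    rows <- ratios$category == cat & !ratios$flagged
    if (sum(rows) < 2L) return(NA_real_)
    rankSumTest(a$rpm[rows], y$rpm[rows], ...)$p.value
  })
  list(ratios = ratios, tests = tests)
}
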