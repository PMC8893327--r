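#' Draw a random insertion plan against a reference bundle
#'
#' Chooses insertion loci uniformly on the genome, keeping every locus at
#' least `minSpacing` bp from any other planned locus and `clearance` bp away
#' from pre-existing TE copies, IGE intervals and chromosome ends, so truth
#' loci stay separable at read scale and do not collide with junctions the
#' caller deliberately excludes.
#'
#' @param bundle a [ReferenceBundle-class]
#' @param n number of insertions
#' @param penetrance recycled vector of haplotype frequencies in (0, 1]
#' @param families recycled vector of family names (default: cycle through
#'   the bundle's library)
#' @param seed RNG seed
#' @param minSpacing minimum distance between planned loci; the default
#'   (1000 bp) exceeds the caller's clustering window so truth loci remain
#'   separable calls
#' @param clearance minimum distance from annotation and chromosome ends
#' @return a data.frame plan with columns `chrom`, `pos` (0-based),
#'   `family`, `penetrance`, `orientation`, `truncLen` (NA = full length)
#' @export
randomInsertionPlan <- function(bundle, n, penetrance = 1, families = NULL,
                                seed = 1L, minSpacing = 1000L,
                                clearance = 600L) {
  set.seed(seed)
  if (is.null(families)) families <- names(bundle@teLibrary)
  families <- rep_len(families, n)
  penetrance <- rep_len(penetrance, n)
  chroms <- names(bundle@genome)
  glen <- Biostrings::width(bundle@genome)
  avoid <- c(bundle@teAnnotation, GenomicRanges::granges(bundle@igeRanges))
  out <- vector("list", n)
  taken <- GenomicRanges::GRanges()
  for (i in seq_len(n)) {
    for (tries in seq_len(200L)) {
      ci <- sample.int(length(chroms), 1L)
      pos <- sample.int(glen[ci] - 2L * clearance, 1L) + clearance  # 0-based
      cand <- GenomicRanges::GRanges(chroms[ci],
                                     IRanges::IRanges(pos + 1L, width = 1L))
      nearAnno <- length(GenomicRanges::findOverlaps(
        cand + clearance, avoid)) > 0L
      nearPlan <- length(GenomicRanges::findOverlaps(
        cand + minSpacing, taken)) > 0L
      if (!nearAnno && !nearPlan) {
        taken <- c(taken, cand)
        out[[i]] <- data.frame(chrom = chroms[ci], pos = pos,
                               family = families[i],
                               penetrance = penetrance[i],
                               orientation = sample(c("+", "-"), 1L),
                               truncLen = NA_integer_)
        break
      }
    }
    if (is.null(out[[i]]))
      stop("could not place ", n, " insertions with the requested spacing")
  }
  do.call(rbind, out)
}

.validatePlan <- function(bundle, plan, minSpacing = 150L) {
  need <- c("chrom", "pos", "family", "penetrance")
  if (!all(need %in% names(plan)))
    stop("plan must have columns ", paste(need, collapse = ", "))
  if (is.null(plan$orientation))
    plan$orientation <- rep("+", nrow(plan))
  if (is.null(plan$truncLen))
    plan$truncLen <- rep(NA_integer_, nrow(plan))
  glen <- setNames(Biostrings::width(bundle@genome), names(bundle@genome))
  if (!all(plan$chrom %in% names(glen)))
    stop("plan references unknown chromosomes")
  if (any(plan$pos < 0L) || any(plan$pos >= glen[plan$chrom]))
    stop("plan positions must lie within their chromosome")
  if (!all(plan$family %in% names(bundle@teLibrary)))
    stop("plan references unknown TE families")
  if (any(plan$penetrance <= 0) || any(plan$penetrance > 1))
    stop("penetrance must be in (0, 1]")
  sp <- split(plan$pos, plan$chrom)
  if (any(vapply(sp, function(p) length(p) > 1L &&
                 min(diff(sort(p))) < minSpacing, logical(1))))
    stop("plan entries closer than ", minSpacing,
         " bp (2x read length) are not allowed")
  plan
}

#' Plant insertions into a pooled sample of 2N haplotypes
#'
#' Builds the 2N haplotype sequences of a pooled sample. Each plan entry is
#' inserted into exactly `round(penetrance * 2N)` haplotypes chosen by a
#' seeded draw; the realized penetrance is therefore exactly
#' `round(p * 2N) / 2N`. Insertions use the family consensus (reverse
#' complemented for orientation `"-"`); a finite `truncLen` keeps only the
#' 3' end of the consensus, emulating 5'-truncated elements.
#'
#' @param bundle a [ReferenceBundle-class]
#' @param plan a plan data.frame (see [randomInsertionPlan])
#' @param nIndividuals pooled individuals N (>= 1); haplotypes = 2N
#' @param seed RNG seed for the carrier draw
#' @param minSpacing spacing precondition on the plan (default 150 bp,
#'   i.e. 2x a 75 bp read)
#' @return a [SampleModel-class]
#' @export
plantInsertions <- function(bundle, plan, nIndividuals, seed = 1L,
                            minSpacing = 150L) {
  stopifnot(nIndividuals >= 1L)
  plan <- .validatePlan(bundle, plan, minSpacing)
  set.seed(seed)
  nHap <- 2L * as.integer(nIndividuals)
  nCarr <- pmax(0L, pmin(nHap, as.integer(round(plan$penetrance * nHap))))
  carriers <- lapply(nCarr, function(k) sort(sample.int(nHap, k)))

  teSeq <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    s <- bundle@teLibrary[[plan$family[i]]]
    if (!is.na(plan$truncLen[i])) {
      tl <- min(plan$truncLen[i], length(s))
      s <- Biostrings::subseq(s, start = length(s) - tl + 1L)
    }
    if (plan$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
    teSeq[i] <- as.character(s)
  }

  chromNames <- names(bundle@genome)
  haps <- vector("list", nHap * length(chromNames))
  nm <- character(length(haps))
  k <- 0L
  for (h in seq_len(nHap)) {
    mine <- which(vapply(carriers, function(cc) h %in% cc, logical(1)))
    for (chrom in chromNames) {
      k <- k + 1L
      idx <- mine[plan$chrom[mine] == chrom]
      sq <- bundle@genome[[chrom]]
      if (length(idx)) {
        idx <- idx[order(plan$pos[idx])]
        # zero-width anchors: TE inserted between bases pos and pos+1 (0-based)
        at <- IRanges::IRanges(start = plan$pos[idx] + 1L, width = 0L)
        sq <- Biostrings::replaceAt(sq, at,
                                    Biostrings::DNAStringSet(teSeq[idx]))
      }
      haps[[k]] <- as.character(sq)
      nm[k] <- sprintf("h%02d.%s", h, chrom)
    }
  }
  truth <- data.frame(plan,
                      nCarriers = nCarr,
                      carriers = vapply(carriers, paste, character(1),
                                        collapse = ","),
                      teLength = nchar(teSeq))
  new("SampleModel", bundle = bundle, nIndividuals = as.integer(nIndividuals),
      haplotypes = Biostrings::DNAStringSet(
        setNames(unlist(haps), nm)),
      truth = truth)
}

#' Write a sample's truth table as TSV (and loci as BED)
#' @param sample a [SampleModel-class]
#' @param file TSV output path
#' @return invisibly, the path
#' @export
writeTruthTable <- function(sample, file) {
  write.table(sample@truth, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname SampleModel-class
#' @export
setMethod("truthTable", "SampleModel", function(x) x@truth)
#' @rdname SampleModel-class
#' @export
setMethod("haplotypes", "SampleModel", function(x) x@haplotypes)

setMethod("show", "SampleModel", function(object) {
  cat("SampleModel:", object@nIndividuals, "individuals (",
      2L * object@nIndividuals, "haplotypes ),",
      nrow(object@truth), "planted insertions\n")
})

#' @rdname ReadPairSet-class
#' @export
setMethod("firstReads", "ReadPairSet", function(x) x@first)
#' @rdname ReadPairSet-class
#' @export
setMethod("secondReads", "ReadPairSet", function(x) x@second)
#' @rdname ReadPairSet-class
#' @export
setMethod("truthTable", "ReadPairSet", function(x) x@truth)
#' @rdname ReadPairSet-class
#' @export
setMethod("length", "ReadPairSet", function(x) length(x@first))

setMethod("show", "ReadPairSet", function(object) {
  cat("ReadPairSet:", length(object@first), "pairs, read length",
      if (length(object@first)) Biostrings::width(object@first)[1] else 0,
      "\n")
})
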