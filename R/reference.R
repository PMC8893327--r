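#' Build a synthetic reference bundle
#'
#' Generates a random genome, a TE family consensus library (each family with
#' one pre-existing full-length genomic copy, so consensus mapping is
#' non-trivial and reference-copy junctions exist to be excluded), a set of
#' IGE genes taken verbatim from the genome, and a spike-in plasmid panel.
#' The default plasmid panel mirrors a typical eccDNA spike-in cocktail: four
#' post-extraction plasmids of 2.7/3.5/5.2/6.3 kb added at a 10-fold mass
#' dilution series (1, 0.1, 0.01, 0.001), plus one 7 kb pre-extraction
#' reference plasmid added before gDNA extraction. Plasmids share a common
#' 2 kb backbone with plasmid-specific inserts, so backbone reads map to
#' multiple plasmids and exercise mapping-site normalization.
#'
#' @param genomeLength length of each chromosome in bp (>= 100 kb)
#' @param nChroms number of chromosomes
#' @param nTeFamilies number of TE families
#' @param nIge number of IGE genes (100 in the default fixture)
#' @param seed RNG seed; output is byte-identical for a fixed seed
#' @param teLengthRange min/max TE consensus length (bp)
#' @param igeLength IGE gene length (bp)
#' @param plasmidManifest optional data.frame (`name`, `role`, `length`,
#'   `relAbundance`) overriding the default panel
#' @param backboneLength length of the backbone shared by all plasmids
#'   (default 2 kb; 0 gives fully distinct plasmids)
#' @return a [ReferenceBundle-class]
#' @examples
#' bundle <- buildReference(1e5, nTeFamilies = 3, nIge = 10, seed = 1)
#' bundle
#' @export
buildReference <- function(genomeLength, nChroms = 1L, nTeFamilies = 5L,
                           nIge = 100L, seed = 1L,
                           teLengthRange = c(1500L, 4000L),
                           igeLength = 1000L,
                           plasmidManifest = NULL,
                           backboneLength = 2000L) {
  if (genomeLength < 1e5)
    stop("genomeLength must be >= 100 kb per chromosome")
  stopifnot(nChroms >= 1L, nTeFamilies >= 1L, nIge >= 0L)
  if ((nIge * igeLength + nTeFamilies * max(teLengthRange)) >
      0.5 * nChroms * genomeLength)
    stop("IGE and TE annotation would occupy more than half the genome; ",
         "reduce nIge/igeLength or enlarge the genome")
  set.seed(seed)

  chromNames <- paste0("chr", seq_len(nChroms))
  genome <- Biostrings::DNAStringSet(
    setNames(vapply(seq_len(nChroms), function(i) .randomDna(genomeLength),
                    character(1)), chromNames))

  famNames <- paste0("TEfam", seq_len(nTeFamilies))
  teLen <- sample(seq(teLengthRange[1], teLengthRange[2]), nTeFamilies,
                  replace = TRUE)
  teLibrary <- Biostrings::DNAStringSet(
    setNames(vapply(teLen, .randomDna, character(1)), famNames))

  # one pre-existing full-length copy per family, embedded by replacement so
  # chromosome lengths are unchanged
  anno <- NULL
  occupied <- lapply(chromNames, function(x) IRanges::IRanges())
  names(occupied) <- chromNames
  for (i in seq_len(nTeFamilies)) {
    chrom <- chromNames[(i - 1L) %% nChroms + 1L]
    at <- .placeIntervals(1L, teLen[i], genomeLength,
                          avoid = occupied[[chrom]])
    occupied[[chrom]] <- c(occupied[[chrom]], at)
    genome[[chrom]] <- Biostrings::replaceAt(genome[[chrom]], at,
                                             teLibrary[[i]])
    anno <- rbind(anno, data.frame(chrom = chrom, start = IRanges::start(at),
                                   end = IRanges::end(at),
                                   family = famNames[i]))
  }
  teAnno <- GenomicRanges::GRanges(anno$chrom,
                                   IRanges::IRanges(anno$start, anno$end),
                                   family = anno$family)

  # IGEs: genome substrings, placed clear of TE copies
  igeSeqs <- Biostrings::DNAStringSet()
  igeGr <- GenomicRanges::GRanges()
  if (nIge > 0L) {
    perChrom <- diff(round(seq(0, nIge, length.out = nChroms + 1L)))
    igeIdx <- 0L
    for (ci in seq_len(nChroms)) {
      k <- perChrom[ci]
      if (k == 0L) next
      chrom <- chromNames[ci]
      at <- .placeIntervals(k, igeLength, genomeLength,
                            avoid = occupied[[chrom]])
      occupied[[chrom]] <- c(occupied[[chrom]], at)
      nm <- paste0("IGE", sprintf("%03d", igeIdx + seq_len(k)))
      igeIdx <- igeIdx + k
      sq <- Biostrings::extractAt(genome[[chrom]], at)
      names(sq) <- nm
      igeSeqs <- c(igeSeqs, sq)
      igeGr <- c(igeGr, GenomicRanges::GRanges(
        chrom, at, gene = nm))
    }
    names(igeGr) <- igeGr$gene
  }

  if (is.null(plasmidManifest))
    plasmidManifest <- data.frame(
      name = c("pUC19", "pMaxGFP", "pGSH0", "pCENPm3", "pGL3pre"),
      role = c(rep("post_extraction", 4L), "pre_extraction"),
      length = c(2700L, 3500L, 5200L, 6300L, 7000L),
      relAbundance = c(1, 0.1, 0.01, 0.001, 0.08))
  stopifnot(backboneLength >= 0L,
            all(plasmidManifest$length > backboneLength))
  backbone <- .randomDna(backboneLength)
  plasmids <- Biostrings::DNAStringSet(setNames(vapply(
    plasmidManifest$length,
    function(L) paste0(backbone, .randomDna(L - backboneLength)),
    character(1)),
    plasmidManifest$name))

  new("ReferenceBundle", genome = genome, teLibrary = teLibrary,
      igeSeqs = igeSeqs, igeRanges = igeGr, plasmids = plasmids,
      plasmidManifest = plasmidManifest, teAnnotation = teAnno)
}

#' Write a reference bundle to FASTA and BED files
#'
#' Writes `genome.fa`, `te_library.fa`, `ige.fa`, `plasmids.fa`,
#' `ige.bed` and `te_annotation.bed` (BED is 0-based half-open).
#'
#' @param bundle a [ReferenceBundle-class]
#' @param dir output directory (created if missing)
#' @return invisibly, the output paths
#' @export
writeReferenceBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, c("genome.fa", "te_library.fa", "ige.fa",
                        "plasmids.fa", "ige.bed", "te_annotation.bed"))
  Biostrings::writeXStringSet(bundle@genome, p[1])
  Biostrings::writeXStringSet(bundle@teLibrary, p[2])
  Biostrings::writeXStringSet(bundle@igeSeqs, p[3])
  Biostrings::writeXStringSet(bundle@plasmids, p[4])
  .writeBed(bundle@igeRanges, names(bundle@igeRanges), p[5])
  .writeBed(bundle@teAnnotation, bundle@teAnnotation$family, p[6])
  invisible(p)
}

.writeBed <- function(gr, names, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),
                   name = names)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' @rdname ReferenceBundle-class
#' @export
setMethod("teLibrary", "ReferenceBundle", function(x) x@teLibrary)
#' @rdname ReferenceBundle-class
#' @export
setMethod("igeRanges", "ReferenceBundle", function(x) x@igeRanges)
#' @rdname ReferenceBundle-class
#' @export
setMethod("teAnnotation", "ReferenceBundle", function(x) x@teAnnotation)
#' @rdname ReferenceBundle-class
#' @export
setMethod("plasmidManifest", "ReferenceBundle", function(x) x@plasmidManifest)

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle\n")
  cat("  genome:    ", length(object@genome), "chromosome(s),",
      sum(Biostrings::width(object@genome)), "bp\n")
  cat("  TE library:", length(object@teLibrary), "families\n")
  cat("  IGEs:      ", length(object@igeSeqs), "genes\n")
  cat("  plasmids:  ", length(object@plasmids), "spike-ins\n")
})
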