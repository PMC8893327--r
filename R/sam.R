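#' Export an alignment set as SAM
#'
#' Writes standard SAM with `@SQ` headers for every reference target.
#' Full-length reads get an all-match CIGAR; junction reads get a
#' soft-clipped CIGAR (`<seg>M<clip>S` for a left-side genomic segment,
#' `<clip>S<seg>M` for a right-side one). Mate fields are filled when both
#' mates mapped.
#'
#' @param aln an [AlignmentSet-class]
#' @param file output path
#' @return invisibly, the path
#' @export
writeSAM <- function(aln, file) {
  rec <- aln@records
  tg <- aln@targets
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", tg$name, tg$length))
  flag <- ifelse(rec$strand == "-", 16L, 0L) +
    1L + ifelse(rec$mate == 1L, 64L, 128L)
  cigar <- ifelse(rec$type == "full", paste0(rec$width, "M"),
                  ifelse(rec$side == "left",
                         paste0(rec$width, "M", rec$clipLen, "S"),
                         paste0(rec$clipLen, "S", rec$width, "M")))
  mateRow <- match(paste0(rec$pairId, "/", 3L - rec$mate), rec$readId)
  rnext <- ifelse(is.na(mateRow), "*",
                  ifelse(rec$target[mateRow] == rec$target, "=",
                         rec$target[mateRow]))
  pnext <- ifelse(is.na(mateRow), 0L, rec$start[mateRow] + 1L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t*\t*",
                   rec$pairId, flag, rec$target, rec$start + 1L,
                   ifelse(rec$type == "full", 60L, 30L), cigar,
                   rnext, pnext)
  writeLines(c(hdr, lines), file)
  invisible(file)
}
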