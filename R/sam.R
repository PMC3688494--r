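#' Read alignment records from a SAM file
#'
#' Plain-text SAM in, one row per alignment record out. The file is converted
#' to BAM in a temporary directory with Rsamtools and scanned back, so the
#' parsing and flag semantics are the htslib ones. Mapping-uniqueness ("one top
#' alignment") is taken from the aligner's own fields: the `X0` tag (number of
#' best hits, BWA convention) when present, otherwise `MAPQ > 0`; ties are
#' thereby rejected downstream.
#'
#' @param path SAM file path (must carry `@SQ` header lines).
#' @return data.table with columns `qname`, `flag`, `template_id`, `pos`
#'   (1-based leftmost), `mapq`, `cigar`, `seq` (as stored: template
#'   orientation), `reverse` (logical), `is_secondary`, `is_unmapped`,
#'   `unique_top`.
#' @export
read_alignments <- function(path) {
  dest <- tempfile("orgedit_sam")
  bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(paste0(dest, c(".bam", ".bam.bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("X0"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  n <- length(x$qname)
  x0 <- x$tag$X0
  if (is.null(x0)) x0 <- rep(NA_integer_, n)
  dt <- data.table(
    qname = x$qname,
    flag = x$flag,
    template_id = as.character(x$rname),
    pos = x$pos,
    mapq = x$mapq,
    cigar = x$cigar,
    seq = as.character(x$seq),
    reverse = bitwAnd(x$flag, 16L) > 0L,
    is_secondary = bitwAnd(x$flag, 256L) > 0L,
    is_unmapped = bitwAnd(x$flag, 4L) > 0L
  )
  dt[, unique_top := ifelse(is.na(x0), mapq > 0L, x0 == 1L)]
  dt[]
}

cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(data.table(len = integer(), op = character()))
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    stop("malformed CIGAR: ", cigar)
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  data.table(len = len, op = op)
}

cigar_has_indel <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(TRUE)
    grepl("[IDN]", cg)
  }, logical(1), USE.NAMES = FALSE)
}

#' Filter alignment records
#'
#' Keeps only records with one top alignment, no secondary-alignment flag, and
#' no indels in the CIGAR (mapped, of course). This is the record-level filter
#' applied before pileup construction.
#'
#' @param aln data.table from [read_alignments()].
#' @return The accepted subset, with an attribute `rejected` giving the number
#'   of records dropped for each reason.
#' @export
filter_alignments <- function(aln) {
  unmapped <- aln$is_unmapped
  secondary <- !unmapped & aln$is_secondary
  multi <- !unmapped & !secondary & !aln$unique_top
  indel <- !unmapped & !secondary & !multi & cigar_has_indel(aln$cigar)
  keep <- !(unmapped | secondary | multi | indel)
  out <- aln[keep]
  setattr(out, "rejected",
          c(unmapped = sum(unmapped), secondary = sum(secondary),
            not_unique = sum(multi), indel = sum(indel)))
  out
}

#' Is a single alignment record accepted?
#'
#' Scalar form of [filter_alignments()]: accepted iff the record is mapped,
#' has a unique top hit, is not secondary, and its CIGAR contains no
#' insertion/deletion/skip operation.
#'
#' @param cigar CIGAR string.
#' @param is_secondary secondary-alignment flag.
#' @param unique_top does the aligner report a single best hit?
#' @param is_unmapped unmapped flag.
#' @return logical.
#' @export
alignment_accepted <- function(cigar, is_secondary = FALSE, unique_top = TRUE,
                               is_unmapped = FALSE) {
  cigar_ops(cigar) # validates; errors on malformed CIGAR
  !is_unmapped && !is_secondary && unique_top && !cigar_has_indel(cigar)
}
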