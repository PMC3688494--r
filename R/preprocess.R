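#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ path.
#' @return list with `id` (character), `bases` (character vector of read
#'   sequences) and `qual` (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- lapply(as.character(S4Vectors::mcols(x)$qualities), phred33_to_int)
  list(id = sub("\\s.*$", "", names(x)),
       bases = unname(as.character(x)),
       qual = unname(qual))
}

phred33_to_int <- function(q) as.integer(charToRaw(q)) - 33L

#' Preprocess sequencing reads
#'
#' Applies the amplicon-sequencing read cleanup: remove the first `trim5`
#' (low-quality) bases from the 5' end, then clip the 3' fragment starting at
#' the first base whose Phred quality falls below `qmin`; keep the read only if
#' the surviving length is at least `lmin`. Retained positions are renumbered
#' 1..L so that downstream pileups record the position on the processed read.
#'
#' @param bases character vector of read sequences.
#' @param qual list of integer Phred quality vectors (same lengths as `bases`).
#' @param id optional read ids.
#' @param qmin minimum acceptable base quality (default 20).
#' @param lmin minimum surviving read length (default 60).
#' @param trim5 number of 5' bases removed unconditionally (default 3).
#' @return list with `id`, `bases`, `qual` for kept reads, plus `discarded`
#'   (ids of dropped reads) and `n_input`.
#' @export
preprocess_reads <- function(bases, qual, id = NULL, qmin = 20L, lmin = 60L,
                             trim5 = 3L) {
  stopifnot(length(bases) == length(qual))
  if (is.null(id)) id <- as.character(seq_along(bases))
  lens <- nchar(bases)
  if (any(lens != lengths(qual)))
    stop("sequence/quality length mismatch")
  out_b <- character(length(bases)); out_q <- vector("list", length(bases))
  keep <- logical(length(bases))
  for (k in seq_along(bases)) {
    L <- lens[k]
    if (L <= trim5) next
    q <- qual[[k]][(trim5 + 1L):L]
    bad <- which(q < qmin)
    newlen <- if (length(bad)) bad[1L] - 1L else length(q)
    if (newlen < lmin) next
    keep[k] <- TRUE
    out_b[k] <- substr(bases[k], trim5 + 1L, trim5 + newlen)
    out_q[[k]] <- q[seq_len(newlen)]
  }
  list(id = id[keep], bases = out_b[keep], qual = out_q[keep],
       discarded = id[!keep], n_input = length(bases))
}

#' Preprocess a single read
#'
#' Scalar convenience wrapper around [preprocess_reads()]; returns `NULL` for a
#' discarded read.
#'
#' @param bases read sequence (single string).
#' @param qual integer Phred vector.
#' @inheritParams preprocess_reads
#' @return list with `bases` and `qual`, or `NULL` if discarded.
#' @export
preprocess_read <- function(bases, qual, qmin = 20L, lmin = 60L, trim5 = 3L) {
  res <- preprocess_reads(bases, list(qual), qmin = qmin, lmin = lmin,
                          trim5 = trim5)
  if (length(res$id) == 0L) return(NULL)
  list(bases = res$bases[[1L]], qual = res$qual[[1L]])
}

#' Write reads to FASTQ (Phred+33)
#' @param id,bases,qual read ids, sequences, integer Phred quality vectors.
#' @param path output path.
#' @export
write_fastq <- function(id, bases, qual, path) {
  qstr <- vapply(qual, function(q) rawToChar(as.raw(q + 33L)), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", id, "\n", bases, "\n+\n", qstr), con)
  invisible(path)
}
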