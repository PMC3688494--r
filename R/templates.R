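#' Amplicon template set
#'
#' Container for the amplicon/template sequences (transcript orientation) that
#' reads are aligned to, plus the per-template metadata used for site naming
#' and partitioning: gene name, genomic offset (added to the 1-based template
#' position when rendering site names such as `ndhB-708`), organelle partition,
#' and an optional coding region (`cds_start`/`cds_end`, frame 0 at
#' `cds_start`) used to classify edits as silent or non-silent.
#'
#' @param seqs named character vector of template sequences (A/C/G/T/N), or a
#'   `Biostrings::DNAStringSet`.
#' @param gene gene label per template; defaults to the template id.
#' @param genomic_offset integer added to template positions for site naming.
#' @param organelle partition label per template (e.g. `"mitochondrial"`,
#'   `"plastid"`).
#' @param cds_start,cds_end optional 1-based coding-region bounds per template
#'   (`NA` = non-coding template).
#' @return An object of class `template_set`: list with elements `seq` (named
#'   uppercase character vector) and `info` (data.table keyed by
#'   `template_id`).
#' @export
template_set <- function(seqs, gene = NULL, genomic_offset = 0L,
                         organelle = "mitochondrial",
                         cds_start = NA_integer_, cds_end = NA_integer_) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("template sequences must carry unique names")
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) stop("empty template sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in template(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  ids <- names(seqs)
  info <- data.table(
    template_id = ids,
    gene = if (is.null(gene)) ids else rep_len(gene, length(ids)),
    genomic_offset = as.integer(rep_len(genomic_offset, length(ids))),
    organelle = rep_len(organelle, length(ids)),
    cds_start = as.integer(rep_len(cds_start, length(ids))),
    cds_end = as.integer(rep_len(cds_end, length(ids)))
  )
  setkey(info, template_id)
  structure(list(seq = seqs, info = info), class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat("template_set:", length(x$seq), "templates,",
      sum(nchar(x$seq)), "bases total\n")
  cat("  organelle partition:",
      paste(sprintf("%s=%d", names(table(x$info$organelle)),
                    table(x$info$organelle)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.template_set <- function(x) length(x$seq)

#' Read templates from FASTA (+ optional metadata TSV)
#'
#' @param fasta path to a FASTA file of template sequences.
#' @param metadata optional TSV with columns `template_id` and any of `gene`,
#'   `genomic_offset`, `organelle`, `cds_start`, `cds_end`.
#' @return A [template_set()].
#' @export
read_templates <- function(fasta, metadata = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  # FASTA descriptions may carry comments after the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ts <- template_set(seqs)
  if (!is.null(metadata)) {
    md <- fread(metadata, sep = "\t", colClasses = list(character = "template_id"))
    if (!"template_id" %in% names(md)) stop("metadata lacks template_id column")
    for (col in intersect(
      c("gene", "genomic_offset", "organelle", "cds_start", "cds_end"),
      names(md))) {
      ts$info[md, (col) := get(paste0("i.", col)), on = "template_id"]
    }
  }
  ts
}

#' Write templates to FASTA
#' @param templates a [template_set()].
#' @param path output FASTA path.
#' @export
write_templates <- function(templates, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(templates$seq), path)
  invisible(path)
}

#' All cytidine positions of a template set
#'
#' The scan universe of the editing-site caller: every C on the transcript
#' strand of every template.
#'
#' @param templates a [template_set()].
#' @return data.table with columns `template_id`, `position`, `ref` ("C").
#' @export
c_positions <- function(templates) {
  res <- rbindlist(lapply(names(templates$seq), function(id) {
    p <- gregexpr("C", templates$seq[[id]], fixed = TRUE)[[1]]
    if (p[1] == -1L) return(NULL)
    data.table(template_id = id, position = as.integer(p), ref = "C")
  }))
  if (nrow(res) == 0L)
    res <- data.table(template_id = character(), position = integer(),
                      ref = character())
  setkey(res, template_id, position)
  res[]
}

#' Render gene-offset site names
#'
#' @param templates a [template_set()].
#' @param template_id,position vectors identifying sites.
#' @return character vector like `"ndhB-708"` (gene, dash, genomic position =
#'   template position + genomic offset).
#' @export
site_name <- function(templates, template_id, position) {
  i <- match(template_id, templates$info$template_id)
  paste0(templates$info$gene[i], "-",
         templates$info$genomic_offset[i] + as.integer(position))
}

template_base <- function(templates, template_id, position) {
  substring(templates$seq[template_id], position, position)
}
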