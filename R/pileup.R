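#' Build a per-library pileup over amplicon templates
#'
#' Every aligned base of every accepted record contributes one observation
#' `(template position, position on the read, observed base)`. Observations are
#' stored aggregated: one row per unique
#' `(template_id, position, ref, read_pos, obs)` with its multiplicity `n`.
#'
#' Reads aligning to the reverse strand are stored reverse-complemented in SAM,
#' i.e. already in template orientation, so observed bases are taken as-is; for
#' those records the read position is converted back to the sequenced 5'-based
#' index on the processed read (`L - k + 1` for SEQ index `k`), which is the
#' coordinate the position-on-read error model is indexed by.
#'
#' `N` observations are recorded but carry no weight in counts or likelihoods
#' downstream.
#'
#' @param aln accepted alignment records ([filter_alignments()] output).
#' @param templates a [template_set()].
#' @return data.table (class `pileup`) with columns `template_id`, `position`
#'   (1-based template coordinate), `ref`, `read_pos` (1-based position on the
#'   processed read as sequenced), `obs`, `n`.
#' @export
build_pileup <- function(aln, templates) {
  empty <- data.table(template_id = character(), position = integer(),
                      ref = character(), read_pos = integer(),
                      obs = character(), n = integer())
  setattr(empty, "class", c("pileup", class(empty)))
  if (nrow(aln) == 0L) return(empty)
  unknown <- setdiff(unique(aln$template_id), names(templates$seq))
  if (length(unknown))
    stop("alignments reference unknown template(s): ",
         paste(unknown, collapse = ", "))

  simple <- grepl("^[0-9]+M$", aln$cigar)
  parts <- list()

  if (any(simple)) {
    a <- aln[simple]
    lens <- nchar(a$seq)
    idx <- rep(seq_len(nrow(a)), lens)
    ridx <- sequence(lens)
    parts$simple <- data.table(
      rec = idx,
      template_id = a$template_id[idx],
      position = sequence(lens, from = a$pos),
      read_pos = ifelse(a$reverse[idx], lens[idx] - ridx + 1L, ridx),
      obs = unlist(strsplit(a$seq, ""), use.names = FALSE),
      qname = a$qname[idx]
    )
  }
  if (any(!simple)) {
    a <- aln[!simple]
    rows <- vector("list", nrow(a))
    for (r in seq_len(nrow(a))) {
      ops <- cigar_ops(a$cigar[r])
      if (any(ops$op %in% c("I", "D", "N")))
        stop("indel-containing record reached build_pileup: ", a$qname[r])
      rc <- 0L; tc <- a$pos[r]
      ridx <- integer(0); tpos <- integer(0)
      for (j in seq_len(nrow(ops))) {
        l <- ops$len[j]
        switch(ops$op[j],
          M = , `=` = , X = {
            ridx <- c(ridx, (rc + 1L):(rc + l))
            tpos <- c(tpos, tc:(tc + l - 1L))
            rc <- rc + l; tc <- tc + l
          },
          S = { rc <- rc + l },
          NULL)
      }
      L <- nchar(a$seq[r])
      rows[[r]] <- data.table(
        rec = r,
        template_id = a$template_id[r],
        position = tpos,
        read_pos = if (a$reverse[r]) L - ridx + 1L else ridx,
        obs = strsplit(a$seq[r], "")[[1L]][ridx],
        qname = a$qname[r]
      )
    }
    parts$general <- rbindlist(rows)
  }
  dt <- rbindlist(parts)

  tlen <- nchar(templates$seq)
  over <- dt[position > tlen[template_id]]
  if (nrow(over))
    stop("alignment extends past template end: record ", over$qname[1L],
         " on ", over$template_id[1L])

  dt[, ref := strsplit(templates$seq[[template_id[1L]]], "")[[1L]][position],
     by = template_id]
  pu <- dt[, .(n = .N), by = .(template_id, position, ref, read_pos, obs)]
  setkey(pu, template_id, position)
  setattr(pu, "class", c("pileup", class(pu)))
  pu
}

#' Per-site base counts from a pileup
#'
#' Collapses a pileup over read positions into per-site counts. `N`
#' observations are excluded from all counts; `depth` is the number of
#' contributing (non-N) observations and `t_fraction = T/(C+T)` (NA when
#' C+T = 0).
#'
#' @param pileup a [build_pileup()] result.
#' @return data.table with `template_id`, `position`, `ref`, `c_count`,
#'   `t_count`, `other_count`, `depth`, `t_fraction`.
#' @export
pileup_counts <- function(pileup) {
  cnt <- pileup[obs != "N",
    .(c_count = sum(n[obs == "C"]),
      t_count = sum(n[obs == "T"]),
      other_count = sum(n[!obs %in% c("C", "T")])),
    by = .(template_id, position, ref)]
  cnt[, depth := c_count + t_count + other_count]
  cnt[, t_fraction := ifelse(c_count + t_count > 0L,
                             t_count / (c_count + t_count), NA_real_)]
  setkey(cnt, template_id, position)
  cnt[]
}

#' Extract one pileup column
#'
#' @param pileup a [build_pileup()] result.
#' @param template_id,position the site.
#' @return data.table of the `(read_pos, obs, n)` observations at that site
#'   (zero rows when uncovered), with `ref` attached.
#' @export
pileup_column <- function(pileup, template_id, position) {
  q <- data.table(template_id = template_id, position = as.integer(position))
  pileup[q, on = c("template_id", "position"), nomatch = NULL]
}
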