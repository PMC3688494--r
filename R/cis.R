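#' Extract the cis-element window around an editing site
#'
#' The putative cis-element recognized by editing specificity factors lies
#' mostly upstream of the edited C; the window taken is 20 nt upstream through
#' 5 nt downstream of the target C (26 nt total), in transcript orientation,
#' truncated at template boundaries.
#'
#' @param templates a [template_set()].
#' @param template_id,position the site (must be a template C).
#' @param up,down bases upstream/downstream of the C (defaults 20 and 5).
#' @return list of class `cis_window`: `site` (gene-offset name), `sequence`,
#'   `target_index` (position of the C within the window), `truncated`.
#' @export
extract_window <- function(templates, template_id, position, up = 20L,
                           down = 5L) {
  seq <- templates$seq[[template_id]]
  if (is.null(seq)) stop("unknown template: ", template_id)
  position <- as.integer(position)
  if (substr(seq, position, position) != "C")
    stop("site base at ", template_id, ":", position, " is not C")
  start <- max(1L, position - up)
  end <- min(nchar(seq), position + down)
  structure(list(site = site_name(templates, template_id, position),
                 sequence = substr(seq, start, end),
                 target_index = position - start + 1L,
                 truncated = (start > position - up) || (end < position + down)),
            class = "cis_window")
}

#' Gapped identity between two cis windows
#'
#' Local alignment scored match +1, mismatch -1, gap -2 (linear); the reported
#' identity is the number of identical aligned positions in the best local
#' alignment, maximized over score-optimal alignments (so the count is
#' well-defined under score ties). Two sequences with no common character have
#' identity 0.
#'
#' @param a,b sequences (character strings) or `cis_window` objects.
#' @param match,mismatch,gap alignment scores (defaults +1/-1/-2).
#' @return list: `identity`, `score`, `aligned_a`, `aligned_b` (aligned
#'   strings with `-` gaps; empty when identity is 0).
#' @export
cis_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (inherits(a, "cis_window")) a <- a$sequence
  if (inherits(b, "cis_window")) b <- b$sequence
  x <- strsplit(toupper(a), "")[[1L]]
  y <- strsplit(toupper(b), "")[[1L]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1L, m + 1L)  # best local score ending at (i, j)
  K <- matrix(0L, n + 1L, m + 1L) # max matches among score-optimal endings
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      hit <- x[i] == y[j]
      sc <- c(S[i, j] + if (hit) match else mismatch,
              S[i, j + 1L] + gap,
              S[i + 1L, j] + gap,
              0)
      km <- c(K[i, j] + as.integer(hit), K[i, j + 1L], K[i + 1L, j], 0L)
      best <- max(sc)
      S[i + 1L, j + 1L] <- best
      K[i + 1L, j + 1L] <- max(km[sc == best])
    }
  }
  score <- max(S)
  if (score <= 0)
    return(list(identity = 0L, score = 0, aligned_a = "", aligned_b = ""))
  ident <- max(K[S == score])
  # deterministic endpoint: first cell (row-major) achieving (score, ident)
  end <- which(S == score & K == ident, arr.ind = TRUE)[1L, ]
  i <- end[1L]; j <- end[2L]
  ra <- character(0); rb <- character(0)
  # walk back until the restart option (score 0, no matches) started the path;
  # zero-score cells with matches are interior to score-optimal alignments
  while (i > 1L && j > 1L && !(S[i, j] == 0 && K[i, j] == 0L)) {
    hit <- x[i - 1L] == y[j - 1L]
    dsc <- S[i - 1L, j - 1L] + (if (hit) match else mismatch)
    dkm <- K[i - 1L, j - 1L] + as.integer(hit)
    if (dsc == S[i, j] && dkm == K[i, j]) {
      ra <- c(x[i - 1L], ra); rb <- c(y[j - 1L], rb)
      i <- i - 1L; j <- j - 1L
    } else if (i > 1L && S[i - 1L, j] + gap == S[i, j] &&
               K[i - 1L, j] == K[i, j]) {
      ra <- c(x[i - 1L], ra); rb <- c("-", rb); i <- i - 1L
    } else if (j > 1L && S[i, j - 1L] + gap == S[i, j] &&
               K[i, j - 1L] == K[i, j]) {
      ra <- c("-", ra); rb <- c(y[j - 1L], rb); j <- j - 1L
    } else break
  }
  list(identity = as.integer(ident), score = score,
       aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""))
}

#' Scan a query window against known-site windows
#'
#' Computes the gapped identity of the query cis window against every known
#' window and reports those reaching `min_identity` identical nucleotides,
#' sorted by identity (descending), ties broken by known-site id.
#'
#' @param query a `cis_window` (or sequence string).
#' @param known list of `cis_window`s (named, or carrying `$site`).
#' @param min_identity minimum identical aligned nucleotides (default 10).
#' @return data.table of hits: `query_site`, `known_site`, `identity`,
#'   `aligned_query`, `aligned_known` (zero rows when nothing reaches the
#'   threshold).
#' @export
best_identity_match <- function(query, known, min_identity = 10L) {
  qname <- if (inherits(query, "cis_window")) query$site else "query"
  empty <- data.table(query_site = character(), known_site = character(),
                      identity = integer(), aligned_query = character(),
                      aligned_known = character())
  if (length(known) == 0L) return(empty)
  knames <- names(known)
  if (is.null(knames))
    knames <- vapply(seq_along(known), function(i) {
      w <- known[[i]]
      if (inherits(w, "cis_window")) w$site else as.character(i)
    }, character(1))
  hits <- rbindlist(lapply(seq_along(known), function(i) {
    al <- cis_identity(query, known[[i]])
    data.table(query_site = qname, known_site = knames[i],
               identity = al$identity, aligned_query = al$aligned_a,
               aligned_known = al$aligned_b)
  }))
  hits <- hits[identity >= min_identity]
  if (nrow(hits) == 0L) return(empty)
  setorder(hits, -identity, known_site)
  hits[]
}
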