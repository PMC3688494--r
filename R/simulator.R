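#' Simulation configuration
#'
#' Defaults emulate the study conditions of deep amplicon sequencing of
#' organelle cDNAs: processed reads of length 97 (100 nt sequencing minus the
#' 5' trim), per-site depth of order 5500 (the mean depth per editing site
#' when pooling 24 libraries), per-substitution error rates of order 1e-3
#' (PCR/RT-PCR-like; plasmid-spike-like runs use 1e-4), and editing fractions
#' anywhere in `[0, 1]`.
#'
#' @param seed integer seed fixing all randomness.
#' @param n_templates,template_length,gc_fraction random template parameters.
#' @param read_length processed read length (default 97).
#' @param depth target per-site read depth (default 5500).
#' @param error_rate per-substitution-pair error rate: scalar, or a vector of
#'   length `read_length` for position-dependent profiles. Each target base is
#'   misread as a given other base with this probability (total mismatch rate
#'   is 3x the scalar).
#' @param editing_sites optional data.table/data.frame `template_id`,
#'   `position`, `theta` of true editing sites; alternatively give
#'   `n_edit_sites` and `theta_values` to place sites on random C positions.
#' @param n_edit_sites,theta_values used when `editing_sites` is NULL.
#' @param coverage_shape read-start distribution along templates: `"flat"`,
#'   `"mid_dip"` (fragmentation depletes template middles), or `"end_peak"`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_templates = 2L, template_length = 500L,
                       gc_fraction = 0.5, read_length = 97L, depth = 5500L,
                       error_rate = 1e-3, editing_sites = NULL,
                       n_edit_sites = 10L, theta_values = c(0.1, 0.5, 0.9),
                       coverage_shape = c("flat", "mid_dip", "end_peak")) {
  coverage_shape <- match.arg(coverage_shape)
  stopifnot(gc_fraction >= 0, gc_fraction <= 1,
            all(error_rate >= 0), all(error_rate <= 1/3),
            read_length >= 1L, depth >= 1L)
  structure(list(seed = as.integer(seed), n_templates = as.integer(n_templates),
                 template_length = as.integer(template_length),
                 gc_fraction = gc_fraction, read_length = as.integer(read_length),
                 depth = as.integer(depth), error_rate = error_rate,
                 editing_sites = editing_sites,
                 n_edit_sites = as.integer(n_edit_sites),
                 theta_values = theta_values, coverage_shape = coverage_shape),
            class = "sim_config")
}

#' Generate random templates and an editing truth set
#'
#' Templates are i.i.d. bases at the requested GC content; editing sites are
#' placed only on C positions (a configured site on a non-C position is an
#' error, as is requesting sites when the alphabet contains no C).
#'
#' @param config a [sim_config()].
#' @return list: `templates` (a [template_set()]) and `truth` (data.table
#'   `template_id`, `position`, `theta`).
#' @export
simulate_truth_set <- function(config) {
  set.seed(config$seed)
  probs <- c(A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
             G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2)
  seqs <- vapply(seq_len(config$n_templates), function(i)
    paste(sample(BASES, config$template_length, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  names(seqs) <- sprintf("tmpl%02d", seq_len(config$n_templates))
  templates <- template_set(seqs)

  if (!is.null(config$editing_sites)) {
    truth <- as.data.table(config$editing_sites)
    stopifnot(all(c("template_id", "position", "theta") %in% names(truth)))
  } else if (config$n_edit_sites > 0L) {
    cpos <- c_positions(templates)
    # keep sites clear of template ends so full-length reads can cover them
    cpos <- cpos[position > config$read_length &
                 position <= config$template_length - config$read_length]
    if (nrow(cpos) < config$n_edit_sites)
      stop("not enough interior C positions to place ", config$n_edit_sites,
           " editing sites (gc_fraction too low or templates too short)")
    pick <- cpos[sample(.N, config$n_edit_sites)]
    truth <- pick[, .(template_id, position,
                      theta = rep_len(config$theta_values, .N))]
  } else {
    truth <- data.table(template_id = character(), position = integer(),
                        theta = numeric())
  }
  if (nrow(truth)) {
    truth[, theta := as.numeric(theta)]
    stopifnot(all(truth$theta >= 0), all(truth$theta <= 1))
    bad <- truth[template_base(templates, template_id, position) != "C"]
    if (nrow(bad))
      stop("editing theta assigned to non-C position: ",
           paste(bad$template_id, bad$position, sep = ":", collapse = ", "))
    setkey(truth, template_id, position)
  }
  list(templates = templates, truth = truth)
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1L]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

start_weights <- function(n_starts, shape) {
  x <- seq_len(n_starts)
  mid <- (n_starts + 1) / 2
  switch(shape,
    flat = rep(1, n_starts),
    mid_dip = 0.2 + abs(x - mid) / mid,
    end_peak = 0.2 + pmax(exp(-(x - 1) / (n_starts / 8)),
                          exp(-(n_starts - x) / (n_starts / 8))))
}

#' Simulate strand-specific amplicon reads
#'
#' Draws reads from template intervals according to the configured coverage
#' shape; at each true editing site a read carries T with probability `theta`
#' (else C); then the position-on-read substitution error channel is applied
#' to every base. Reads are emitted pre-aligned: the SAM records carry the
#' true coordinates (flag 16 and reverse-complemented FASTQ sequence for
#' reverse-strand reads), so no external aligner is needed. Base qualities are
#' constant Q35.
#'
#' @param templates a [template_set()] (from [simulate_truth_set()]).
#' @param truth the editing truth table (`template_id`, `position`, `theta`).
#' @param config a [sim_config()].
#' @param dir output directory; created if needed.
#' @return list with file paths `fasta`, `fastq`, `sam`, `truth_tsv`, and the
#'   in-memory `alignments` data.table (same columns as [read_alignments()]).
#' @export
simulate_reads <- function(templates, truth, config, dir = tempfile("sim")) {
  set.seed(config$seed + 1L)
  rl <- config$read_length
  if (any(nchar(templates$seq) < rl))
    stop("read_length exceeds a template length")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  per_tmpl <- lapply(names(templates$seq), function(tid) {
    tlen <- nchar(templates$seq[[tid]])
    n_reads <- ceiling(config$depth * tlen / rl)
    n_starts <- tlen - rl + 1L
    starts <- sample.int(n_starts, n_reads, replace = TRUE,
                         prob = start_weights(n_starts, config$coverage_shape))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    tchars <- strsplit(templates$seq[[tid]], "")[[1L]]
    basemat <- matrix(tchars[outer(starts, 0:(rl - 1L), `+`)], nrow = n_reads)

    tsites <- truth[template_id == tid]
    for (s in seq_len(nrow(tsites))) {
      p <- tsites$position[s]
      cov <- which(starts <= p & starts + rl - 1L >= p)
      if (!length(cov)) next
      edited <- runif(length(cov)) < tsites$theta[s]
      basemat[cbind(cov[edited], p - starts[cov[edited]] + 1L)] <- "T"
    }

    # substitution errors, indexed by position on the read as sequenced
    eps <- rep_len(config$error_rate, rl)        # per-pair rate by read pos
    col_idx <- outer(rep(1L, n_reads), 1:rl, `*`)
    rev_m <- matrix(strand == "-", nrow = n_reads, ncol = rl)
    seqpos <- ifelse(rev_m, rl - col_idx + 1L, col_idx)
    err <- matrix(runif(n_reads * rl) < 3 * eps[seqpos], nrow = n_reads)
    if (any(err)) {
      ii <- which(err)
      cur <- basemat[ii]
      shift <- sample.int(3L, length(ii), replace = TRUE)
      basemat[ii] <- BASES[(match(cur, BASES) - 1L + shift) %% 4L + 1L]
    }
    seqs <- apply(basemat, 1L, paste, collapse = "")
    data.table(qname = sprintf("%s_r%06d", tid, seq_len(n_reads)),
               template_id = tid, pos = starts, strand = strand, seq = seqs)
  })
  reads <- rbindlist(per_tmpl)

  fasta <- file.path(dir, "templates.fasta")
  write_templates(templates, fasta)
  fastq <- file.path(dir, "reads.fastq")
  seq_fastq <- ifelse(reads$strand == "-", revcomp(reads$seq), reads$seq)
  write_fastq(reads$qname, seq_fastq,
              rep(list(rep(35L, rl)), nrow(reads)), fastq)
  sam <- file.path(dir, "alignments.sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(templates$seq),
                   nchar(templates$seq)))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  reads$qname, ifelse(reads$strand == "-", 16L, 0L),
                  reads$template_id, reads$pos, rl, reads$seq,
                  strrep(rawToChar(as.raw(35L + 33L)), rl))
  writeLines(c(hdr, body), sam)
  truth_tsv <- file.path(dir, "truth_sites.tsv")
  fwrite(truth, truth_tsv, sep = "\t")

  aln <- reads[, .(qname, flag = ifelse(strand == "-", 16L, 0L), template_id,
                   pos, mapq = 60L, cigar = paste0(rl, "M"), seq,
                   reverse = strand == "-", is_secondary = FALSE,
                   is_unmapped = FALSE, unique_top = TRUE)]
  list(fasta = fasta, fastq = fastq, sam = sam, truth_tsv = truth_tsv,
       alignments = aln)
}

#' Fast count-level pileup simulation
#'
#' Generates pileup columns directly at the count level — the sufficient
#' statistics of the site caller — skipping read assembly. Each site receives
#' `depth` molecules, edited with probability `theta`, pushed through a
#' position-uniform per-pair substitution channel with rate `error_rate`. All
#' observations of a site share one read position (sites cycle through
#' positions `1..read_length`), which is exact for a position-uniform channel;
#' use [simulate_reads()] when positional structure matters.
#'
#' @param n_sites number of simulated C columns.
#' @param depth per-site molecule count.
#' @param theta true editing fraction, scalar or per-site vector.
#' @param error_rate per-pair substitution rate (scalar).
#' @param read_length read positions cycled over (default 97).
#' @param template_id template label for the synthetic columns.
#' @return list: `pileup` (a `pileup` data.table; sites at positions
#'   `1..n_sites`) and `truth` (`template_id`, `position`, `theta`).
#' @export
simulate_pileup <- function(n_sites, depth, theta, error_rate = 1e-3,
                            read_length = 97L, template_id = "simT") {
  theta <- rep_len(theta, n_sites)
  eps <- error_rate
  nT <- rbinom(n_sites, depth, theta)       # edited molecules
  nC <- depth - nT
  # channel draws: per molecule class, counts of each observed base
  draw <- function(nmol, p_obs) {
    if (all(nmol == 0L)) return(matrix(0L, n_sites, 4L, dimnames = list(NULL, BASES)))
    out <- matrix(0L, n_sites, 4L, dimnames = list(NULL, BASES))
    nz <- which(nmol > 0L)
    draws <- vapply(nz, function(i) rmultinom(1L, nmol[i], p_obs),
                    numeric(4L))
    out[nz, ] <- t(draws)
    out
  }
  pC <- c(A = eps, C = 1 - 3 * eps, G = eps, T = eps)
  pT <- c(A = eps, C = eps, G = eps, T = 1 - 3 * eps)
  obsC <- draw(nC, pC)
  obsT <- draw(nT, pT)
  tot <- obsC + obsT
  rp <- ((seq_len(n_sites) - 1L) %% read_length) + 1L
  pu <- data.table(template_id = template_id,
                   position = rep(seq_len(n_sites), 4L),
                   ref = "C",
                   read_pos = rep(rp, 4L),
                   obs = rep(BASES, each = n_sites),
                   n = as.integer(tot))
  pu <- pu[n > 0L]
  setkey(pu, template_id, position)
  setattr(pu, "class", c("pileup", class(pu)))
  list(pileup = pu,
       truth = data.table(template_id = template_id,
                          position = seq_len(n_sites), theta = theta))
}

#' Error-only pileup over non-edited reference bases
#'
#' Simulates the alignments used for mismatch-rate estimation: `n_obs`
#' observations of a fixed reference base spread evenly over read positions,
#' pushed through the per-pair substitution channel. Useful both for
#' estimating a rate table that matches a generator and for checking rate
#' recovery.
#'
#' @param n_obs total observations.
#' @param ref reference base (default "C").
#' @param error_rate per-pair substitution rate, scalar or per-position.
#' @param read_length number of read positions (default 97).
#' @param template_id template label.
#' @return a `pileup` data.table (positions = read positions).
#' @export
simulate_error_pileup <- function(n_obs, ref = "C", error_rate = 1e-3,
                                  read_length = 97L, template_id = "spike") {
  eps <- rep_len(error_rate, read_length)
  per_pos <- diff(floor(seq(0, n_obs, length.out = read_length + 1L)))
  rows <- lapply(seq_len(read_length), function(i) {
    p <- rep(eps[i], 4L); names(p) <- BASES
    p[ref] <- 1 - 3 * eps[i]
    cnt <- as.integer(rmultinom(1L, per_pos[i], p))
    data.table(template_id = template_id, position = i, ref = ref,
               read_pos = i, obs = BASES, n = cnt)
  })
  pu <- rbindlist(rows)[n > 0L]
  setkey(pu, template_id, position)
  setattr(pu, "class", c("pileup", class(pu)))
  pu
}

#' Exact position-uniform mismatch-rate table
#'
#' Constructs a `mismatch_rates` object whose looked-up rates equal a given
#' channel exactly (no sampling noise, zero pseudocount) — the error model an
#' idealized generator run of infinite depth would estimate. Useful as a
#' known-truth channel in tests and worked examples.
#'
#' @param error_rate per-pair substitution rate.
#' @param read_length number of read positions.
#' @param pairs `"all"` (every off-diagonal pair at `error_rate`) or
#'   `"ct_only"` (only C->T and T->C; other bases read perfectly).
#' @return a `mismatch_rates` object with `pseudocount = 0`.
#' @export
uniform_mismatch_rates <- function(error_rate = 1e-3, read_length = 97L,
                                   pairs = c("all", "ct_only")) {
  pairs <- match.arg(pairs)
  N <- 1e9 # synthetic stratum size; large so strata are always trusted
  counts <- array(0, dim = c(read_length, 4L, 4L),
                  dimnames = list(NULL, BASES, BASES))
  for (r in BASES) for (o in BASES) {
    rate <- if (r == o) NA else if (pairs == "all") error_rate
            else if ((r == "C" && o == "T") || (r == "T" && o == "C"))
              error_rate else 0
    if (!is.na(rate)) counts[, r, o] <- rate * N
  }
  for (r in BASES) counts[, r, r] <- N - rowSums(counts[, r, , drop = FALSE])
  structure(list(counts = counts, pooled = apply(counts, c(2L, 3L), sum),
                 pseudocount = 0, min_stratum = 1L,
                 library_id = "uniform"),
            class = "mismatch_rates")
}
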