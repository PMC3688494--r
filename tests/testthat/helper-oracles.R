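# Independent oracles and small fixture builders shared across tests.

library(data.table)

# Pearson 2x2 statistic written out cell by cell (no shared code with the
# implementation).
pearson_oracle <- function(c1, t1, c2, t2) {
  O <- c(c1, t1, c2, t2)
  n <- sum(O)
  row1 <- c1 + t1; row2 <- c2 + t2
  col1 <- c1 + c2; col2 <- t1 + t2
  E <- c(row1 * col1, row1 * col2, row2 * col1, row2 * col2) / n
  sum((O - E)^2 / E)
}

# Top-down memoized local-alignment oracle: best score and, among
# score-optimal local alignments, the maximum number of identical aligned
# positions. Same definition as cis_identity, independently coded.
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  Sc <- matrix(NA_real_, n + 1, m + 1)
  Mt <- matrix(NA_integer_, n + 1, m + 1)
  ending <- function(i, j) {
    if (i == 0 || j == 0) return(c(0, 0))
    if (!is.na(Sc[i + 1, j + 1])) return(c(Sc[i + 1, j + 1], Mt[i + 1, j + 1]))
    hit <- x[i] == y[j]
    d <- ending(i - 1, j - 1); u <- ending(i - 1, j); l <- ending(i, j - 1)
    cand_s <- c(d[1] + if (hit) match else mismatch, u[1] + gap, l[1] + gap, 0)
    cand_m <- c(d[2] + as.integer(hit), u[2], l[2], 0)
    s <- max(cand_s); k <- max(cand_m[cand_s == s])
    Sc[i + 1, j + 1] <<- s; Mt[i + 1, j + 1] <<- k
    c(s, k)
  }
  best_s <- 0; best_k <- 0L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    e <- ending(i, j)
    if (e[1] > best_s || (e[1] == best_s && e[2] > best_k)) {
      best_s <- e[1]; best_k <- e[2]
    }
  }
  list(score = best_s, identity = as.integer(best_k))
}

# Exhaustive enumeration of every local alignment of two short strings:
# all substring pairs x all monotone pairings with gaps. Returns the best
# score and the max matches among best-scoring alignments.
enum_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  best <- c(score = 0, matches = 0)
  glob <- function(xs, ys, sc, mt) {
    if (!length(xs) && !length(ys)) {
      if (sc > best["score"] ||
          (sc == best["score"] && mt > best["matches"]))
        best <<- c(score = sc, matches = mt)
      return(invisible())
    }
    if (length(xs) && length(ys)) {
      hit <- xs[1] == ys[1]
      glob(xs[-1], ys[-1], sc + if (hit) match else mismatch,
           mt + as.integer(hit))
    }
    if (length(xs)) glob(xs[-1], ys, sc + gap, mt)
    if (length(ys)) glob(xs, ys[-1], sc + gap, mt)
  }
  for (i1 in seq_along(x)) for (i2 in i1:length(x))
    for (j1 in seq_along(y)) for (j2 in j1:length(y))
      glob(x[i1:i2], y[j1:j2], 0, 0L)
  list(score = unname(best["score"]), identity = as.integer(best["matches"]))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Hand-build a pileup data.table (count-level fixture).
make_pileup <- function(template_id, position, ref, read_pos, obs, n) {
  pu <- data.table(template_id = template_id, position = as.integer(position),
                   ref = ref, read_pos = as.integer(read_pos), obs = obs,
                   n = as.integer(n))
  setkey(pu, template_id, position)
  setattr(pu, "class", c("pileup", class(pu)))
  pu
}

# Rate table estimated from a large simulated error-only run over both C and T
# reference strata (the two the caller's likelihood needs).
calibration_rates <- function(eps = 1e-3, n_c = 1e7, n_t = 1e6, seed = 42) {
  set.seed(seed)
  pu <- rbind(simulate_error_pileup(n_c, "C", eps),
              simulate_error_pileup(n_t, "T", eps))
  estimate_mismatch_rates(pu, library_id = "calibration")
}

# Minimal two-template set with known Cs and a coding region on tmplA.
toy_templates <- function() {
  template_set(
    c(tmplA = "ATGCCTCTTGGACGTACCGTAGCTAGCTAAGGCATCAGT",
      tmplB = "TTTTCAAACCCGGGTTTACGCATGCA"),
    gene = c("geneA", "geneB"),
    genomic_offset = c(100L, 0L),
    organelle = c("mitochondrial", "plastid"),
    cds_start = c(1L, NA), cds_end = c(30L, NA))
}

write_toy_sam <- function(path, records,
                          sq = c("tmplA" = 39L, "tmplB" = 26L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, rname, pos, mapq, cigar, seq,
                       tags = character(0)) {
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq,
          strrep("I", nchar(seq)), tags), collapse = "\t")
}
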