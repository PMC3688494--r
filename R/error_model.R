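#' Empirical position-on-read mismatch rates
#'
#' Estimates `P_i(o | r)` — the probability of observing base `o` at position
#' `i` of the (processed) read when the aligned template base is `r` — from a
#' per-library pileup, excluding masked columns (obvious editing sites). A
#' pseudocount is added to each off-diagonal count, with the diagonal taking
#' the complementary mass, so that no substitution probability is exactly zero
#' (the likelihood-ratio test degenerates at rate 0):
#' `P_i(o|r) = (count_i(o|r) + pc * [o != r]) / (N_i(r) + 3 * pc)`.
#'
#' Per-position strata are only trusted when their reference-base coverage
#' reaches `min_stratum` observations; sparser strata fall back to the
#' position-marginal pooled table (same pseudocount scheme). A reference base
#' with no unmasked observations at all is an error.
#'
#' @param pileup a [build_pileup()] result for one library.
#' @param mask optional data.table/data.frame with columns `template_id`,
#'   `position` of columns to exclude (e.g. [auto_mask()] output).
#' @param pseudocount added to each off-diagonal count (default 0.5).
#' @param min_stratum minimum per-position reference-base coverage before the
#'   positional stratum is used instead of the pooled table (default 1000).
#' @param library_id optional label carried in the result.
#' @return Object of class `mismatch_rates`: list with `counts` (3-d array
#'   `position x ref x obs`), `pooled` (4 x 4 matrix), `pseudocount`,
#'   `min_stratum`, `library_id`.
#' @export
estimate_mismatch_rates <- function(pileup, mask = NULL, pseudocount = 0.5,
                                    min_stratum = 1000L, library_id = NA_character_) {
  dt <- pileup[obs %in% BASES & ref %in% BASES]
  if (!is.null(mask) && nrow(mask) > 0L) {
    mk <- as.data.table(mask)[, .(template_id, position)]
    dt <- dt[!mk, on = c("template_id", "position")]
  }
  if (nrow(dt) == 0L) stop("no unmasked observations to estimate rates from")
  maxpos <- max(dt$read_pos)
  counts <- array(0, dim = c(maxpos, 4L, 4L),
                  dimnames = list(NULL, BASES, BASES))
  agg <- dt[, .(n = sum(n)), by = .(read_pos, ref, obs)]
  counts[cbind(agg$read_pos, match(agg$ref, BASES), match(agg$obs, BASES))] <- agg$n
  pooled <- apply(counts, c(2L, 3L), sum)
  structure(list(counts = counts, pooled = pooled,
                 pseudocount = pseudocount, min_stratum = as.integer(min_stratum),
                 library_id = library_id),
            class = "mismatch_rates")
}

#' @export
print.mismatch_rates <- function(x, ...) {
  tot <- rowSums(x$pooled)
  cat("mismatch_rates", if (!is.na(x$library_id)) paste0("[", x$library_id, "]"),
      ":", dim(x$counts)[1L], "read positions,",
      format(sum(tot), big.mark = ","), "observations\n")
  offdiag <- (sum(x$pooled) - sum(diag(x$pooled))) / max(sum(x$pooled), 1)
  cat("  pooled total mismatch rate:", signif(offdiag, 3), "\n")
  invisible(x)
}

rate_from_counts <- function(cnt_o, cnt_tot, off_diag, pc) {
  (cnt_o + pc * off_diag) / (cnt_tot + 3 * pc)
}

#' Look up mismatch rates
#'
#' Vectorized lookup of `P_i(o|r)`. Positions whose `(i, r)` stratum has fewer
#' than `min_stratum` observations (including positions beyond the table, or
#' never observed) use the pooled position-marginal rate. With a positive
#' pseudocount the result is never exactly 0, and for each `(i, r)` the four
#' rates sum to 1.
#'
#' @param rates a `mismatch_rates` object.
#' @param i read position(s), 1-based.
#' @param r reference base(s).
#' @param o observed base(s).
#' @return numeric vector of probabilities.
#' @export
rate_lookup <- function(rates, i, r, o) {
  k <- max(length(i), length(r), length(o))
  i <- rep_len(as.integer(i), k)
  ri <- match(rep_len(r, k), BASES)
  oi <- match(rep_len(o, k), BASES)
  if (anyNA(ri) || anyNA(oi)) stop("unknown base symbol in rate_lookup")
  maxpos <- dim(rates$counts)[1L]
  pc <- rates$pseudocount

  inrange <- i >= 1L & i <= maxpos
  cnt_tot <- numeric(k); cnt_o <- numeric(k)
  if (any(inrange)) {
    ii <- i[inrange]
    strata <- rates$counts[cbind(rep(ii, 4L), rep(ri[inrange], 4L),
                                 rep(1:4, each = sum(inrange)))]
    cnt_tot[inrange] <- rowSums(matrix(strata, ncol = 4L))
    cnt_o[inrange] <- rates$counts[cbind(ii, ri[inrange], oi[inrange])]
  }
  use_stratum <- inrange & cnt_tot >= rates$min_stratum

  pooled_tot <- rowSums(rates$pooled)[ri]
  if (any(!use_stratum & pooled_tot == 0))
    stop("no observations (positional or pooled) for reference base ",
         paste(unique(BASES[ri[!use_stratum & pooled_tot == 0]]), collapse = ","))
  pooled_o <- rates$pooled[cbind(ri, oi)]

  off <- as.numeric(ri != oi)
  out <- rate_from_counts(pooled_o, unname(pooled_tot), off, pc)
  if (any(use_stratum))
    out[use_stratum] <- rate_from_counts(cnt_o[use_stratum],
                                         cnt_tot[use_stratum],
                                         off[use_stratum], pc)
  unname(out)
}

#' Mask obvious editing sites before rate estimation
#'
#' C->T editing inflates the apparent C->T error rate, so the most obvious
#' editing sites are excluded from mismatch-rate estimation. A C column is
#' masked when its pooled (all supplied libraries) `T/(C+T)` fraction is at
#' least `threshold`.
#'
#' @param pileups a single pileup or a list of per-library pileups.
#' @param threshold pooled T-fraction at or above which a C column is masked
#'   (default 0.02).
#' @return data.table of masked `template_id`, `position` rows.
#' @export
auto_mask <- function(pileups, threshold = 0.02) {
  if (inherits(pileups, "pileup")) pileups <- list(pileups)
  all <- rbindlist(lapply(pileups, as.data.table))
  cnt <- all[ref == "C" & obs %in% c("C", "T"),
             .(t_frac_pooled = sum(n[obs == "T"]) / sum(n)),
             by = .(template_id, position)]
  out <- cnt[t_frac_pooled >= threshold, .(template_id, position)]
  setkey(out, template_id, position)
  out[]
}

#' Serialize / read a mismatch-rate table as TSV
#'
#' Long format: `library`, `read_position`, `ref`, `obs`, `count`, `rate`
#' (pooled rows use read_position 0).
#'
#' @param rates a `mismatch_rates` object.
#' @param path output TSV path.
#' @export
write_rate_table <- function(rates, path) {
  maxpos <- dim(rates$counts)[1L]
  grid <- CJ(read_position = 0:maxpos, ref = BASES, obs = BASES)
  cnt <- ifelse(grid$read_position == 0L,
                rates$pooled[cbind(grid$ref, grid$obs)],
                rates$counts[cbind(pmax(grid$read_position, 1L),
                                   match(grid$ref, BASES),
                                   match(grid$obs, BASES))])
  grid[, `:=`(library = rates$library_id, count = cnt)]
  grid[, rate := {
    tot <- sum(count)
    rate_from_counts(count, tot, as.numeric(ref != obs), rates$pseudocount)
  }, by = .(read_position, ref)]
  setcolorder(grid, c("library", "read_position", "ref", "obs", "count", "rate"))
  fwrite(grid, path, sep = "\t")
  invisible(path)
}
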