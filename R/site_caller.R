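#' Log-likelihood of a pileup column under an editing fraction
#'
#' At a template C, each (non-N) observation of base `o` at read position `i`
#' contributes `log[(1 - theta) * P_i(o|C) + theta * P_i(o|T)]`: with
#' probability `theta` the sequenced molecule is edited (template base behaves
#' as T), otherwise it is unedited, and the empirical position-on-read error
#' channel is applied either way. The column log-likelihood is the sum over
#' observations; an empty column has log-likelihood 0 by convention.
#'
#' @param column a [pileup_column()] data.table (`read_pos`, `obs`, `n`).
#' @param rates a `mismatch_rates` object.
#' @param theta editing fraction(s) in `[0, 1]`.
#' @return numeric vector, one log-likelihood per `theta`.
#' @export
site_log_likelihood <- function(column, rates, theta) {
  stopifnot(all(theta >= 0 & theta <= 1))
  col <- column[obs != "N"]
  if (nrow(col) == 0L) return(rep(0, length(theta)))
  if (!all(col$ref == "C")) stop("site_log_likelihood requires a C column")
  pC <- rate_lookup(rates, col$read_pos, "C", col$obs)
  pT <- rate_lookup(rates, col$read_pos, "T", col$obs)
  vapply(theta, function(th) sum(col$n * log((1 - th) * pC + th * pT)),
         numeric(1))
}

# core fit shared by call_editing_site and the vectorized driver: takes the
# precomputed per-observation channel probabilities and aggregated counts
fit_theta <- function(pC, pT, n, tol = 1e-8) {
  ll <- function(th) sum(n * log((1 - th) * pC + th * pT))
  ll0 <- sum(n * log(pC))
  opt <- optimize(ll, c(0, 1), maximum = TRUE, tol = tol)
  theta <- opt$maximum
  lrt <- 2 * (opt$objective - ll0)
  # Brent never lands exactly on the boundary; snap to the null when it wins
  if (lrt <= 0) { theta <- 0; lrt <- 0 }
  list(theta_hat = theta, lrt = lrt,
       pvalue = pchisq(lrt, df = 1L, lower.tail = FALSE))
}

#' Call one editing site
#'
#' Maximum-likelihood editing fraction and likelihood-ratio test for a single
#' pileup column: `theta_hat = argmax L(theta)` over `[0, 1]` (Brent, absolute
#' tolerance 1e-8), `lrt = 2 (L(theta_hat) - L(0))`, and the p-value is the
#' chi-square(1 df) upper tail at `lrt`. Because `theta = 0` lies on the
#' boundary of the parameter space this convention is conservative (the exact
#' null is a half-half mixture of a point mass at 0 and chi-square(1)).
#'
#' @inheritParams site_log_likelihood
#' @return one-row data.table: `c_count`, `t_count`, `other_count`, `depth`,
#'   `t_fraction`, `theta_hat`, `lrt`, `pvalue`. An uncovered column yields
#'   `theta_hat = 0`, `lrt = 0`, `pvalue = 1`, `depth = 0`.
#' @export
call_editing_site <- function(column, rates) {
  col <- column[obs != "N"]
  cc <- sum(col$n[col$obs == "C"])
  tc <- sum(col$n[col$obs == "T"])
  oc <- sum(col$n[!col$obs %in% c("C", "T")])
  depth <- cc + tc + oc
  tf <- if (cc + tc > 0L) tc / (cc + tc) else NA_real_
  if (depth == 0L || tc == 0L)
    return(data.table(c_count = cc, t_count = tc, other_count = oc,
                      depth = depth, t_fraction = tf,
                      theta_hat = 0, lrt = 0, pvalue = 1))
  pC <- rate_lookup(rates, col$read_pos, "C", col$obs)
  pT <- rate_lookup(rates, col$read_pos, "T", col$obs)
  fit <- fit_theta(pC, pT, col$n)
  data.table(c_count = cc, t_count = tc, other_count = oc, depth = depth,
             t_fraction = tf, theta_hat = fit$theta_hat, lrt = fit$lrt,
             pvalue = fit$pvalue)
}

#' Call every covered C column of a pileup
#'
#' Lower-level driver behind [call_sites()]: fits the editing-fraction MLE and
#' LRT at every `ref == "C"` column present in the pileup (covered sites
#' only; no template universe needed, which suits count-level simulated
#' pileups).
#'
#' @param pileup a `pileup` data.table.
#' @param rates a `mismatch_rates` object.
#' @return data.table with one row per covered C column: counts, `t_fraction`,
#'   `theta_hat`, `lrt`, `pvalue`.
#' @export
call_columns <- function(pileup, rates) {
  cols <- pileup[ref == "C" & obs != "N"]
  if (nrow(cols)) {
    # one vectorized channel lookup for all (read_pos, obs) pairs
    cols[, `:=`(pC = rate_lookup(rates, read_pos, "C", obs),
                pT = rate_lookup(rates, read_pos, "T", obs))]
    called <- cols[, {
      cc <- sum(n[obs == "C"]); tc <- sum(n[obs == "T"])
      oc <- sum(n[!obs %in% c("C", "T")])
      if (tc == 0L) {
        list(c_count = cc, t_count = tc, other_count = oc,
             depth = cc + tc + oc,
             t_fraction = if (cc + tc > 0L) 0 else NA_real_,
             theta_hat = 0, lrt = 0, pvalue = 1)
      } else {
        fit <- fit_theta(pC, pT, n)
        list(c_count = cc, t_count = tc, other_count = oc,
             depth = cc + tc + oc, t_fraction = tc / (cc + tc),
             theta_hat = fit$theta_hat, lrt = fit$lrt, pvalue = fit$pvalue)
      }
    }, by = .(template_id, position)]
  } else {
    called <- data.table(template_id = character(), position = integer(),
                         c_count = integer(), t_count = integer(),
                         other_count = integer(), depth = integer(),
                         t_fraction = numeric(), theta_hat = numeric(),
                         lrt = numeric(), pvalue = numeric())
  }
  called[]
}

#' Call every template C position of one library
#'
#' Runs the editing-fraction fit of [call_columns()] over the full C-site scan
#' universe of the template set, including uncovered positions (reported with
#' depth 0 and p-value 1), and flags per-library significance at `alpha_site`
#' (strict `pvalue < alpha_site`).
#'
#' @param pileup per-library [build_pileup()] result.
#' @param rates the library's `mismatch_rates`.
#' @param templates a [template_set()].
#' @param library_id label attached to the calls.
#' @param alpha_site per-site significance cutoff (default 1e-6).
#' @return data.table of SiteCalls: `template_id`, `position`, `library_id`,
#'   counts, `t_fraction`, `theta_hat`, `lrt`, `pvalue`, `significant`.
#' @export
call_sites <- function(pileup, rates, templates, library_id = NA_character_,
                       alpha_site = 1e-6) {
  universe <- c_positions(templates)
  cols <- pileup[universe, on = c("template_id", "position"), nomatch = NULL]
  called <- call_columns(cols, rates)
  out <- merge(universe[, .(template_id, position)], called,
               by = c("template_id", "position"), all.x = TRUE)
  out[is.na(pvalue), `:=`(c_count = 0L, t_count = 0L, other_count = 0L,
                          depth = 0L, t_fraction = NA_real_, theta_hat = 0,
                          lrt = 0, pvalue = 1)]
  out[, `:=`(library_id = library_id, significant = pvalue < alpha_site)]
  setkey(out, template_id, position)
  out[]
}

#' Call one library and return its significant set
#'
#' @inheritParams call_sites
#' @return list with `calls` (all SiteCalls, see [call_sites()]) and
#'   `significant` (data.table of sites with `pvalue < alpha_site`).
#' @export
call_sample <- function(pileup, rates, templates, library_id = NA_character_,
                        alpha_site = 1e-6) {
  calls <- call_sites(pileup, rates, templates, library_id, alpha_site)
  list(calls = calls,
       significant = calls[significant == TRUE, .(template_id, position)])
}

#' Combine per-library calls into the candidate editing-site set
#'
#' A site is a candidate when (i) its LRT p-value is below `alpha_site` in at
#' least one library, (ii) its editing fraction `T/(C+T)` exceeds
#' `min_fraction` in at least one library, and (iii) its mean read depth
#' across all libraries exceeds `min_mean_depth` (all inequalities strict;
#' libraries not covering a site contribute depth 0 to the mean).
#'
#' @param all_calls rbind of [call_sites()] outputs across libraries.
#' @param min_fraction editing-fraction filter (default 0.05).
#' @param min_mean_depth mean-depth filter (default 100).
#' @param alpha_site per-site significance cutoff (default 1e-6).
#' @param n_libraries number of libraries the depth mean is taken over;
#'   defaults to the number of distinct `library_id`s present.
#' @return data.table per site: `max_t_fraction`, `mean_depth`,
#'   `passed_union`, `passed_fraction`, `passed_depth`, `selected`.
#' @export
select_candidates <- function(all_calls, min_fraction = 0.05,
                              min_mean_depth = 100, alpha_site = 1e-6,
                              n_libraries = NULL) {
  if (nrow(all_calls) == 0L) stop("no calls supplied")
  if (is.null(n_libraries))
    n_libraries <- length(unique(all_calls$library_id))
  if (n_libraries == 0L) stop("empty library set")
  per_site <- all_calls[, .(
    passed_union = any(pvalue < alpha_site),
    max_t_fraction = if (all(is.na(t_fraction))) NA_real_
                     else max(t_fraction, na.rm = TRUE),
    mean_depth = sum(depth) / n_libraries
  ), by = .(template_id, position)]
  per_site[, passed_fraction := !is.na(max_t_fraction) &
                                max_t_fraction > min_fraction]
  per_site[, passed_depth := mean_depth > min_mean_depth]
  per_site[, selected := passed_union & passed_fraction & passed_depth]
  setkey(per_site, template_id, position)
  per_site[]
}

#' Editing extent
#'
#' The fraction of edited transcripts at a site, `T / (C + T)` read counts.
#'
#' @param c_count,t_count unedited (C) and edited (T) read counts.
#' @return numeric vector of extents in `[0, 1]`.
#' @export
editing_extent <- function(c_count, t_count) {
  denom <- c_count + t_count
  if (any(denom <= 0)) stop("editing extent undefined: C + T = 0")
  t_count / denom
}

#' Classify an edit as silent, non-silent, or non-coding
#'
#' Compares the amino acid encoded by the codon containing the C before and
#' after the C->T change, using the template's coding-region annotation
#' (`cds_start`/`cds_end`, frame 0 at `cds_start`). Sites outside the
#' annotated coding region (or on templates without one) are `non_coding`.
#'
#' @param templates a [template_set()].
#' @param template_id,position the site(s); must be template Cs.
#' @return character vector in `{"silent", "non_silent", "non_coding"}`.
#' @export
annotate_silent <- function(templates, template_id, position) {
  idx <- match(template_id, templates$info$template_id)
  info <- templates$info[idx]
  position <- as.integer(position)
  out <- rep("non_coding", length(position))
  for (k in seq_along(position)) {
    cs <- info$cds_start[k]; ce <- info$cds_end[k]
    if (is.na(cs) || is.na(ce)) next
    if ((ce - cs + 1L) %% 3L != 0L || ce > nchar(templates$seq[[template_id[k]]]))
      stop("coding-region annotation inconsistent with template ",
           template_id[k])
    p <- position[k]
    if (p < cs || p > ce) next
    if (template_base(templates, template_id[k], p) != "C")
      stop("annotate_silent: base at ", template_id[k], ":", p, " is not C")
    off <- p - cs
    codon_start <- cs + 3L * (off %/% 3L)
    codon <- substr(templates$seq[[template_id[k]]], codon_start, codon_start + 2L)
    edited <- codon
    substr(edited, off %% 3L + 1L, off %% 3L + 1L) <- "T"
    aa <- Biostrings::GENETIC_CODE[[codon]]
    aa2 <- Biostrings::GENETIC_CODE[[edited]]
    out[k] <- if (identical(aa, aa2)) "silent" else "non_silent"
  }
  out
}
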