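#' Pool replicate counts
#'
#' Biological replicates of a genotype are pooled by summing C and T read
#' counts element-wise before any testing.
#'
#' @param counts list of `c(c, t)` pairs, or a two-column matrix/data.frame
#'   with columns `(c, t)`.
#' @return named numeric vector `c(c = ..., t = ...)`.
#' @export
pool_replicates <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    if (length(counts) == 0L) stop("no replicate counts to pool")
    m <- do.call(rbind, counts)
  } else {
    m <- as.matrix(counts)
  }
  if (nrow(m) == 0L) stop("no replicate counts to pool")
  stopifnot(ncol(m) == 2L)
  c(c = sum(m[, 1L]), t = sum(m[, 2L]))
}

#' Pearson chi-square test on a 2x2 count table
#'
#' Tests whether the editing proportion differs between two genotypes, using
#' the plain Pearson statistic `sum((O - E)^2 / E)` with expected cells from
#' the row/column marginals, one degree of freedom, and no continuity
#' correction. A zero marginal (a genotype with no reads, or no T and no C
#' anywhere) leaves the statistic undefined; such tests are returned as
#' excluded rather than raising.
#'
#' @param c1,t1 genotype A unedited/edited counts.
#' @param c2,t2 genotype B unedited/edited counts.
#' @return list with `chisq`, `pvalue`, `df = 1`, `excluded` (logical).
#' @export
chisq_2x2 <- function(c1, t1, c2, t2) {
  if (any(c(c1, t1, c2, t2) < 0)) stop("negative counts")
  O <- matrix(c(c1, t1, c2, t2), nrow = 2L, byrow = TRUE)
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  if (any(rs == 0) || any(cs == 0))
    return(list(chisq = NA_real_, pvalue = NA_real_, df = 1L, excluded = TRUE))
  E <- outer(rs, cs) / N
  stat <- sum((O - E)^2 / E)
  list(chisq = stat, pvalue = pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L, excluded = FALSE)
}

#' Bonferroni nominal threshold
#'
#' Familywise error control by dividing the target familywise rate by the
#' number of tests performed: with 619 mitochondrial sites and a familywise
#' rate of 1e-3 the nominal per-test threshold is 1.6e-6; with the 37 plastid
#' sites it is 2.7e-5.
#'
#' @param alpha_family target familywise error rate.
#' @param n_tests number of tests in the family (>= 1).
#' @return the nominal per-test rate (full precision; summaries print it to 2
#'   significant figures).
#' @export
bonferroni_threshold <- function(alpha_family, n_tests) {
  if (n_tests < 1L) stop("n_tests must be >= 1")
  alpha_family / n_tests
}

#' Change in editing extent (delta-EE)
#'
#' `(reference extent - test extent) / reference extent`: the relative drop of
#' editing in the mutant (or silenced) genotype against its comparator.
#' Negative values mean an editing increase.
#'
#' @param ref_extent,test_extent editing extents of the comparator and test
#'   genotypes.
#' @return numeric; `NA` when the reference extent is 0.
#' @export
delta_ee <- function(ref_extent, test_extent) {
  ifelse(ref_extent > 0, (ref_extent - test_extent) / ref_extent, NA_real_)
}

diff_row <- function(wt, mut, nominal, delta_cut) {
  wt_ext <- if (sum(wt) > 0) unname(wt["t"] / sum(wt)) else NA_real_
  mut_ext <- if (sum(mut) > 0) unname(mut["t"] / sum(mut)) else NA_real_
  tst <- chisq_2x2(wt["c"], wt["t"], mut["c"], mut["t"])
  dee <- if (!is.na(wt_ext) && wt_ext > 0 && !is.na(mut_ext))
    (wt_ext - mut_ext) / wt_ext else NA_real_
  if (tst$excluded || is.na(dee)) {
    cls <- "excluded"
    reason <- if (tst$excluded) "degenerate_marginal" else "zero_wildtype_extent"
  } else {
    cls <- if (tst$pvalue < nominal && dee >= delta_cut) "dependent"
           else "independent"
    reason <- NA_character_
  }
  data.table(wt_extent = wt_ext, mut_extent = mut_ext, delta_ee = dee,
             chisq = tst$chisq, chisq_p = tst$pvalue, nominal = nominal,
             class = cls, reason = reason)
}

#' Classify a site: mutant vs wild-type sibling
#'
#' Applies the dependence rule: if the chi-square p-value is not below the
#' Bonferroni nominal threshold the site is factor-independent; otherwise it
#' is dependent when the editing-extent drop `delta_ee >= delta_cut` (default
#' 0.1) and independent below. Editing increases (negative delta) are reported
#' but never classified dependent. A site whose wild-type extent is 0 (delta
#' undefined) or whose 2x2 table has a zero marginal is excluded with a
#' reason code.
#'
#' @param wt,mut pooled `c(c, t)` count pairs (see [pool_replicates()]).
#' @param nominal Bonferroni nominal p-value threshold.
#' @param delta_cut dependence cutoff on delta-EE (default 0.1).
#' @return one-row data.table: `wt_extent`, `mut_extent`, `delta_ee`, `chisq`,
#'   `chisq_p`, `nominal`, `class` in `{dependent, independent, excluded}`,
#'   `reason`.
#' @export
classify_vs_wildtype <- function(wt, mut, nominal, delta_cut = 0.1) {
  stopifnot(length(wt) == 2L, length(mut) == 2L)
  names(wt) <- names(mut) <- c("c", "t")
  diff_row(wt, mut, nominal, delta_cut)
}

#' Classify a site: silenced plant vs two controls
#'
#' Silencing is delivered by virus inoculation, which can itself perturb
#' editing, so a silenced genotype is compared against both an uninoculated
#' control and a GFP-silenced (vector-only) control. The site is excluded from
#' the silenced-comparison universe when the GFP-silenced control itself shows
#' a significant reduction against the uninoculated control (same chi-square +
#' delta rule); otherwise it is dependent only when the rule holds against
#' *both* controls. The reported extents and delta anchor on the uninoculated
#' control.
#'
#' @param sil,uninoc,gfp_sil pooled `c(c, t)` count pairs for the silenced
#'   plant, the uninoculated control, and the GFP-silenced control.
#' @inheritParams classify_vs_wildtype
#' @return one-row data.table as in [classify_vs_wildtype()] (`wt_*` columns
#'   refer to the uninoculated control).
#' @export
classify_silenced <- function(sil, uninoc, gfp_sil, nominal, delta_cut = 0.1) {
  stopifnot(length(sil) == 2L, length(uninoc) == 2L, length(gfp_sil) == 2L)
  names(sil) <- names(uninoc) <- names(gfp_sil) <- c("c", "t")
  ctrl <- diff_row(uninoc, gfp_sil, nominal, delta_cut)
  if (ctrl$class == "dependent") {
    out <- diff_row(uninoc, sil, nominal, delta_cut)
    out[, `:=`(class = "excluded", reason = "gfp_control_reduced")]
    return(out[])
  }
  vs_uninoc <- diff_row(uninoc, sil, nominal, delta_cut)
  vs_gfp <- diff_row(gfp_sil, sil, nominal, delta_cut)
  out <- vs_uninoc
  if (out$class == "dependent" && !identical(vs_gfp$class, "dependent"))
    out[, class := "independent"]
  out[]
}

#' Summarize dependent/independent counts
#'
#' Counts and integer percentages (round half up) of dependent vs independent
#' sites, optionally split by a grouping column (e.g. organelle or gene).
#' Excluded sites are reported separately; percentages are over the analyzed
#' (non-excluded) universe.
#'
#' @param results data.table with a `class` column (and optionally the column
#'   named in `by`).
#' @param by optional grouping column name.
#' @return data.table with `n_dependent`, `n_independent`, `n_excluded`,
#'   `n_analyzed`, `pct_dependent`, `pct_independent`.
#' @export
summarize_classification <- function(results, by = NULL) {
  grp <- if (is.null(by)) character(0) else by
  out <- as.data.table(results)[, {
    nd <- sum(class == "dependent"); ni <- sum(class == "independent")
    nx <- sum(class == "excluded"); na <- nd + ni
    list(n_dependent = nd, n_independent = ni, n_excluded = nx,
         n_analyzed = na,
         pct_dependent = if (na > 0) round_half_up(100 * nd / na) else 0,
         pct_independent = if (na > 0) round_half_up(100 * ni / na) else 0)
  }, by = grp]
  out[]
}

#' Differential editing analysis over a count matrix
#'
#' Runs the replicate-pooling, chi-square, and classification machinery over a
#' per-site per-library count table for one comparison. The Bonferroni nominal
#' threshold is `alpha_family / (number of analyzed sites)`.
#'
#' @param counts data.table with columns `site`, `library_id`, `c_count`,
#'   `t_count` (long format; one row per site x library).
#' @param test_libs,ref_libs library ids of the test genotype (replicates are
#'   pooled) and of the reference genotype.
#' @param gfp_libs optional library ids of a GFP-silenced control; when given,
#'   the dual-control silenced logic of [classify_silenced()] is applied with
#'   `ref_libs` as the uninoculated control.
#' @param alpha_family familywise error rate (default 1e-3).
#' @param delta_cut dependence cutoff on delta-EE (default 0.1).
#' @return data.table with one row per site: pooled counts, extents,
#'   `delta_ee`, `chisq`, `chisq_p`, `nominal`, `class`, `reason`.
#' @export
differential_test <- function(counts, test_libs, ref_libs, gfp_libs = NULL,
                              alpha_family = 1e-3, delta_cut = 0.1) {
  dt <- as.data.table(counts)
  need <- c("site", "library_id", "c_count", "t_count")
  if (!all(need %in% names(dt)))
    stop("counts must have columns ", paste(need, collapse = ", "))
  pool <- function(libs) dt[library_id %in% libs,
                            .(c = sum(c_count), t = sum(t_count)), by = site]
  test <- pool(test_libs); ref <- pool(ref_libs)
  sites <- sort(unique(dt$site))
  nominal <- bonferroni_threshold(alpha_family, length(sites))
  gfp <- if (!is.null(gfp_libs)) pool(gfp_libs) else NULL
  grab <- function(tab, s) {
    i <- match(s, tab$site)
    if (is.na(i)) c(c = 0, t = 0) else c(c = tab$c[i], t = tab$t[i])
  }
  res <- rbindlist(lapply(sites, function(s) {
    if (is.null(gfp))
      classify_vs_wildtype(grab(ref, s), grab(test, s), nominal, delta_cut)
    else
      classify_silenced(grab(test, s), grab(ref, s), grab(gfp, s), nominal,
                        delta_cut)
  }))
  res[, site := sites]
  setcolorder(res, "site")
  res[]
}
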