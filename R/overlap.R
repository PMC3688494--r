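#' Build a site x factor classification matrix
#'
#' @param results named list of per-factor classification tables (each a
#'   [differential_test()] result with columns `site` and `class`).
#' @return data.table with a `site` column and one column per factor holding
#'   `dependent` / `independent` / `excluded` (sites absent from a factor's
#'   table are `excluded` for that factor).
#' @export
classification_matrix <- function(results) {
  if (is.null(names(results)) || any(names(results) == ""))
    stop("results must be a named list (one name per factor)")
  sites <- sort(unique(unlist(lapply(results, function(r) r$site))))
  out <- data.table(site = sites)
  for (f in names(results)) {
    r <- as.data.table(results[[f]])
    out[, (f) := r$class[match(sites, r$site)]]
    out[is.na(get(f)), (f) := "excluded"]
  }
  out[]
}

#' Venn-region counts of factor-dependent sites
#'
#' Counts sites in each of the `2^k` membership regions of up to three
#' factors' dependent sets. Sites excluded for any of the chosen factors are
#' dropped listwise; the remaining region counts partition the analyzed set.
#'
#' @param matrix a [classification_matrix()].
#' @param factors character vector of 1-3 factor column names.
#' @return data.table with `region` (factor names joined by `+`, or `"none"`),
#'   `count`, plus an attribute `n_analyzed`.
#' @export
venn_counts <- function(matrix, factors) {
  if (length(factors) < 1L || length(factors) > 3L)
    stop("venn_counts supports 1 to 3 factors")
  if (!all(factors %in% names(matrix))) stop("unknown factor column(s)")
  m <- as.data.table(matrix)
  keep <- Reduce(`&`, lapply(factors, function(f) m[[f]] != "excluded"))
  m <- m[keep]
  dep <- as.data.table(lapply(factors, function(f) m[[f]] == "dependent"))
  setnames(dep, factors)
  combos <- do.call(CJ, setNames(rep(list(c(TRUE, FALSE)), length(factors)),
                                 factors))
  counts <- vapply(seq_len(nrow(combos)), function(i) {
    sel <- Reduce(`&`, lapply(factors, function(f)
      dep[[f]] == combos[[f]][i]))
    sum(sel)
  }, integer(1))
  region <- vapply(seq_len(nrow(combos)), function(i) {
    inset <- factors[unlist(combos[i])]
    if (length(inset) == 0L) "none" else paste(inset, collapse = "+")
  }, character(1))
  out <- data.table(region = region, count = counts)
  setattr(out, "n_analyzed", nrow(m))
  out[]
}

#' Overlap percentage
#'
#' `round(100 * shared / total)`, half up — the style used when reporting,
#' e.g., the fraction of sites controlled by one factor that are also
#' controlled by another (112/127 -> 88).
#'
#' @param shared,total counts with `total > 0`.
#' @return integer percent.
#' @export
overlap_percentage <- function(shared, total) {
  if (any(total <= 0)) stop("total must be > 0")
  as.integer(round_half_up(100 * shared / total))
}

#' Chi-square test of independence between two factors' classifications
#'
#' Builds the 2x2 joint table of dependent/independent memberships over the
#' sites analyzed for both factors (listwise exclusion) and applies
#' [chisq_2x2()], also reporting the observed and expected-under-independence
#' cell counts (an excess of observed doubly-dependent sites indicates a
#' synergistic pair).
#'
#' @param matrix a [classification_matrix()].
#' @param factor_a,factor_b factor column names.
#' @return list with `chisq`, `pvalue`, `df`, `excluded`, `observed` and
#'   `expected` (2x2 matrices, rows = factor A dependent/independent, columns
#'   = factor B), `n_analyzed`.
#' @export
factor_independence_test <- function(matrix, factor_a, factor_b) {
  m <- as.data.table(matrix)
  m <- m[get(factor_a) != "excluded" & get(factor_b) != "excluded"]
  a <- factor(m[[factor_a]], levels = c("dependent", "independent"))
  b <- factor(m[[factor_b]], levels = c("dependent", "independent"))
  O <- as.matrix(table(a, b))
  tst <- chisq_2x2(O[1, 1], O[1, 2], O[2, 1], O[2, 2])
  E <- if (tst$excluded) matrix(NA_real_, 2, 2)
       else outer(rowSums(O), colSums(O)) / sum(O)
  dimnames(E) <- dimnames(O)
  c(tst, list(observed = O, expected = E, n_analyzed = nrow(m)))
}
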