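#' Write a site table (TSV)
#'
#' Fixed-header TSV of per-site calls and, when present, differential results.
#' Header: `template`, `gene`, `position`, `ref`, `C_count`, `T_count`,
#' `depth`, `T_fraction`, `theta_hat`, `lrt`, `pvalue`, and for differential
#' tables additionally `wt_extent`, `mut_extent`, `delta_EE`, `chisq`,
#' `chisq_p`, `class`. Floating-point values are printed with 8 significant
#' digits; rows are ordered deterministically by (template, position). The
#' file round-trips unchanged through [read_site_table()].
#'
#' @param calls data.table of [call_sites()] output, optionally merged with
#'   differential columns (`wt_extent`, `mut_extent`, `delta_ee`, `chisq`,
#'   `chisq_p`, `class`).
#' @param path output TSV path.
#' @param templates optional [template_set()] used to fill the `gene` column.
#' @export
write_site_table <- function(calls, path, templates = NULL) {
  dt <- as.data.table(calls)
  out <- data.table(
    template = dt$template_id,
    gene = if (!is.null(templates))
      templates$info[J(dt$template_id), on = "template_id"]$gene
    else if ("gene" %in% names(dt)) dt$gene else dt$template_id,
    position = dt$position,
    ref = if ("ref" %in% names(dt)) dt$ref else "C",
    C_count = dt$c_count,
    T_count = dt$t_count,
    depth = dt$depth,
    T_fraction = dt$t_fraction,
    theta_hat = dt$theta_hat,
    lrt = dt$lrt,
    pvalue = dt$pvalue
  )
  diffcols <- c(wt_extent = "wt_extent", mut_extent = "mut_extent",
                delta_EE = "delta_ee", chisq = "chisq", chisq_p = "chisq_p",
                class = "class")
  if (any(names(diffcols) %in% names(dt)) || any(diffcols %in% names(dt))) {
    for (k in seq_along(diffcols)) {
      src <- diffcols[k]
      if (src %in% names(dt)) out[, (names(diffcols)[k]) := dt[[src]]]
    }
  }
  setorder(out, template, position)
  num <- names(out)[vapply(out, is.double, logical(1))]
  for (cn in num) out[, (cn) := signif(get(cn), 8)]
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a site table written by [write_site_table()]
#'
#' @param path TSV path.
#' @return data.table in the internal naming (`template_id`, `position`, ...,
#'   `c_count`, `t_count`, `t_fraction`, and `delta_ee` etc. when present).
#' @export
read_site_table <- function(path) {
  dt <- fread(path, sep = "\t", na.strings = "NA",
              colClasses = list(character = c("template", "ref")))
  setnames(dt, old = c("template", "C_count", "T_count", "T_fraction"),
           new = c("template_id", "c_count", "t_count", "t_fraction"),
           skip_absent = TRUE)
  if ("delta_EE" %in% names(dt)) setnames(dt, "delta_EE", "delta_ee")
  setkey(dt, template_id, position)
  dt[]
}

#' Read a per-site per-library count matrix
#'
#' Long-format TSV with columns `site`, `library_id`, `c_count`, `t_count`
#' (one row per site x library) — the shape of a per-editing-site read-count
#' supplement — for replaying a differential analysis without going through
#' read-level data. An optional `organelle` column is carried through.
#'
#' @param path TSV path.
#' @return data.table with the columns above.
#' @export
read_count_matrix <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("site", "library_id")))
  need <- c("site", "library_id", "c_count", "t_count")
  if (!all(need %in% names(dt)))
    stop("count matrix must have columns ", paste(need, collapse = ", "))
  dt[]
}
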