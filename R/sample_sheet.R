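#' Read and validate a sample sheet
#'
#' TSV (or YAML with a `libraries:` list) mapping libraries to genotypes and
#' comparison roles. Columns: `library_id`, `genotype`, `role` (one of
#' `mutant`, `wildtype_sibling`, `silenced`, `uninoculated_control`,
#' `gfp_silenced_control`, `spike_control`), `comparison` (group id tying a
#' mutant to its wild-type sibling; silenced libraries share a comparison
#' group with both controls), and optional `replicate_group`.
#'
#' Validation: library ids unique; roles known; every mutant comparison group
#' contains exactly one wild-type sibling genotype; every silenced comparison
#' group contains both an uninoculated and a GFP-silenced control.
#'
#' @param path sample sheet path (.tsv/.txt or .yml/.yaml).
#' @return data.table of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    dt <- rbindlist(y$libraries, fill = TRUE)
  } else {
    dt <- fread(path, sep = "\t", colClasses = "character")
  }
  validate_sample_sheet(dt)
}

#' @rdname read_sample_sheet
#' @param sheet a data.frame/data.table with the sample-sheet columns.
#' @export
validate_sample_sheet <- function(sheet) {
  dt <- as.data.table(sheet)
  need <- c("library_id", "genotype", "role", "comparison")
  if (!all(need %in% names(dt)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  if (nrow(dt) == 0L) stop("empty sample sheet")
  if (anyDuplicated(dt$library_id)) stop("duplicated library_id in sample sheet")
  roles <- c("mutant", "wildtype_sibling", "silenced", "uninoculated_control",
             "gfp_silenced_control", "spike_control")
  bad <- setdiff(unique(dt$role), roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (!"replicate_group" %in% names(dt)) dt[, replicate_group := library_id]

  for (cmp in unique(dt[role == "mutant"]$comparison)) {
    wt <- unique(dt[comparison == cmp & role == "wildtype_sibling"]$genotype)
    if (length(wt) != 1L)
      stop("comparison '", cmp, "': a mutant needs exactly one wild-type ",
           "sibling genotype (found ", length(wt), ")")
  }
  for (cmp in unique(dt[role == "silenced"]$comparison)) {
    has_un <- nrow(dt[comparison == cmp & role == "uninoculated_control"]) > 0L
    has_gfp <- nrow(dt[comparison == cmp & role == "gfp_silenced_control"]) > 0L
    if (!has_un || !has_gfp)
      stop("comparison '", cmp, "': silenced libraries need both an ",
           "uninoculated and a GFP-silenced control")
  }
  setattr(dt, "class", c("sample_sheet", class(dt)))
  dt[]
}

#' Enumerate the genotype comparisons of a sample sheet
#'
#' @param sheet a validated sample sheet.
#' @return data.table with one row per comparison: `comparison`, `type`
#'   (`mutant` or `silenced`), `test_genotype`, and list columns `test_libs`,
#'   `ref_libs`, `gfp_libs` (replicates pooled downstream).
#' @export
sheet_comparisons <- function(sheet) {
  dt <- as.data.table(sheet)
  out <- list()
  for (cmp in unique(dt[role == "mutant"]$comparison)) {
    for (g in unique(dt[comparison == cmp & role == "mutant"]$genotype)) {
      out[[length(out) + 1L]] <- data.table(
        comparison = cmp, type = "mutant", test_genotype = g,
        test_libs = list(dt[comparison == cmp & genotype == g]$library_id),
        ref_libs = list(dt[comparison == cmp & role == "wildtype_sibling"]$library_id),
        gfp_libs = list(character(0)))
    }
  }
  for (cmp in unique(dt[role == "silenced"]$comparison)) {
    for (g in unique(dt[comparison == cmp & role == "silenced"]$genotype)) {
      out[[length(out) + 1L]] <- data.table(
        comparison = cmp, type = "silenced", test_genotype = g,
        test_libs = list(dt[comparison == cmp & genotype == g]$library_id),
        ref_libs = list(dt[comparison == cmp & role == "uninoculated_control"]$library_id),
        gfp_libs = list(dt[comparison == cmp & role == "gfp_silenced_control"]$library_id))
    }
  }
  if (!length(out)) stop("sample sheet defines no comparisons")
  rbindlist(out)
}
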