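#' Run the full editing-analysis pipeline
#'
#' Wires the modules into the standard workflow: per library, read its SAM,
#' filter the records, and build a pileup; estimate per-library mismatch rates
#' with auto-masking; call every template C site; combine libraries with the
#' candidate filters; run the differential comparisons defined by the sample
#' sheet on the candidate sites (replicates pooled, Bonferroni nominal
#' threshold per organelle partition); and write the factor-overlap summary.
#' All thresholds come from the config and are echoed into `run_config.yaml`;
#' a rerun on the same inputs is byte-identical.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `templates` (FASTA path), `template_metadata` (optional TSV),
#'   `sample_sheet` (TSV/YAML path), `alignments` (named list/ mapping
#'   `library_id` -> SAM path), `out_dir`, and optional thresholds
#'   `alpha_site` (1e-6), `min_fraction` (0.05), `min_mean_depth` (100),
#'   `alpha_family` (1e-3), `delta_ee_cut` (0.1), `mask_threshold` (0.02).
#' @return invisibly, a list with `calls`, `candidates`, `differential`
#'   (named list per comparison), `summary`, and the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(alpha_site = 1e-6, min_fraction = 0.05,
                   min_mean_depth = 100, alpha_family = 1e-3,
                   delta_ee_cut = 0.1, mask_threshold = 0.02)
  config <- modifyList(defaults, config)
  for (f in c("templates", "sample_sheet", "alignments", "out_dir"))
    if (is.null(config[[f]])) stop("config missing field: ", f)

  sheet <- if (is.character(config$sample_sheet))
    read_sample_sheet(config$sample_sheet) else validate_sample_sheet(config$sample_sheet)
  comparisons <- sheet_comparisons(sheet)  # fails fast on a bad sheet
  libs <- sheet[role != "spike_control"]$library_id
  missing_aln <- setdiff(libs, names(config$alignments))
  if (length(missing_aln))
    stop("no alignment file configured for librar",
         if (length(missing_aln) > 1) "ies: " else "y: ",
         paste(missing_aln, collapse = ", "))

  templates <- read_templates(config$templates, config$template_metadata)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  yaml::write_yaml(config[names(config) != "alignments"],
                   file.path(config$out_dir, "run_config.yaml"))

  pileups <- lapply(setNames(libs, libs), function(lb) {
    aln <- filter_alignments(read_alignments(config$alignments[[lb]]))
    logf("library %s: %d accepted records (rejected: %s)", lb, nrow(aln),
         paste(names(attr(aln, "rejected")), attr(aln, "rejected"),
               sep = "=", collapse = ", "))
    build_pileup(aln, templates)
  })
  mask <- auto_mask(pileups, threshold = config$mask_threshold)
  logf("auto-masked %d columns for rate estimation", nrow(mask))

  calls <- rbindlist(lapply(libs, function(lb) {
    rates <- estimate_mismatch_rates(pileups[[lb]], mask = mask,
                                     library_id = lb)
    call_sites(pileups[[lb]], rates, templates, library_id = lb,
               alpha_site = config$alpha_site)
  }))
  candidates <- select_candidates(calls, min_fraction = config$min_fraction,
                                  min_mean_depth = config$min_mean_depth,
                                  alpha_site = config$alpha_site,
                                  n_libraries = length(libs))
  sel <- candidates[selected == TRUE, .(template_id, position)]
  logf("candidate editing sites: %d of %d scanned C positions", nrow(sel),
       nrow(candidates))
  fwrite(candidates, file.path(config$out_dir, "candidates.tsv"), sep = "\t")
  for (lb in libs)
    write_site_table(calls[library_id == lb],
                     file.path(config$out_dir, paste0("calls_", lb, ".tsv")),
                     templates)

  # long count table on candidate sites, named gene-position
  counts <- calls[sel, on = c("template_id", "position")]
  counts[, site := site_name(templates, template_id, position)]
  counts <- merge(counts,
                  templates$info[, .(template_id, organelle)],
                  by = "template_id")

  diffs <- list()
  for (i in seq_len(nrow(comparisons))) {
    cm <- comparisons[i]
    label <- paste0(cm$test_genotype, "_vs_",
                    if (cm$type == "mutant") "wt" else "controls")
    per_org <- lapply(split(counts, counts$organelle), function(cc) {
      differential_test(cc[, .(site, library_id, c_count, t_count)],
                        test_libs = cm$test_libs[[1L]],
                        ref_libs = cm$ref_libs[[1L]],
                        gfp_libs = if (length(cm$gfp_libs[[1L]]))
                          cm$gfp_libs[[1L]] else NULL,
                        alpha_family = config$alpha_family,
                        delta_cut = config$delta_ee_cut)
    })
    res <- rbindlist(per_org, idcol = "organelle")
    logf("comparison %s: analyzed universe %s", label,
         paste(vapply(names(per_org), function(o)
           sprintf("%s=%d", o, sum(per_org[[o]]$class != "excluded")),
           character(1)), collapse = ", "))
    fwrite(res, file.path(config$out_dir, paste0("diff_", label, ".tsv")),
           sep = "\t")
    diffs[[cm$test_genotype]] <- res
  }

  summary <- rbindlist(lapply(names(diffs), function(g)
    cbind(genotype = g, summarize_classification(diffs[[g]], by = "organelle"))))
  fwrite(summary, file.path(config$out_dir, "classification_summary.tsv"),
         sep = "\t")

  if (length(diffs) >= 2L) {
    for (org in unique(summary$organelle)) {
      per_factor <- lapply(diffs, function(d) d[organelle == org])
      cmat <- classification_matrix(per_factor)
      pairs <- utils::combn(names(diffs), 2L, simplify = FALSE)
      ind <- rbindlist(lapply(pairs, function(p) {
        t <- factor_independence_test(cmat, p[1L], p[2L])
        data.table(organelle = org, factor_a = p[1L], factor_b = p[2L],
                   chisq = t$chisq, pvalue = t$pvalue,
                   n_analyzed = t$n_analyzed)
      }))
      fwrite(ind, file.path(config$out_dir,
                            paste0("factor_independence_", org, ".tsv")),
             sep = "\t")
    }
  }

  invisible(list(calls = calls, candidates = candidates, differential = diffs,
                 summary = summary, out_dir = config$out_dir))
}
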