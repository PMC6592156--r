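#' Configuration for a full corona perturbation analysis
#'
#' Collects every stage parameter of the pipeline (simulate -> quantify ->
#' profile -> enrich -> tree) in one validated list that round-trips
#' losslessly through JSON.
#'
#' @param axis Perturbation axis, `"temperature"` or `"pH"`.
#' @param design A [synthetic_design()]; defaults to
#'   `synthetic_design(axis, seed = seed)`.
#' @param min_peptides Top3 quantification threshold (default 3).
#' @param min_replicates Presence-call threshold (default 2).
#' @param amplitude_threshold,alpha Sigmoid model-selection thresholds.
#' @param boundary Class II/III boundary; default [class_boundary()] of
#'   the axis.
#' @param q_threshold Enrichment FDR threshold (default 0.005).
#' @param n_perm Permutation count for the lessening test.
#' @param n_indices Number of amino-acid indices to analyse: `NULL` uses
#'   every index supplied.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param out_dir Output directory (created if needed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(axis = c("temperature", "pH"),
                            design = NULL,
                            min_peptides = 3L,
                            min_replicates = 2L,
                            amplitude_threshold = 0.5,
                            alpha = 0.05,
                            boundary = NULL,
                            q_threshold = 0.005,
                            n_perm = 999L,
                            n_indices = NULL,
                            seed = 1L,
                            out_dir = tempfile("coronashift_run_")) {
  axis <- match.arg(axis)
  if (is.null(design)) design <- synthetic_design(axis, seed = seed)
  stopifnot(inherits(design, "synthetic_design"), design$axis == axis)
  if (is.null(boundary)) boundary <- class_boundary(axis)
  stopifnot(min_peptides >= 1L, min_replicates >= 1L,
            amplitude_threshold >= 0, alpha > 0, alpha < 1,
            q_threshold > 0, q_threshold <= 1, n_perm >= 100L)
  structure(list(axis = axis, design = design, min_peptides = min_peptides,
                 min_replicates = min_replicates,
                 amplitude_threshold = amplitude_threshold, alpha = alpha,
                 boundary = boundary, q_threshold = q_threshold,
                 n_perm = as.integer(n_perm), n_indices = n_indices,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full corona perturbation pipeline
#'
#' Simulates an experiment from the configured design, quantifies it
#' (Top3 + control subtraction), profiles every persistent protein with
#' sigmoid fits and response classes, runs the dispersion-lessening scan
#' over the supplied amino-acid indices, builds the annotated property
#' MST, and writes all stage outputs plus a machine-readable JSON report
#' and a human-readable text summary into `config$out_dir`. Any stage
#' error aborts with the stage name and cause. Identical configurations
#' (including seed) give byte-identical JSON reports.
#'
#' @param config A [pipeline_config()].
#' @param indices List of [property_index()] objects (default:
#'   [aaindex_properties()]).
#' @param quiet Suppress progress messages.
#' @return The report, invisibly: a list with `quant_summary`,
#'   `class_counts`, `shared`, `persistent`, `enrichment` (significant
#'   rows), `files`, and the echoed configuration.
#' @export
run_pipeline <- function(config, indices = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(indices)) indices <- stage("indices", aaindex_properties())
  if (!is.null(config$n_indices))
    indices <- indices[seq_len(min(config$n_indices, length(indices)))]

  say("simulate: ", config$design$n_proteins, " proteins, axis ", config$axis)
  sim <- stage("simulate", {
    prot <- generate_proteome(config$design, indices = indices)
    exp <- generate_experiment(config$design, prot$truth)
    list(proteome = prot, experiment = exp)
  })
  truth <- sim$proteome$truth
  files <- list()
  files$fasta <- write_proteome_fasta(sim$proteome$sequences,
                                      file.path(config$out_dir, "proteome.fasta"))
  fwrite(truth, file.path(config$out_dir, "truth.tsv"), sep = "\t")
  files$truth <- file.path(config$out_dir, "truth.tsv")
  files$sample <- write_peptide_table(sim$experiment$sample,
                                      file.path(config$out_dir, "peptides_np.tsv"))
  files$control <- write_peptide_table(sim$experiment$control,
                                       file.path(config$out_dir, "peptides_control.tsv"))

  say("quantify: Top3 (min ", config$min_peptides, " peptides) + control subtraction")
  quant <- stage("quantify", {
    m_np <- top3(sim$experiment$sample, min_peptides = config$min_peptides)
    m_ctl <- if (nrow(sim$experiment$control))
      top3(sim$experiment$control, min_peptides = config$min_peptides)
    else m_np[0]
    corrected <- subtract_control(m_np, m_ctl)
    summ <- quant_summary(
      identified = list(peptides = uniqueN(sim$experiment$sample$peptide),
                        proteins = nrow(truth)),
      table = sim$experiment$sample, matrix = m_np)
    list(matrix = corrected, summary = summ)
  })
  files$matrix <- write_abundance_matrix(quant$matrix,
                                         file.path(config$out_dir, "matrix.tsv"))

  say("profile: presence, persistence, sigmoid fits, classes")
  prof <- stage("profile", {
    pres <- presence_calls(quant$matrix, min_replicates = config$min_replicates)
    pers <- persistent_set(pres)
    shared <- shared_counts(pres)
    fits <- fit_profiles(quant$matrix, proteins = pers,
                         amplitude_threshold = config$amplitude_threshold,
                         alpha = config$alpha)
    fits[, class_label := classify(verdict, x_c, direction, config$boundary)]
    list(presence = pres, persistent = pers, shared = shared, fits = fits)
  })
  fwrite(prof$fits, file.path(config$out_dir, "fits.tsv"), sep = "\t")
  files$fits <- file.path(config$out_dir, "fits.tsv")
  fwrite(as.data.table(prof$shared$pairwise, keep.rownames = "condition"),
         file.path(config$out_dir, "shared_counts.tsv"), sep = "\t")
  files$shared <- file.path(config$out_dir, "shared_counts.tsv")
  writeLines(prof$persistent, file.path(config$out_dir, "persistent.txt"))
  files$persistent <- file.path(config$out_dir, "persistent.txt")

  say("enrich: lessening scan over ", length(indices), " properties, ",
      config$n_perm, " permutations")
  enr <- stage("enrich", {
    X <- property_matrix(sim$proteome$sequences, indices)
    scan <- lessening_scan(X, prof$persistent, n_perm = config$n_perm,
                           seed = config$seed + 2L, indices = indices)
    list(scan = scan, significant = enrichment_table(scan, config$q_threshold))
  })
  fwrite(enr$scan, file.path(config$out_dir, "enrichment.tsv"), sep = "\t")
  files$enrichment <- file.path(config$out_dir, "enrichment.tsv")

  say("tree: Kruskal MST over ", length(indices), " properties")
  tree <- stage("tree", {
    g <- build_mst(indices)
    annotate_graph(g, enr$scan, q_threshold = config$q_threshold)
  })
  files$tree <- export_property_graph(tree,
                                      file.path(config$out_dir, "tree.graphml"))

  class_counts <- as.list(table(prof$fits$class_label))
  report <- list(
    config = config_as_list(config),
    quant_summary = quant$summary,
    class_counts = class_counts,
    shared = list(pairwise = as.data.frame(prof$shared$pairwise),
                  n_all = prof$shared$n_all, n_union = prof$shared$n_union,
                  pct_all = prof$shared$pct_all),
    persistent = list(n = length(prof$persistent),
                      pct_of_quantified = 100 * length(prof$persistent) /
                        quant$summary$n_proteins_quantified),
    enrichment = list(n_tested = nrow(enr$scan),
                      n_significant = nrow(enr$significant),
                      significant = as.data.frame(
                        enr$significant[, .(accession, category, L, q, direction)])),
    tree = list(nodes = nrow(tree$nodes), edges = nrow(tree$edges),
                components = tree$n_components,
                total_weight = tree$total_weight),
    files = files)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(report), file.path(config$out_dir, "report.txt"))
  say("done: report written to ", file.path(config$out_dir, "report.json"))
  invisible(report)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$design <- unclass(out$design)
  out$design$enrichment_spec <-
    if (is.null(out$design$enrichment_spec)) NULL
    else out$design$enrichment_spec[c("accession", "shift")]
  out
}

format_report <- function(report) {
  qs <- report$quant_summary
  c(sprintf("corona perturbation pipeline report (axis: %s, seed: %d)",
            report$config$axis, report$config$seed),
    sprintf("quantified proteins: %d (%.0f%% of identified); peptides quantified: %.0f%%; median peptides/protein: %g",
            qs$n_proteins_quantified, 100 * qs$frac_proteins_quantified,
            100 * qs$frac_peptides_quantified, qs$median_peptides_per_protein),
    sprintf("persistent proteins: %d (%.1f%% of union across conditions)",
            report$persistent$n, report$shared$pct_all),
    paste0("class counts: ",
           paste(names(report$class_counts), unlist(report$class_counts),
                 sep = "=", collapse = ", ")),
    sprintf("enrichment: %d/%d properties significant at q < %g",
            report$enrichment$n_significant, report$enrichment$n_tested,
            report$config$q_threshold),
    sprintf("property MST: %d nodes, %d edges, total weight %.3f",
            report$tree$nodes, report$tree$edges, report$tree$total_weight))
}
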