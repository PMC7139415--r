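# End-to-end screen pipeline: qc -> index -> cluster -> rank -> associate,
# with every intermediate written as a stamped TSV.

#' Assemble a pipeline configuration
#'
#' Paths may be NULL when the corresponding stage is skipped or fed from a
#' simulated cohort. A configuration can also be loaded from a YAML file with
#' [read_pipeline_config()].
#'
#' @param readouts path to the readout TSV.
#' @param annotations path to the sample annotation TSV.
#' @param out_dir output directory (created if missing).
#' @param min_signal,min_ratio QC thresholds.
#' @param success_threshold day-6/day-0 success cut-off.
#' @param k number of clusters.
#' @param alpha significance level for dependency labelling.
#' @param subgroups named character vector of subgroup filter expressions to
#'   rank (in addition to the full cohort).
#' @param genes mutation flag columns for the association screen.
#' @param reference reference condition id.
#' @param seed integer seed recorded in the run log.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(readouts = NULL, annotations = NULL,
                            out_dir = "gfscan_out",
                            min_signal = 5000, min_ratio = 0.5,
                            success_threshold = 1,
                            k = 4L, alpha = 0.05,
                            subgroups = c(
                              idh1_mut_intact = "idh1_mut & !codel_1p19q",
                              idh1_mut_codel = "idh1_mut & codel_1p19q",
                              mesenchymal_idh1_wt = "!idh1_mut & subtype_mesenchymal"),
                            genes = c("idh1_mut", "atrx_mut", "braf_mut",
                                      "tp53_mut"),
                            reference = "NBE", seed = 1L) {
  stopifnot(min_signal >= 0, min_ratio >= 0, k >= 2L,
            alpha > 0, alpha < 1, success_threshold >= 0)
  structure(list(readouts = readouts, annotations = annotations,
                 out_dir = out_dir, min_signal = min_signal,
                 min_ratio = min_ratio, success_threshold = success_threshold,
                 k = k, alpha = alpha, subgroups = subgroups, genes = genes,
                 reference = reference, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path a YAML file whose keys match the [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_gfscan(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$subgroups)) raw$subgroups <- unlist(raw$subgroups)
  do.call(pipeline_config, raw)
}

#' Run the screen-side pipeline end to end
#'
#' Executes QC, growth-index construction, Ward clustering with dependency
#' labelling, condition ranking for the full cohort and each configured
#' subgroup, and the mutation-condition association screen, writing every
#' intermediate TSV plus a run log (package version, seed, parameters) into
#' `config$out_dir`. Any stage error aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config a `pipeline_config`.
#' @param readouts optional readout data.frame (overrides `config$readouts`).
#' @param annotations optional annotation data.frame.
#' @param catalog optional `condition_catalog` (default: full panel).
#' @return invisibly, a list with the in-memory stage results (`index`,
#'   `clusters`, `rankings`, `associations`) and the output paths.
#' @export
run_pipeline <- function(config, readouts = NULL, annotations = NULL,
                         catalog = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  # hash the analysis parameters only, not machine-specific paths
  stamp <- output_stamp(
    unclass(config)[setdiff(names(config),
                            c("out_dir", "readouts", "annotations"))])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(stamp, sprintf("seed=%d", config$seed))
  fail <- function(stage, err) {
    writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", stage,
                                    conditionMessage(err))), log_path)
    stop_gfscan(sprintf("pipeline stage '%s' failed: %s", stage,
                        conditionMessage(err)))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) fail(name, e))
  }

  catalog <- catalog %||% enumerate_conditions(gf_panel())
  readouts <- readouts %||% stage("read", read_readouts(config$readouts))
  annotations <- annotations %||%
    if (!is.null(config$annotations)) {
      stage("read", read_annotations(config$annotations))
    } else {
      NULL
    }

  m <- stage("index", {
    gim <- build_index_matrix(readouts, catalog,
                              min_signal = config$min_signal,
                              min_ratio = config$min_ratio)
    if (all(!gim$qc_pass)) {
      stop_gfscan("all wells failed QC; check min_signal / min_ratio")
    }
    gim
  })
  write_index_matrix(m, file.path(config$out_dir, "growth_index.tsv"),
                     comment = stamp)
  log_lines <- c(log_lines, sprintf("index: %d samples x %d conditions",
                                    length(m$samples), length(m$conditions)))

  clusters <- stage("cluster", {
    cl <- hierarchical_cluster(m, k = config$k)
    label_clusters(cl, m, catalog, alpha = config$alpha)
  })
  write_tsv_stamped(clusters$assignment,
                    file.path(config$out_dir, "clusters.tsv"), stamp)
  write_tsv_stamped(clusters$merge_tree,
                    file.path(config$out_dir, "merge_tree.tsv"), stamp)

  ann_ext <- annotations
  if (!is.null(ann_ext)) {
    ann_ext$ef_label <- clusters$assignment$ef_label[
      match(ann_ext$sample_id, clusters$assignment$sample_id)]
    ann_ext$ef_independent_recovered <- !is.na(ann_ext$ef_label) &
      ann_ext$ef_label == "independent"
  }

  rankings <- stage("rank", {
    groups <- c(list(all = NULL), as.list(config$subgroups))
    out <- list()
    for (gname in names(groups)) {
      sub <- groups[[gname]]
      if (!is.null(sub) && is.null(ann_ext)) next
      ranked <- tryCatch(
        rank_conditions(m, subgroup = sub, annotations = ann_ext,
                        reference = config$reference,
                        threshold = config$success_threshold),
        error = function(e) NULL)
      if (!is.null(ranked)) {
        ranked <- cbind(subgroup = gname, ranked, stringsAsFactors = FALSE)
        out[[gname]] <- ranked
      }
    }
    do.call(rbind, out)
  })
  if (!is.null(rankings)) {
    write_tsv_stamped(rankings, file.path(config$out_dir, "rankings.tsv"), stamp)
  }

  associations <- NULL
  if (!is.null(ann_ext) && length(config$genes) > 0) {
    associations <- stage("associate", {
      genes <- intersect(config$genes, names(ann_ext))
      if (length(genes) == 0L) NULL else
        mutation_condition_screen(m, ann_ext, genes)
    })
    if (!is.null(associations)) {
      write_tsv_stamped(associations,
                        file.path(config$out_dir, "associations.tsv"), stamp)
    }
  }

  writeLines(c(log_lines, "status=ok"), log_path)
  invisible(list(index = m, clusters = clusters, rankings = rankings,
                 associations = associations, out_dir = config$out_dir))
}
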