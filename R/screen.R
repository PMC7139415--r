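# Screen core: QC filtering of raw readouts, replicate aggregation, and the
# cell growth index statistics.
#
# The cell growth index of a sample under a condition is (D6 - N6)/D0: day-6
# luminescence under the condition minus day-6 luminescence in basal media
# without growth factors, relative to the seeding-day signal. It can be
# negative when a condition does worse than bare basal media.

#' Cell growth index (D6 - N6) / D0
#'
#' @param d0 seeding-day luminescence (> 0).
#' @param d6 day-6 luminescence under the condition (>= 0).
#' @param n6 day-6 luminescence in basal media without growth factors (>= 0).
#' @return the index, possibly negative. Vectorised.
#' @examples
#' cell_growth_index(1000, 5000, 1000)  # 4
#' @export
cell_growth_index <- function(d0, d6, n6) {
  if (any(!is.finite(d0)) || any(d0 <= 0)) {
    stop_gfscan("d0 must be positive (no usable seeding signal)")
  }
  if (any(d6 < 0) || any(n6 < 0)) {
    stop_gfscan("luminescence readouts must be non-negative")
  }
  (d6 - n6) / d0
}

validate_readouts <- function(readouts) {
  req <- c("sample_id", "condition_id", "replicate", "role", "lum")
  missing <- setdiff(req, names(readouts))
  if (length(missing) > 0) {
    stop_gfscan(sprintf("readout table lacks column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  bad_role <- !readouts$role %in% c("D0", "D6", "N6")
  if (any(bad_role)) {
    stop_gfscan(sprintf("unknown readout role '%s' (row %d)",
                        readouts$role[which(bad_role)[1]], which(bad_role)[1]))
  }
  if (any(readouts$lum < 0)) {
    stop_gfscan(sprintf("negative luminescence (row %d)",
                        which(readouts$lum < 0)[1]))
  }
  key <- paste(readouts$sample_id, readouts$condition_id, readouts$replicate,
               readouts$role, sep = "\r")
  if (anyDuplicated(key)) {
    stop_gfscan(sprintf("duplicate (sample, condition, replicate, role) at row %d",
                        which(duplicated(key))[1]))
  }
  invisible(readouts)
}

#' Quality-control mask for screen wells
#'
#' A (sample, condition, replicate) well passes iff its day-6 signal exceeds
#' `min_signal` (strictly: readings at or below it are treated as too few
#' viable cells to score) and its day-6/day-0 ratio strictly exceeds
#' `min_ratio`. Wells with a D6 reading but no matching D0 are failed with a
#' warning rather than an error.
#'
#' @param readouts long readout table (`sample_id`, `condition_id`,
#'   `replicate`, `role`, `lum`).
#' @param min_signal minimum day-6 luminescence (default 5000).
#' @param min_ratio minimum day-6/day-0 ratio (default 0.5).
#' @return data.frame per measured well: `sample_id`, `condition_id`,
#'   `replicate`, `d0`, `d6`, `ratio`, `qc_pass`, `reason` (NA when passed).
#' @export
qc_filter <- function(readouts, min_signal = 5000, min_ratio = 0.5) {
  stopifnot(min_signal >= 0, min_ratio >= 0)
  validate_readouts(readouts)
  d6 <- readouts[readouts$role == "D6", ]
  d0 <- readouts[readouts$role == "D0", ]
  key <- function(x) paste(x$sample_id, x$condition_id, x$replicate, sep = "\r")
  d6$d0 <- d0$lum[match(key(d6), key(d0))]
  missing_d0 <- is.na(d6$d0)
  if (any(missing_d0)) {
    warning(sprintf("%d well(s) have a D6 reading but no D0; marked as QC failures",
                    sum(missing_d0)), call. = FALSE)
  }
  ratio <- d6$lum / d6$d0
  pass <- !missing_d0 & d6$lum > min_signal & ratio > min_ratio
  reason <- rep(NA_character_, nrow(d6))
  reason[!pass & missing_d0] <- "missing_d0"
  reason[!pass & !missing_d0 & d6$lum <= min_signal] <- "low_signal"
  low_ratio <- !pass & !missing_d0 & d6$lum > min_signal & ratio <= min_ratio
  reason[low_ratio] <- "low_ratio"
  data.frame(
    sample_id = d6$sample_id, condition_id = d6$condition_id,
    replicate = d6$replicate, d0 = d6$d0, d6 = d6$lum, ratio = ratio,
    qc_pass = pass, reason = reason, stringsAsFactors = FALSE
  )
}

#' Build the growth index matrix from a readout table
#'
#' Technical replicate luminescence values are averaged per role before the
#' index formula is applied (the per-sample N6 reference is the mean of the
#' sample's basal-media day-6 readings). Only QC-passing replicates enter the
#' averages; a cell whose replicates all fail QC is masked. Samples without
#' any N6 measurement are masked entirely, with a warning.
#'
#' @param readouts long readout table.
#' @param catalog a `condition_catalog`; its non-`NO_GF` conditions define the
#'   matrix columns.
#' @param min_signal,min_ratio QC thresholds, see [qc_filter()].
#' @return an object of class `growth_index_matrix`: list with matrices
#'   `index` (cell growth index), `rate` (day-6/day-0 ratio), `qc_pass`
#'   (mask), `n_replicates` (replicates used per cell), the per-sample `n6`
#'   reference, and the `qc` well report.
#' @export
build_index_matrix <- function(readouts, catalog,
                               min_signal = 5000, min_ratio = 0.5) {
  stopifnot(inherits(catalog, "condition_catalog"))
  validate_readouts(readouts)
  qc <- qc_filter(readouts, min_signal = min_signal, min_ratio = min_ratio)

  cond <- catalog$conditions
  cond_ids <- cond$condition_id[cond$kind != "control_no_gf"]
  samples <- unique(readouts$sample_id)

  n6_rows <- readouts[readouts$role == "N6", ]
  n6 <- tapply(n6_rows$lum, factor(n6_rows$sample_id, levels = samples), mean)
  n6 <- as.numeric(n6)
  names(n6) <- samples
  if (anyNA(n6)) {
    warning(sprintf("%d sample(s) lack an N6 measurement; all their cells are masked",
                    sum(is.na(n6))), call. = FALSE)
  }

  shape <- list(samples, cond_ids)
  idx <- matrix(NA_real_, length(samples), length(cond_ids), dimnames = shape)
  rate <- matrix(NA_real_, length(samples), length(cond_ids), dimnames = shape)
  nrep <- matrix(0L, length(samples), length(cond_ids), dimnames = shape)

  ok <- qc[qc$qc_pass & qc$condition_id %in% cond_ids, ]
  if (nrow(ok) > 0) {
    cell <- interaction(factor(ok$sample_id, levels = samples),
                        factor(ok$condition_id, levels = cond_ids), drop = FALSE)
    mean_d0 <- tapply(ok$d0, cell, mean)
    mean_d6 <- tapply(ok$d6, cell, mean)
    counts <- tapply(ok$d0, cell, length)
    grid_i <- rep(seq_along(samples), times = length(cond_ids))
    grid_j <- rep(seq_along(cond_ids), each = length(samples))
    filled <- !is.na(mean_d0)
    i <- grid_i[filled]; j <- grid_j[filled]
    rate[cbind(i, j)] <- mean_d6[filled] / mean_d0[filled]
    idx[cbind(i, j)] <- (mean_d6[filled] - n6[samples[i]]) / mean_d0[filled]
    nrep[cbind(i, j)] <- counts[filled]
  }
  masked <- is.na(idx)
  idx[masked] <- NA_real_
  structure(list(
    index = idx, rate = rate, qc_pass = !masked, n_replicates = nrep,
    n6 = n6, qc = qc, samples = samples, conditions = cond_ids
  ), class = "growth_index_matrix")
}

#' @export
print.growth_index_matrix <- function(x, ...) {
  cat(sprintf("growth_index_matrix: %d samples x %d conditions (%.1f%% cells pass QC)\n",
              length(x$samples), length(x$conditions),
              100 * mean(x$qc_pass)))
  invisible(x)
}

#' Squared Pearson correlation between two index profiles
#'
#' Replicate-run concordance of the screen: the squared Pearson correlation
#' of two growth-index profiles of the same sample over their shared
#' unmasked conditions.
#'
#' @param run_a,run_b numeric vectors of growth indices over the same
#'   conditions (NA = masked).
#' @return R-squared in [0, 1].
#' @export
replicate_concordance <- function(run_a, run_b) {
  stopifnot(length(run_a) == length(run_b))
  shared <- !is.na(run_a) & !is.na(run_b)
  if (sum(shared) < 3L) {
    stop_gfscan("fewer than 3 shared unmasked conditions")
  }
  cor(run_a[shared], run_b[shared])^2
}

#' Two-group growth comparison (Welch t-test)
#'
#' Compares e.g. day-6/day-0 growth rates under one condition between two
#' diagnostic groups, with a two-tailed Welch t-test.
#'
#' @param values numeric vector (e.g. rates under the NBE condition).
#' @param groups a factor-like vector with exactly two levels.
#' @return list with `means` (named group means), `t`, `df` and `p`.
#' @export
group_growth_comparison <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) != 2L) stop_gfscan("exactly two groups required")
  sizes <- table(groups)
  if (any(sizes < 2L)) stop_gfscan("both groups must have >= 2 values")
  means <- setNames(as.numeric(tapply(values, groups, mean)), levels(groups))
  if (all(as.numeric(tapply(values, groups, sd)) == 0) &&
      means[1] == means[2]) {
    return(list(means = means, t = 0, df = sum(sizes) - 2, p = 1))
  }
  tt <- t.test(values ~ groups, var.equal = FALSE)
  list(means = means, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Printed cohort-composition proportions
#'
#' Summarises the screen cohort's headline proportions from an annotation
#' table: the fraction of LGGs in the EGF/bFGF-independent group, of
#' IDH1-mutant glioblastomas, of co-deleted LGGs, and of proneural samples
#' among EGF/bFGF-dependent IDH1-wild-type GSCs.
#'
#' @param annotations an annotation data.frame with the columns produced by
#'   [generate_cohort()] (or measured equivalents).
#' @param ef_column name of the column holding the dependency group
#'   (default the planted `true_ef_group`; pass a recovered assignment
#'   column to summarise pipeline output).
#' @param subtype_column name of the subtype column.
#' @return data.frame with `metric`, `numerator`, `denominator`, `pct`.
#' @export
cohort_proportions <- function(annotations, ef_column = "true_ef_group",
                               subtype_column = "true_subtype") {
  ef <- annotations[[ef_column]]
  st <- annotations[[subtype_column]]
  lgg <- annotations$diagnosis == "LGG"
  gbm <- annotations$diagnosis == "GBM"
  dep_wt <- !annotations$idh1_mut & !is.na(ef) & ef == "dependent"
  prop_row <- function(metric, num, den) {
    data.frame(metric = metric, numerator = num, denominator = den,
               pct = round(100 * num / den, 1), stringsAsFactors = FALSE)
  }
  rbind(
    prop_row("lgg_ef_independent",
             sum(lgg & !is.na(ef) & ef == "independent"), sum(lgg)),
    prop_row("proneural_among_dependent_idh1wt",
             sum(dep_wt & !is.na(st) & st == "proneural"), sum(dep_wt)),
    prop_row("gbm_idh1_mut", sum(gbm & annotations$idh1_mut), sum(gbm)),
    prop_row("lgg_codel", sum(lgg & annotations$codel_1p19q), sum(lgg))
  )
}
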