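# Condition ranking within genotype subgroups and the mutation-condition
# association screen.
#
# The growth success rate of a condition is the fraction of evaluable samples
# whose day-6/day-0 ratio strictly exceeds 1. Conditions are ranked by
# success rate, then mean growth index, then canonical label; fold change
# versus the reference (NBE) condition is the ratio of subgroup mean indices
# over samples evaluable in both.

#' Growth success rate of one condition
#'
#' @param rates per-sample day-6/day-0 ratios under one condition
#'   (NA = masked; masked samples are excluded from numerator and
#'   denominator).
#' @param threshold success cut-off (strict `>`, default 1).
#' @return list with `rate` (successes / evaluable) and `n` (evaluable).
#' @examples
#' growth_success_rate(c(1.2, 0.9, 1.0))  # rate 1/3: exactly 1 is a failure
#' @export
growth_success_rate <- function(rates, threshold = 1) {
  rates <- rates[!is.na(rates)]
  if (length(rates) == 0L) stop_gfscan("no evaluable samples")
  list(rate = mean(rates > threshold), n = length(rates))
}

#' Rank conditions within a sample subgroup
#'
#' Orders every condition by growth success rate (descending), breaking ties
#' by mean growth index and then canonical label, and reports each
#' condition's fold change versus the reference condition (mean index over
#' samples evaluable in both, divided by the reference mean over the same
#' samples).
#'
#' @param m a `growth_index_matrix`.
#' @param subgroup NULL (all samples), a filter string over annotation
#'   columns (needs `annotations`), a logical vector, or sample ids.
#' @param annotations annotation table (required for filter-string
#'   subgroups).
#' @param reference reference condition id (default `"NBE"`).
#' @param threshold success cut-off on the day-6/day-0 ratio.
#' @return data.frame (`condition_id`, `success_rate`, `n_evaluable`,
#'   `mean_index`, `fold_vs_nbe`, `beats_reference`, `rank`), ordered by
#'   rank. Conditions with no evaluable sample are dropped.
#' @export
rank_conditions <- function(m, subgroup = NULL, annotations = NULL,
                            reference = "NBE", threshold = 1) {
  stopifnot(inherits(m, "growth_index_matrix"))
  samples <- resolve_subgroup(subgroup, annotations, m$samples)
  if (length(samples) == 0L) stop_gfscan("empty subgroup")
  missing <- setdiff(samples, m$samples)
  if (length(missing) > 0) {
    stop_gfscan(sprintf("subgroup sample(s) not in matrix: %s",
                        paste(head(missing, 3), collapse = ", ")))
  }
  if (!reference %in% m$conditions) {
    stop_gfscan(sprintf("reference condition '%s' not present", reference))
  }
  rate <- m$rate[samples, , drop = FALSE]
  idx <- m$index[samples, , drop = FALSE]
  ref_idx <- idx[, reference]

  rows <- lapply(m$conditions, function(cid) {
    r <- rate[, cid]
    ev <- !is.na(r)
    if (!any(ev)) return(NULL)
    sr <- growth_success_rate(r)
    both <- ev & !is.na(ref_idx)
    fold <- if (any(both)) {
      ref_mean <- mean(ref_idx[both])
      if (ref_mean == 0) NA_real_ else mean(idx[both, cid]) / ref_mean
    } else {
      NA_real_
    }
    ref_sr <- if (any(!is.na(rate[, reference]))) {
      growth_success_rate(rate[, reference])$rate
    } else {
      NA_real_
    }
    data.frame(condition_id = cid, success_rate = sr$rate, n_evaluable = sr$n,
               mean_index = mean(idx[ev, cid]), fold_vs_nbe = fold,
               beats_reference = !is.na(ref_sr) & sr$rate > ref_sr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_gfscan("no condition has an evaluable sample")
  ord <- order(-out$success_rate, -out$mean_index,
               tolower(out$condition_id), method = "radix")
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Two-sided Wilcoxon rank-sum p-value: exact distribution when both groups
# have <= 10 observations and no ties, normal approximation with tie
# correction (and continuity correction) otherwise.
wilcoxon_p <- function(x, y) {
  use_exact <- length(x) <= 10L && length(y) <= 10L &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)$p.value
  )
}

#' Mutation-condition association screen
#'
#' For every (gene, condition) pair, compares growth indices of mutant versus
#' wild-type samples with a two-sided Wilcoxon rank-sum test (exact when both
#' groups have at most 10 samples and no ties, normal approximation with tie
#' correction otherwise), and reports the mean-index difference alongside a
#' Benjamini-Hochberg q-value computed across all emitted pairs. Pairs where
#' either group has fewer than 2 evaluable samples are skipped.
#'
#' @param m a `growth_index_matrix`.
#' @param annotations annotation table with `sample_id` and logical mutation
#'   columns.
#' @param genes character vector of mutation column names (e.g.
#'   `"atrx_mut"`).
#' @param restrict optional subgroup (filter string, logical vector or sample
#'   ids) within which the screen runs.
#' @return data.frame (`gene`, `condition_id`, `delta`, `p`, `q`,
#'   `mutation_frequency`, `n_mut`, `n_wt`), suitable for volcano plotting
#'   (`delta` vs `-log10(p)`).
#' @export
mutation_condition_screen <- function(m, annotations, genes, restrict = NULL) {
  stopifnot(inherits(m, "growth_index_matrix"))
  samples <- resolve_subgroup(restrict, annotations, m$samples)
  samples <- intersect(samples, m$samples)
  if (length(samples) == 0L) stop_gfscan("empty restrict set")
  absent <- setdiff(genes, names(annotations))
  if (length(absent) > 0) {
    stop_gfscan(sprintf("gene flag(s) absent from annotations: %s",
                        paste(absent, collapse = ", ")))
  }
  ann <- annotations[match(samples, annotations$sample_id), ]
  idx <- m$index[samples, , drop = FALSE]

  rows <- list()
  for (gene in genes) {
    mut <- ann[[gene]]
    if (!is.logical(mut)) stop_gfscan(sprintf("'%s' is not a logical column", gene))
    mut_freq <- mean(mut, na.rm = TRUE)
    for (cid in m$conditions) {
      v <- idx[, cid]
      gm <- v[mut %in% TRUE & !is.na(v)]
      gw <- v[mut %in% FALSE & !is.na(v)]
      if (length(gm) < 2L || length(gw) < 2L) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, condition_id = cid,
        delta = mean(gm) - mean(gw),
        p = wilcoxon_p(gm, gw),
        mutation_frequency = mut_freq,
        n_mut = length(gm), n_wt = length(gw),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    stop_gfscan("no (gene, condition) pair with >= 2 evaluable samples per group")
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[, c("gene", "condition_id", "delta", "p", "q", "mutation_frequency",
          "n_mut", "n_wt")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate q-values (monotone step-up).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values of the same length (empty input gives empty output).
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop_gfscan("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}
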