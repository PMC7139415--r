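# Expression-side procedures: tumor-intrinsic gene filtering against paired
# tissue profiles, two-group differential expression at fixed p/q thresholds,
# nearest template prediction (NTP), single-sample GSEA scores with subtype
# assignment, and a two-class GSEA engine with a gene-set permutation null.
#
# Expression matrices are plain numeric matrices of log2(RPKM + 1) values,
# genes in rows (unique rownames), samples in columns.

validate_expression <- function(e) {
  stopifnot(is.matrix(e), is.numeric(e))
  if (is.null(rownames(e)) || anyDuplicated(rownames(e))) {
    stop_gfscan("expression matrix needs unique gene rownames")
  }
  if (is.null(colnames(e)) || anyDuplicated(colnames(e))) {
    stop_gfscan("expression matrix needs unique sample colnames")
  }
  if (any(e < 0, na.rm = TRUE)) {
    stop_gfscan("log2(RPKM + 1) values must be >= 0")
  }
  invisible(e)
}

#' Tumor-intrinsic gene filter
#'
#' Keeps genes whose expression correlates between GSCs and their parental
#' tissues across paired samples (Spearman rho >= `rho_min`, inclusive), that
#' are annotated, and that are expressed (value > 0) in at least
#' `1 - zero_frac` of tissues AND of GSCs. Genes failing any rule are
#' dropped; the microenvironment-specific signal missing from cultured GSCs
#' is what the correlation rule removes.
#'
#' @param gsc,tissue expression matrices (genes x samples).
#' @param pairs named character vector mapping GSC sample ids to tissue
#'   sample ids; defaults to identical column names.
#' @param rho_min minimum Spearman correlation (default 0.4).
#' @param zero_frac a gene unexpressed in more than this fraction of either
#'   compartment is dropped (default 0.5).
#' @param annotated optional logical vector (named by gene or in row order);
#'   unannotated genes are dropped.
#' @return list with `keep` (character vector of surviving genes) and
#'   `report` (per-gene data.frame: `gene`, `rho`, `zero_frac_gsc`,
#'   `zero_frac_tissue`, `annotated`, `kept`, `reason`).
#' @export
tumor_intrinsic_filter <- function(gsc, tissue, pairs = NULL, rho_min = 0.4,
                                   zero_frac = 0.5, annotated = NULL) {
  validate_expression(gsc)
  validate_expression(tissue)
  if (is.null(pairs)) {
    shared <- intersect(colnames(gsc), colnames(tissue))
    pairs <- setNames(shared, shared)
  }
  if (length(pairs) < 5L) {
    stop_gfscan("at least 5 paired samples are required")
  }
  if (anyDuplicated(names(pairs)) || anyDuplicated(pairs)) {
    stop_gfscan("sample pairing must be one-to-one")
  }
  genes <- intersect(rownames(gsc), rownames(tissue))
  g <- gsc[genes, names(pairs), drop = FALSE]
  t_ <- tissue[genes, unname(pairs), drop = FALSE]

  if (is.null(annotated)) {
    ann <- rep(TRUE, length(genes))
  } else if (!is.null(names(annotated))) {
    ann <- annotated[genes]
    ann[is.na(ann)] <- FALSE
  } else {
    stopifnot(length(annotated) == length(genes))
    ann <- annotated
  }

  # Spearman = Pearson on average ranks within each gene's paired vectors
  rho <- vapply(seq_along(genes), function(i) {
    suppressWarnings(cor(g[i, ], t_[i, ], method = "spearman"))
  }, numeric(1))
  zf_g <- rowMeans(g == 0)
  zf_t <- rowMeans(t_ == 0)

  kept <- !is.na(rho) & rho >= rho_min & ann &
    zf_g <= zero_frac & zf_t <= zero_frac
  reason <- rep(NA_character_, length(genes))
  reason[!ann] <- "unannotated"
  zero_fail <- ann & (zf_g > zero_frac | zf_t > zero_frac)
  reason[zero_fail] <- "unexpressed"
  low_cor <- ann & !zero_fail & (is.na(rho) | rho < rho_min)
  reason[low_cor] <- "low_correlation"
  list(
    keep = genes[kept],
    report = data.frame(gene = genes, rho = rho, zero_frac_gsc = zf_g,
                        zero_frac_tissue = zf_t, annotated = ann, kept = kept,
                        reason = reason, stringsAsFactors = FALSE)
  )
}

#' Two-group differential expression at fixed thresholds
#'
#' Per-gene two-sided Welch t-test between two sample groups with
#' Benjamini-Hochberg adjustment; a gene is called differentially expressed
#' iff p <= `p_max` and q <= `q_max`. Genes constant in both groups get
#' p = 1 rather than an error.
#'
#' @param e expression matrix (genes x samples).
#' @param labels two-level grouping over the columns of `e`.
#' @param p_max,q_max inclusion thresholds (defaults 0.05 and 0.1).
#' @return data.frame (`gene`, `mean_1`, `mean_2`, `diff`, `p`, `q`, `deg`,
#'   `direction`); `diff = mean_1 - mean_2` and `direction` is `up` when the
#'   first group is higher.
#' @export
differential_expression <- function(e, labels, p_max = 0.05, q_max = 0.1) {
  validate_expression(e)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop_gfscan("labels must have exactly two levels")
  if (any(table(labels) < 3L)) stop_gfscan("both groups need >= 3 samples")
  g1 <- e[, labels == levels(labels)[1], drop = FALSE]
  g2 <- e[, labels == levels(labels)[2], drop = FALSE]
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, stats::var); v2 <- apply(g2, 1, stats::var)
  n1 <- ncol(g1); n2 <- ncol(g2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  constant <- v1 == 0 & v2 == 0
  p[constant & m1 == m2] <- 1
  # zero within-group spread with distinct means: perfectly separated
  p[constant & m1 != m2] <- .Machine$double.xmin
  p[is.na(p)] <- 1
  q <- bh_adjust(p)
  data.frame(
    gene = rownames(e), mean_1 = m1, mean_2 = m2, diff = m1 - m2,
    p = p, q = q, deg = p <= p_max & q <= q_max,
    direction = ifelse(m1 >= m2, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  1 - sum(a * b) / (na * nb)
}

# z-standardise each gene (row) across samples; zero-variance rows become 0.
standardize_rows <- function(e) {
  mu <- rowMeans(e)
  s <- apply(e, 1, sd)
  z <- (e - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Nearest template prediction
#'
#' Classifies each sample by cosine distance between its gene-wise
#' standardised expression over the pooled marker genes and each class
#' template (+1 at the class's markers, -1 elsewhere). Significance of the
#' winning distance is estimated against `n_perm` random marker sets of the
#' same per-class sizes drawn from all genes; q-values are BH-adjusted across
#' samples.
#'
#' @param e expression matrix (genes x samples).
#' @param templates named list: class name -> character vector of marker
#'   genes, disjoint across classes, each with >= 10 members present in `e`.
#' @param n_perm number of random-template permutations (default 1000).
#' @param seed integer seed for the permutation null.
#' @return data.frame (`sample_id`, `class`, `distance`, `p`, `q`, `tie`,
#'   `low_confidence`) plus a `"distances"` attribute (samples x classes).
#' @export
ntp_classify <- function(e, templates, n_perm = 1000L, seed) {
  validate_expression(e)
  stopifnot(is.list(templates), length(templates) >= 2L,
            !is.null(names(templates)))
  classes <- names(templates)
  all_markers <- unlist(templates, use.names = FALSE)
  if (anyDuplicated(all_markers)) {
    stop_gfscan("template marker lists must be disjoint")
  }
  present <- lapply(templates, function(g) intersect(g, rownames(e)))
  n_present <- vapply(present, length, integer(1))
  if (any(n_present < 10L)) {
    stop_gfscan("each class needs >= 10 template genes present in the matrix")
  }
  low_confidence <- vapply(seq_len(ncol(e)), function(j) FALSE, logical(1))
  frac_missing <- 1 - sum(n_present) / length(all_markers)
  if (frac_missing > 0.5) low_confidence[] <- TRUE

  z <- standardize_rows(e)
  marker_union <- unlist(present, use.names = FALSE)
  template_mat <- vapply(classes, function(cl) {
    ifelse(marker_union %in% present[[cl]], 1, -1)
  }, numeric(length(marker_union)))

  dist_to_templates <- function(rows) {
    zi <- z[rows, , drop = FALSE]
    out <- matrix(NA_real_, ncol(e), length(classes),
                  dimnames = list(colnames(e), classes))
    for (j in seq_len(ncol(e))) {
      for (k in seq_along(classes)) {
        out[j, k] <- cosine_distance(zi[, j], template_mat[, k])
      }
    }
    out
  }

  obs <- dist_to_templates(marker_union)
  best <- apply(obs, 1, which.min)
  best_dist <- obs[cbind(seq_len(nrow(obs)), best)]
  tie <- apply(obs, 1, function(d) sum(d == min(d)) > 1L)

  null_best <- with_seed(seed, {
    sizes <- n_present
    replicate(n_perm, {
      fake <- sample(rownames(e), sum(sizes))
      split_idx <- rep(seq_along(sizes), sizes)
      fake_present <- split(fake, split_idx)
      zi <- z[fake, , drop = FALSE]
      vapply(seq_len(ncol(e)), function(j) {
        min(vapply(seq_along(classes), function(k) {
          cosine_distance(zi[, j], template_mat[, k])
        }, numeric(1)))
      }, numeric(1))
    })
  })
  # null_best: samples x n_perm matrix of best null distances
  p <- vapply(seq_len(ncol(e)), function(j) {
    (1 + sum(null_best[j, ] <= best_dist[j])) / (n_perm + 1)
  }, numeric(1))

  data.frame(
    sample_id = colnames(e), class = classes[best], distance = best_dist,
    p = p, q = bh_adjust(p), tie = tie, low_confidence = low_confidence,
    stringsAsFactors = FALSE
  ) -> out
  attr(out, "distances") <- obs
  out
}

#' Single-sample GSEA scores
#'
#' Rank-based per-sample enrichment score of each gene set: genes are ranked
#' by expression within the sample, and the score is the sum over the ranked
#' list of the difference between the weighted in-set empirical CDF (weights
#' `rank^alpha`) and the uniform out-of-set CDF. Because only within-sample
#' ranks enter, scores are invariant to any strictly increasing per-sample
#' transform of expression.
#'
#' @param e expression matrix (genes x samples).
#' @param sets named list of gene sets (character vectors); each needs >= 2
#'   members present in `e`.
#' @param alpha rank weighting exponent (default 0.25).
#' @return matrix of scores, sets x samples.
#' @export
ssgsea_scores <- function(e, sets, alpha = 0.25) {
  validate_expression(e)
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  n <- nrow(e)
  present <- lapply(sets, function(g) intersect(g, rownames(e)))
  bad <- vapply(present, length, integer(1)) < 2L
  if (any(bad)) {
    stop_gfscan(sprintf("gene set(s) with < 2 present members: %s",
                        paste(names(sets)[bad], collapse = ", ")))
  }
  scores <- matrix(NA_real_, length(sets), ncol(e),
                   dimnames = list(names(sets), colnames(e)))
  for (j in seq_len(ncol(e))) {
    r <- rank(e[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)         # highest expression first
    w <- r[ord]^alpha
    for (k in seq_along(sets)) {
      in_set <- rownames(e)[ord] %in% present[[k]]
      w_in <- w * in_set
      p_in <- cumsum(w_in) / sum(w_in)
      p_out <- cumsum(!in_set) / (n - sum(in_set))
      scores[k, j] <- sum(p_in - p_out)
    }
  }
  scores
}

#' Assign each sample the subtype with the highest normalised ssGSEA score
#'
#' Each subtype's score row is z-normalised across samples (zero-variance
#' rows become all zeros, with a message), and each sample is assigned the
#' arg-max subtype; ties are broken by row order and flagged.
#'
#' @param scores sets x samples score matrix from [ssgsea_scores()].
#' @return data.frame (`sample_id`, `subtype`, `score`, `tie`).
#' @export
assign_subtype <- function(scores) {
  stopifnot(is.matrix(scores), nrow(scores) >= 2L)
  if (ncol(scores) < 2L) {
    stop_gfscan("cross-sample normalisation needs >= 2 samples")
  }
  s <- apply(scores, 1, sd)
  if (any(s == 0)) {
    message(sprintf("%d zero-variance score row(s) normalised to zeros", sum(s == 0)))
  }
  z <- (scores - rowMeans(scores)) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  best <- apply(z, 2, which.max)
  tie <- apply(z, 2, function(v) sum(v == max(v)) > 1L)
  data.frame(
    sample_id = colnames(scores), subtype = rownames(scores)[best],
    score = z[cbind(best, seq_len(ncol(z)))], tie = tie,
    stringsAsFactors = FALSE
  )
}

# Signal-to-noise ranking metric between two groups, per gene.
signal_to_noise <- function(e, labels) {
  labels <- factor(labels)
  g1 <- e[, labels == levels(labels)[1], drop = FALSE]
  g2 <- e[, labels == levels(labels)[2], drop = FALSE]
  (rowMeans(g1) - rowMeans(g2)) /
    (apply(g1, 1, sd) + apply(g2, 1, sd) + 1e-12)
}

# Weighted Kolmogorov-Smirnov-style running enrichment score.
gsea_es <- function(metric_sorted_names, metric_sorted_abs, set_genes) {
  in_set <- metric_sorted_names %in% set_genes
  w <- metric_sorted_abs * in_set
  denom_in <- sum(w)
  if (denom_in == 0) return(list(es = 0, running = numeric(0)))
  p_in <- cumsum(w) / denom_in
  p_out <- cumsum(!in_set) / sum(!in_set)
  running <- p_in - p_out
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Two-class GSEA with a gene-set permutation null
#'
#' Ranks genes by the signal-to-noise metric between two sample groups and
#' computes the classic weighted running-sum enrichment score (weighting
#' exponent 1 on |metric|). The null distribution is built from `n_perm`
#' random gene sets of the same size; the normalised enrichment score (NES)
#' divides ES by the mean |null ES| of matching sign, and p / FDR are the
#' fraction of same-sign null scores at least as extreme.
#'
#' @param e expression matrix (genes x samples).
#' @param labels two-level grouping over the columns (first level minus
#'   second defines the metric sign).
#' @param set character vector of gene ids (>= 5 present in `e`).
#' @param n_perm number of random gene sets (default 1000).
#' @param seed integer seed.
#' @return list (`es`, `nes`, `p`, `fdr`, `running`, `order`) where
#'   `running` is the running enrichment over the ranked gene list.
#' @export
gsea_two_class <- function(e, labels, set, n_perm = 1000L, seed) {
  validate_expression(e)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop_gfscan("labels must have exactly two levels")
  if (any(table(labels) < 3L)) stop_gfscan("both groups need >= 3 samples")
  set <- intersect(set, rownames(e))
  if (length(set) < 5L) stop_gfscan("gene set needs >= 5 present members")
  metric <- signal_to_noise(e, labels)
  if (length(unique(metric)) == 1L) {
    stop_gfscan("degenerate ranking metric (all genes tied)")
  }
  ord <- order(metric, decreasing = TRUE)
  nm <- rownames(e)[ord]
  av <- abs(metric[ord])
  obs <- gsea_es(nm, av, set)

  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      gsea_es(nm, av, sample(rownames(e), length(set)))$es
    }, numeric(1))
  })
  same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same_sign) == 0L) {
    nes <- NA_real_
    p <- 1 / (n_perm + 1)
  } else {
    nes <- obs$es / mean(abs(same_sign))
    p <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (length(same_sign) + 1)
  }
  list(es = obs$es, nes = nes, p = p, fdr = p, running = obs$running,
       order = nm)
}
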