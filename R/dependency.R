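# EGF/bFGF-dependency stratification: unsupervised clustering of growth-index
# profiles, per-sample dependency deltas over the E&F condition pairing, and
# significance-based dependent/independent labelling of the clusters.

impute_row_means <- function(m) {
  means <- rowMeans(m, na.rm = TRUE)
  if (anyNA(means)) {
    stop_gfscan("sample(s) with no unmasked conditions cannot be clustered")
  }
  fill <- which(is.na(m), arr.ind = TRUE)
  if (nrow(fill) > 0) m[fill] <- means[fill[, 1]]
  m
}

#' Hierarchical clustering of growth-index profiles
#'
#' Agglomerative clustering of samples on their raw cell-growth-index rows,
#' with Ward linkage on Euclidean distances, cut at `k` clusters. Masked
#' cells are imputed with the sample's row mean for the distance computation
#' only (Ward needs complete vectors); imputation is reported via a message.
#'
#' @param m a `growth_index_matrix` (or a plain numeric samples x conditions
#'   matrix).
#' @param k number of clusters (default 4, the screen's subgroup count).
#' @return an object of class `cluster_assignment`: list with `assignment`
#'   (data.frame `sample_id`, `cluster`), the `hclust` tree, and `merge_tree`
#'   (data.frame `parent`, `child1`, `child2`, `height` for dendrogram
#'   export). Labels are added by [label_clusters()].
#' @export
hierarchical_cluster <- function(m, k = 4L) {
  x <- if (inherits(m, "growth_index_matrix")) m$index else as.matrix(m)
  n <- nrow(x)
  if (k < 2L || k > n) stop_gfscan("k must be in [2, n_samples]")
  n_missing <- sum(is.na(x))
  if (n_missing > 0) {
    message(sprintf("imputing %d masked cell(s) with row means for clustering",
                    n_missing))
    x <- impute_row_means(x)
  }
  tree <- hclust(dist(x, method = "euclidean"), method = "ward.D2")
  cl <- cutree(tree, k = k)
  merge_tree <- data.frame(
    parent = seq_len(nrow(tree$merge)),
    child1 = tree$merge[, 1],
    child2 = tree$merge[, 2],
    height = tree$height
  )
  structure(list(
    assignment = data.frame(sample_id = rownames(x), cluster = unname(cl),
                            stringsAsFactors = FALSE),
    tree = tree, merge_tree = merge_tree, k = k
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples in %d clusters\n",
              nrow(x$assignment), x$k))
  print(table(cluster = x$assignment$cluster,
              label = x$assignment$ef_label %||% rep("(unlabelled)", nrow(x$assignment))))
  invisible(x)
}

# Mean with/without-E&F index per sample over usable twin couples.
ef_paired_means <- function(m, catalog) {
  x <- if (inherits(m, "growth_index_matrix")) m$index else as.matrix(m)
  pairing <- catalog$ef_pairing
  without <- intersect(names(pairing), colnames(x))
  with_ef <- pairing[without]
  usable <- with_ef %in% colnames(x)
  without <- without[usable]; with_ef <- with_ef[usable]
  if (length(without) == 0L) stop_gfscan("no E&F-paired condition couples present")
  g_without <- x[, without, drop = FALSE]
  g_with <- x[, with_ef, drop = FALSE]
  both <- !is.na(g_without) & !is.na(g_with)
  g_without[!both] <- NA
  g_with[!both] <- NA
  list(with_ef = rowMeans(g_with, na.rm = TRUE),
       without = rowMeans(g_without, na.rm = TRUE),
       n_couples = rowSums(both))
}

#' Per-sample EGF/bFGF dependency delta
#'
#' Mean, over all E&F condition couples (same growth-factor set with and
#' without the basal supplement), of the with-E&F index minus the
#' without-E&F index. Couples with either side masked are skipped.
#'
#' @param m a `growth_index_matrix` or plain matrix (samples x conditions).
#' @param catalog the `condition_catalog` providing the twin pairing.
#' @return named numeric vector of deltas. Errors if no sample has a usable
#'   couple; samples with none get NA with a warning.
#' @export
ef_dependency_delta <- function(m, catalog) {
  pm <- ef_paired_means(m, catalog)
  delta <- pm$with_ef - pm$without
  none <- pm$n_couples == 0L
  if (all(none)) stop_gfscan("no usable E&F couples for any sample")
  if (any(none)) {
    delta[none] <- NA_real_
    warning(sprintf("%d sample(s) have no usable E&F couple; delta set to NA",
                    sum(none)), call. = FALSE)
  }
  delta
}

#' Label clusters EGF/bFGF-dependent or -independent
#'
#' A cluster is labelled `dependent` iff a two-tailed paired t-test of its
#' members' mean with-E&F versus mean without-E&F growth indices gives
#' p < `alpha` and the mean delta is positive; otherwise `independent`.
#' Singleton clusters are labelled by the sign of their delta, with a
#' warning.
#'
#' @param assignment a `cluster_assignment` from [hierarchical_cluster()].
#' @param m the `growth_index_matrix` the clustering was computed on.
#' @param catalog the `condition_catalog`.
#' @param alpha significance level (default 0.05).
#' @return the `cluster_assignment` with `ef_label` and `dependency_delta`
#'   columns added to `$assignment` and a `$cluster_tests` table
#'   (`cluster`, `n`, `mean_delta`, `p`, `ef_label`).
#' @export
label_clusters <- function(assignment, m, catalog, alpha = 0.05) {
  stopifnot(inherits(assignment, "cluster_assignment"), alpha > 0, alpha < 1)
  pm <- ef_paired_means(m, catalog)
  a <- assignment$assignment
  stopifnot(all(a$sample_id %in% names(pm$with_ef)))
  delta <- (pm$with_ef - pm$without)[a$sample_id]

  tests <- lapply(sort(unique(a$cluster)), function(cl) {
    members <- a$sample_id[a$cluster == cl]
    d <- delta[members]
    d <- d[!is.na(d)]
    if (length(d) == 0L) stop_gfscan(sprintf("cluster %s has no usable member", cl))
    if (length(d) == 1L) {
      warning(sprintf("cluster %d has a single member; labelled by delta sign", cl),
              call. = FALSE)
      p <- NA_real_
      dep <- d > 0
    } else if (sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
      # constant deltas: the paired test is degenerate; decide by magnitude
      p <- if (abs(mean(d)) <= 1e-10) 1 else 0
      dep <- p < alpha && mean(d) > 0
    } else {
      p <- t.test(pm$with_ef[members], pm$without[members], paired = TRUE)$p.value
      dep <- p < alpha && mean(d) > 0
    }
    data.frame(cluster = cl, n = length(d), mean_delta = mean(d), p = p,
               ef_label = if (dep) "dependent" else "independent",
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  a$ef_label <- tests$ef_label[match(a$cluster, tests$cluster)]
  a$dependency_delta <- unname(delta)
  assignment$assignment <- a
  assignment$cluster_tests <- tests
  assignment
}

#' Genotype enrichment in the dependency groups
#'
#' Two-sided Fisher's exact test of the 2x2 table of dependency label versus
#' a logical genotype flag.
#'
#' @param assignment a labelled `cluster_assignment`.
#' @param annotations annotation data.frame with `sample_id` and the flag.
#' @param flag name of a logical annotation column (e.g. `"idh1_mut"`).
#' @return list with the contingency `table`, `odds_ratio` and `p`.
#' @export
group_enrichment <- function(assignment, annotations, flag) {
  a <- assignment$assignment
  if (is.null(a$ef_label)) stop_gfscan("run label_clusters() first")
  if (!flag %in% names(annotations)) {
    stop_gfscan(sprintf("unknown annotation column '%s'", flag))
  }
  v <- annotations[[flag]][match(a$sample_id, annotations$sample_id)]
  tab <- table(ef_label = a$ef_label, flag = v)
  if (any(dim(tab) < 2L)) stop_gfscan("degenerate contingency table (empty margin)")
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}
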