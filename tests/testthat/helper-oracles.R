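# Independent brute-force oracles used to verify the package's statistics.
# These deliberately re-derive each quantity from first principles and share
# no code with the implementation.

# Two-sided Wilcoxon rank-sum p by complete enumeration of rank assignments.
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  idx_sets <- combn(length(pooled), nx)
  w_null <- apply(idx_sets, 2, function(ix) sum(r[ix]))
  p_le <- mean(w_null <= w_obs)
  p_ge <- mean(w_null >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up by direct evaluation of min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[ord][i:m] / (i:m))
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Two-sided Fisher exact p by summing hypergeometric probabilities of all
# tables with the observed margins that are no more probable.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  k_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(k_range, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Naive agglomerative Ward clustering: recompute the exact increase in total
# within-cluster sum of squares for every cluster pair at every merge.
oracle_ward_partitions <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), function(i) i)
  partitions <- list()
  partition_vec <- function(cl_list) {
    v <- integer(n)
    for (ci in seq_along(cl_list)) v[cl_list[[ci]]] <- ci
    v
  }
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        ci <- x[clusters[[i]], , drop = FALSE]
        cj <- x[clusters[[j]], , drop = FALSE]
        ni <- nrow(ci); nj <- nrow(cj)
        d2 <- sum((colMeans(ci) - colMeans(cj))^2)
        cost <- ni * nj / (ni + nj) * d2
        if (cost < best[1]) best <- c(cost, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    partitions[[length(clusters)]] <- partition_vec(clusters)
  }
  partitions  # partitions[[k]] = labels at k clusters
}

# Pearson correlation from the textbook sum formulas.
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# Hand evaluation of the rank-weighted ssGSEA running-sum score.
oracle_ssgsea_one <- function(values, gene_names, set, alpha = 0.25) {
  r <- rank(values, ties.method = "average")
  ord <- order(values, decreasing = TRUE)
  score <- 0
  p_in <- 0; p_out <- 0
  w_total <- sum(r[ord][gene_names[ord] %in% set]^alpha)
  n_out <- sum(!gene_names %in% set)
  for (i in seq_along(ord)) {
    g <- ord[i]
    if (gene_names[g] %in% set) {
      p_in <- p_in + r[g]^alpha / w_total
    } else {
      p_out <- p_out + 1 / n_out
    }
    score <- score + (p_in - p_out)
  }
  unname(score)
}

# A tiny two-factor catalog used throughout unit tests (6 non-control
# conditions + 2 controls).
tiny_catalog <- function() {
  panel <- data.frame(
    id = c("EGF", "bFGF", "GFA", "GFB"),
    name = c("egf", "bfgf", "factor A", "factor B"),
    concentration = c(5, 5, 1, 1),
    is_basal = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  enumerate_conditions(panel)
}

# Hand-built readout table: one sample per row of `wells`, columns d0/d6 per
# replicate, plus n6 readings.
make_readouts <- function(sample_id, condition_id, d0, d6, replicate = 1L) {
  rbind(
    data.frame(sample_id = sample_id, condition_id = condition_id,
               replicate = replicate, role = "D0", lum = d0,
               stringsAsFactors = FALSE),
    data.frame(sample_id = sample_id, condition_id = condition_id,
               replicate = replicate, role = "D6", lum = d6,
               stringsAsFactors = FALSE)
  )
}

n6_rows <- function(sample_id, lum, replicate = 1L) {
  data.frame(sample_id = sample_id, condition_id = "NO_GF",
             replicate = replicate, role = "N6", lum = lum,
             stringsAsFactors = FALSE)
}
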