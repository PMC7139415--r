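make_expr <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

test_that("the intrinsic filter keeps correlated, expressed, annotated genes", {
  set.seed(20)
  n <- 12
  samples <- paste0("S", 1:n)
  shared <- matrix(rnorm(5 * n, 5), 5, n)
  gsc <- rbind(shared,
               matrix(rnorm(2 * n, 5), 2, n),          # independent
               matrix(c(rep(0, n - 2), 5, 5), 1, n, byrow = TRUE))  # mostly zero
  tissue <- rbind(shared + rnorm(5 * n, 0, 0.05),
                  matrix(rnorm(2 * n, 5), 2, n),
                  matrix(c(rep(0, n - 2), 5, 5), 1, n, byrow = TRUE))
  gsc <- pmax(gsc, 0); tissue <- pmax(tissue, 0)
  genes <- paste0("G", 1:8)
  dimnames(gsc) <- dimnames(tissue) <- list(genes, samples)
  annotated <- setNames(rep(TRUE, 8), genes)
  annotated["G5"] <- FALSE

  res <- tumor_intrinsic_filter(gsc, tissue, annotated = annotated)
  expect_setequal(res$keep, c("G1", "G2", "G3", "G4"))
  expect_identical(res$report$reason[res$report$gene == "G5"], "unannotated")
  expect_identical(res$report$reason[res$report$gene == "G8"], "unexpressed")
  expect_identical(res$report$reason[res$report$gene == "G6"], "low_correlation")
})

test_that("perfect and reversed rank agreement sit at rho 1 and -1", {
  n <- 8
  samples <- paste0("S", 1:n)
  up <- seq_len(n)
  gsc <- rbind(G1 = up, G2 = up)
  tissue <- rbind(G1 = up, G2 = rev(up))
  colnames(gsc) <- colnames(tissue) <- samples
  res <- tumor_intrinsic_filter(gsc + 0.0, tissue + 0.0)
  expect_equal(res$report$rho[res$report$gene == "G1"], 1)
  expect_equal(res$report$rho[res$report$gene == "G2"], -1)
  expect_identical(res$keep, "G1")
})

test_that("Spearman rho boundary is inclusive and ties use average ranks", {
  # rho computed on average ranks equals rank-then-Pearson
  set.seed(30)
  n <- 10
  x <- sample(c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7))
  y <- sample(c(2, 2, 3, 3, 3, 5, 6, 6, 7, 8))
  expect_equal(suppressWarnings(cor(x, y, method = "spearman")),
               oracle_pearson(rank(x), rank(y)))
})

test_that("the filter requires at least five pairs and a one-to-one pairing", {
  e <- make_expr(rnorm(40, 5), paste0("G", 1:10), paste0("S", 1:4))
  expect_error(tumor_intrinsic_filter(pmax(e, 0), pmax(e, 0)), "5 paired")
})

test_that("intrinsic/microenvironment recovery on simulated expression is near-perfect", {
  ok <- sapply(1:3, function(seed) {
    ann <- generate_cohort(40, seed = seed)
    ex <- simulate_expression(ann, n_genes = 400, seed = seed + 50)
    res <- tumor_intrinsic_filter(
      ex$gsc, ex$tissue,
      annotated = setNames(ex$truth$annotated, ex$truth$gene))
    clean <- ex$truth$annotated & !ex$truth$zero_inflated
    intr <- ex$truth$gene[clean & ex$truth$class == "intrinsic"]
    micro <- ex$truth$gene[clean & ex$truth$class == "microenvironment"]
    c(sens = mean(intr %in% res$keep), spec = mean(!micro %in% res$keep))
  })
  expect_true(all(ok >= 0.95))
})

test_that("differential expression flags shifted genes and spares nulls", {
  set.seed(40)
  n_per <- 10
  e <- matrix(rnorm(110 * 2 * n_per, 5), 110, 2 * n_per)
  rownames(e) <- paste0("G", 1:110)
  colnames(e) <- paste0("S", 1:(2 * n_per))
  labels <- rep(c("a", "b"), each = n_per)
  e[101:110, labels == "a"] <- e[101:110, labels == "a"] + 10  # 10 sd shift
  e <- pmax(e, 0)
  deg <- differential_expression(e, labels)
  expect_true(all(deg$deg[101:110]))
  expect_true(all(deg$direction[101:110] == "up"))
  expect_lt(mean(deg$p[1:100] <= 0.05), 0.1 + 0.05)

  # equal means and spreads -> not a DEG; constant gene -> p = 1
  flat <- rbind(G1 = rep(c(5, 5.01), n_per), G2 = rep(5, 2 * n_per))
  colnames(flat) <- colnames(e)
  d2 <- differential_expression(flat, labels)
  expect_false(d2$deg[1])
  expect_equal(d2$p[2], 1)
})

test_that("DEG p-values match t.test and recall holds across seeds", {
  set.seed(41)
  e <- pmax(matrix(rnorm(20 * 12, 4), 20, 12,
                   dimnames = list(paste0("G", 1:20), paste0("S", 1:12))), 0)
  labels <- rep(c("x", "y"), each = 6)
  deg <- differential_expression(e, labels)
  for (g in c(1, 7, 20)) {
    ref <- t.test(e[g, labels == "x"], e[g, labels == "y"])$p.value
    expect_equal(deg$p[g], ref, tolerance = 1e-12)
  }

  recall <- sapply(1:20, function(seed) {
    set.seed(seed)
    e <- matrix(rnorm(110 * 20, 5), 110, 20)
    dimnames(e) <- list(paste0("G", 1:110), paste0("S", 1:20))
    e[101:110, 1:10] <- e[101:110, 1:10] + 3
    d <- differential_expression(pmax(e, 0), rep(c("a", "b"), each = 10))
    mean(d$deg[101:110])
  })
  expect_gte(mean(recall), 0.9)
})

ntp_toy <- function() {
  # 30 markers per class, 3 classes at play via 2-class templates
  set.seed(55)
  n_g <- 120; n_s <- 12
  e <- matrix(rnorm(n_g * n_s, 5), n_g, n_s,
              dimnames = list(paste0("G", 1:n_g), paste0("S", 1:n_s)))
  t_a <- paste0("G", 1:15)
  t_b <- paste0("G", 16:30)
  e[t_a, 1:6] <- e[t_a, 1:6] + 3
  e[t_b, 7:12] <- e[t_b, 7:12] + 3
  list(e = pmax(e, 0), templates = list(A = t_a, B = t_b))
}

test_that("NTP assigns samples to their planted class with confident p-values", {
  toy <- ntp_toy()
  res <- ntp_classify(toy$e, toy$templates, n_perm = 200, seed = 1)
  expect_identical(res$class, rep(c("A", "B"), each = 6))
  expect_true(all(res$p < 0.05))
  expect_false(any(res$tie))
})

test_that("a sample matching a template exactly gets distance ~0 and minimal p", {
  set.seed(56)
  genes <- paste0("G", 1:60)
  t_a <- genes[1:15]; t_b <- genes[16:30]
  e <- matrix(rnorm(60 * 10, 5), 60, 10, dimnames = list(genes, paste0("S", 1:10)))
  # plant one sample whose standardized profile is exactly the +1/-1 template
  e[, 1] <- 5
  e[t_a, 1] <- 50
  e[c(t_b, genes[31:60]), 1] <- 0.01
  e <- pmax(e, 0)
  res <- ntp_classify(e, list(A = t_a, B = t_b), n_perm = 100, seed = 2)
  expect_identical(res$class[1], "A")
  expect_equal(res$p[1], 1 / 101, tolerance = 1e-12)
})

test_that("NTP is invariant to gene order and per-gene affine rescaling", {
  toy <- ntp_toy()
  base <- ntp_classify(toy$e, toy$templates, n_perm = 50, seed = 3)
  perm <- sample(nrow(toy$e))
  reordered <- ntp_classify(toy$e[perm, ], toy$templates, n_perm = 50, seed = 3)
  expect_identical(base$class, reordered$class)

  scaled <- toy$e * 3 + 2
  res_scaled <- ntp_classify(scaled, toy$templates, n_perm = 50, seed = 3)
  expect_identical(base$class, res_scaled$class)
  expect_equal(base$distance, res_scaled$distance, tolerance = 1e-10)
})

test_that("NTP rejects overlapping templates and tiny marker sets", {
  toy <- ntp_toy()
  overlap <- list(A = toy$templates$A, B = c(toy$templates$A[1], toy$templates$B[-1]))
  expect_error(ntp_classify(toy$e, overlap, n_perm = 10, seed = 1), "disjoint")
  small <- list(A = toy$templates$A[1:3], B = toy$templates$B[1:3])
  expect_error(ntp_classify(toy$e, small, n_perm = 10, seed = 1), ">= 10")
})

test_that("ssGSEA scores equal the hand-computed running sum and respect extremes", {
  genes <- paste0("G", 1:5)
  e <- make_expr(c(5, 4, 3, 2, 1), genes, "S1")
  set2 <- c("G1", "G2")
  sc <- ssgsea_scores(e, list(top = set2, bottom = c("G4", "G5")))
  expect_equal(sc["top", 1], oracle_ssgsea_one(e[, 1], genes, set2))
  expect_equal(sc["bottom", 1],
               oracle_ssgsea_one(e[, 1], genes, c("G4", "G5")))

  # top placement maximises the score over all placements of |S| genes
  all_pairs <- combn(genes, 2, simplify = FALSE)
  scores <- sapply(all_pairs, function(s) ssgsea_scores(e, list(x = s))[1, 1])
  expect_equal(which.max(scores), 1)      # {G1, G2}
  expect_equal(which.min(scores), length(all_pairs))  # {G4, G5}
})

test_that("ssGSEA is invariant under strictly monotone per-sample transforms", {
  set.seed(60)
  e <- pmax(matrix(rnorm(50 * 4, 5), 50, 4,
                   dimnames = list(paste0("G", 1:50), paste0("S", 1:4))), 0)
  sets <- list(a = paste0("G", 1:8), b = paste0("G", 30:45))
  base <- ssgsea_scores(e, sets)
  expect_equal(ssgsea_scores(e^2, sets), base, tolerance = 1e-12)
  expect_equal(ssgsea_scores(log1p(e) * 7, sets), base, tolerance = 1e-12)
})

test_that("subtype assignment takes the arg-max of z-normalised scores and flags ties", {
  sc <- rbind(pro = c(5, 1, 1), mes = c(1, 5, 1), cla = c(1, 1, 5))
  colnames(sc) <- paste0("S", 1:3)
  res <- assign_subtype(sc)
  expect_identical(res$subtype, c("pro", "mes", "cla"))
  expect_false(any(res$tie))

  same_cols <- matrix(1:2, 2, 3, dimnames = list(c("a", "b"), paste0("S", 1:3)))
  res2 <- suppressMessages(assign_subtype(same_cols))
  expect_true(all(res2$tie))
})

test_that("NTP and ssGSEA subtype recovery on simulated cohorts exceeds 90%", {
  accs <- sapply(1:3, function(seed) {
    ann <- generate_cohort(48, seed = seed)
    ex <- simulate_expression(ann, n_genes = 400, seed = seed + 70)
    truth_sets <- split(
      ex$truth$gene[!is.na(ex$truth$subtype_marker)],
      ex$truth$subtype_marker[!is.na(ex$truth$subtype_marker)])
    gbm <- !is.na(ann$true_subtype)
    ntp <- ntp_classify(ex$gsc[, gbm], truth_sets, n_perm = 100, seed = seed)
    st <- assign_subtype(ssgsea_scores(ex$gsc[, gbm], truth_sets))
    c(ntp = mean(ntp$class == ann$true_subtype[gbm]),
      ssgsea = mean(st$subtype == ann$true_subtype[gbm]))
  })
  expect_true(all(accs >= 0.9))
})

test_that("two-class GSEA matches a hand-computed running sum on a toy ranking", {
  set.seed(70)
  genes <- paste0("G", 1:10)
  e <- matrix(rnorm(10 * 8, 4, 0.3), 10, 8,
              dimnames = list(genes, paste0("S", 1:8)))
  labels <- rep(c("hi", "lo"), each = 4)
  e[1:3, labels == "hi"] <- e[1:3, labels == "hi"] + 4  # set members to the top
  e <- pmax(e, 0)
  set <- c("G1", "G2", "G3", "G4", "G5")
  res <- gsea_two_class(e, labels, set, n_perm = 200, seed = 4)

  # oracle: recompute signal-to-noise, sort, accumulate the weighted ECDF gap
  m1 <- rowMeans(e[, labels == "hi"]); m2 <- rowMeans(e[, labels == "lo"])
  s <- (m1 - m2) / (apply(e[, labels == "hi"], 1, sd) +
                      apply(e[, labels == "lo"], 1, sd) + 1e-12)
  ord <- order(s, decreasing = TRUE)
  hit <- genes[ord] %in% set
  p_in <- cumsum(abs(s[ord]) * hit) / sum(abs(s[ord]) * hit)
  p_out <- cumsum(!hit) / sum(!hit)
  expect_equal(res$es, (p_in - p_out)[which.max(abs(p_in - p_out))])
  expect_gt(res$es, 0)
  expect_lt(res$p, 0.1)
})

test_that("GSEA is antisymmetric on a mirrored toy and rejects degenerate input", {
  set.seed(71)
  genes <- paste0("G", 1:20)
  e <- matrix(rnorm(20 * 8, 4, 0.2), 20, 8,
              dimnames = list(genes, paste0("S", 1:8)))
  labels <- rep(c("a", "b"), each = 4)
  e[1:10, labels == "a"] <- e[1:10, labels == "a"] + 3
  e <- pmax(e, 0)
  up <- gsea_two_class(e, labels, genes[1:10], n_perm = 100, seed = 5)
  down <- gsea_two_class(e, labels, genes[11:20], n_perm = 100, seed = 5)
  expect_gt(up$es, 0)
  expect_lt(down$es, 0)

  flat <- matrix(5, 20, 8, dimnames = dimnames(e))
  expect_error(gsea_two_class(flat, labels, genes[1:10], seed = 1),
               "degenerate")
})

test_that("GSEA null p-values are roughly uniform for random gene sets", {
  set.seed(72)
  e <- pmax(matrix(rnorm(200 * 10, 4), 200, 10,
                   dimnames = list(paste0("G", 1:200), paste0("S", 1:10))), 0)
  labels <- rep(c("a", "b"), each = 5)
  ps <- sapply(1:20, function(i) {
    set.seed(i)
    gsea_two_class(e, labels, sample(rownames(e), 15), n_perm = 100,
                   seed = i)$p
  })
  expect_gt(mean(ps), 0.2)   # not systematically significant
  expect_gt(min(ps), 1 / 202)
})
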