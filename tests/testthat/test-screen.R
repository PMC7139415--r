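test_that("the cell growth index follows (D6 - N6)/D0, sign included", {
  expect_equal(cell_growth_index(1000, 5000, 1000), 4)
  expect_equal(cell_growth_index(1234, 987, 987), 0)
  expect_equal(cell_growth_index(2000, 1500, 2500), -0.5)
  expect_error(cell_growth_index(0, 1, 1), "positive")
  expect_error(cell_growth_index(-5, 1, 1), "positive")
  expect_error(cell_growth_index(10, -1, 1), "non-negative")
})

test_that("QC applies strict thresholds to day-6 signal and day-6/day-0 ratio", {
  ro <- rbind(
    make_readouts("S1", "GFA", 1000, 4000),            # low signal
    make_readouts("S1", "GFB", 20000, 8000, 1L),       # ratio 0.4, signal ok
    make_readouts("S1", "GFA/GFB", 10000, 6000, 1L),   # ratio 0.6, signal ok
    make_readouts("S1", "NBE", 1000, 5000, 1L),        # signal exactly 5000
    make_readouts("S1", "GFA/E&F", 10000, 5000.5, 1L)  # both rules just pass
  )
  qc <- qc_filter(ro)
  get <- function(cid) qc$qc_pass[qc$condition_id == cid]
  expect_false(get("GFA"))
  expect_identical(qc$reason[qc$condition_id == "GFA"], "low_signal")
  expect_false(get("GFB"))
  expect_identical(qc$reason[qc$condition_id == "GFB"], "low_ratio")
  expect_true(get("GFA/GFB"))
  expect_false(get("NBE"))      # "more than 5000" is strict
  expect_true(get("GFA/E&F"))   # 5000.5 > 5000 and ratio > 0.5
})

test_that("QC monotonicity: raising thresholds never turns a fail into a pass", {
  set.seed(10)
  ro <- do.call(rbind, lapply(1:30, function(i) {
    make_readouts("S1", paste0("C", i), runif(1, 500, 20000),
                  runif(1, 500, 20000))
  }))
  base <- qc_filter(ro, min_signal = 4000, min_ratio = 0.4)
  for (ms in c(5000, 8000)) {
    for (mr in c(0.5, 0.9)) {
      stricter <- qc_filter(ro, min_signal = ms, min_ratio = mr)
      expect_true(all(stricter$qc_pass <= base$qc_pass))
    }
  }
})

test_that("a D6 well without D0 fails QC with a warning, not an error", {
  ro <- data.frame(sample_id = "S1", condition_id = "GFA", replicate = 1L,
                   role = "D6", lum = 9000)
  expect_warning(qc <- qc_filter(ro), "no D0")
  expect_false(qc$qc_pass)
  expect_identical(qc$reason, "missing_d0")
})

test_that("index matrix averages replicate luminescence before the formula", {
  catalog <- tiny_catalog()
  ro <- rbind(
    make_readouts("S1", "GFA", c(1000, 1000), c(4800, 5200), 1:2),
    n6_rows("S1", c(900, 1100), 1:2)
  )
  m <- build_index_matrix(ro, catalog, min_signal = 4000)
  # mean D6 = 5000, mean D0 = 1000, N6 = 1000 -> G = 4
  expect_equal(m$index["S1", "GFA"], 4)
  expect_equal(m$rate["S1", "GFA"], 5)
  expect_equal(m$n_replicates["S1", "GFA"], 2L)
})

test_that("a failing replicate is dropped and the survivor used, provenance recorded", {
  catalog <- tiny_catalog()
  ro <- rbind(
    make_readouts("S1", "GFA", c(1000, 1000), c(6000, 400), 1:2),  # rep 2 fails QC
    n6_rows("S1", 1000)
  )
  m <- build_index_matrix(ro, catalog)
  expect_equal(m$index["S1", "GFA"], (6000 - 1000) / 1000)
  expect_equal(m$n_replicates["S1", "GFA"], 1L)
})

test_that("cells with all replicates failing, or samples without N6, are masked", {
  catalog <- tiny_catalog()
  ro <- rbind(
    make_readouts("S1", "GFA", 1000, 400),   # fails QC
    n6_rows("S1", 1000),
    make_readouts("S2", "GFA", 1000, 6000)   # no N6 for S2
  )
  expect_warning(m <- build_index_matrix(ro, catalog), "N6")
  expect_true(is.na(m$index["S1", "GFA"]))
  expect_false(m$qc_pass["S1", "GFA"])
  expect_true(is.na(m$index["S2", "GFA"]))
})

test_that("index matrix equals a naive per-cell recomputation on random tables", {
  catalog <- tiny_catalog()
  cond_ids <- catalog$conditions$condition_id
  screen_ids <- setdiff(cond_ids, "NO_GF")
  for (seed in 1:5) {
    set.seed(seed)
    samples <- paste0("S", 1:5)
    rows <- list()
    for (s in samples) {
      for (cid in screen_ids) {
        for (r in 1:2) {
          rows[[length(rows) + 1L]] <-
            make_readouts(s, cid, runif(1, 4000, 12000), runif(1, 1000, 30000), r)
        }
      }
      rows[[length(rows) + 1L]] <- n6_rows(s, runif(2, 4000, 9000), 1:2)
    }
    ro <- do.call(rbind, rows)
    m <- build_index_matrix(ro, catalog)

    # oracle: direct loop over the table
    for (s in samples) {
      n6 <- mean(ro$lum[ro$sample_id == s & ro$role == "N6"])
      for (cid in screen_ids) {
        d0 <- d6 <- numeric(0)
        for (r in 1:2) {
          sel <- ro$sample_id == s & ro$condition_id == cid & ro$replicate == r
          d0r <- ro$lum[sel & ro$role == "D0"]
          d6r <- ro$lum[sel & ro$role == "D6"]
          if (d6r > 5000 && d6r / d0r > 0.5) {
            d0 <- c(d0, d0r); d6 <- c(d6, d6r)
          }
        }
        if (length(d0) == 0) {
          expect_true(is.na(m$index[s, cid]))
        } else {
          expect_equal(m$index[s, cid], (mean(d6) - n6) / mean(d0))
          expect_equal(m$rate[s, cid], mean(d6) / mean(d0))
        }
      }
    }
  }
})

test_that("growth statistics are invariant to a per-sample luminescence scale", {
  catalog <- tiny_catalog()
  ann <- generate_cohort(4, seed = 3)
  ro <- simulate_readouts(ann, catalog, growth_model_params(), seed = 3)
  m1 <- build_index_matrix(ro, catalog, min_signal = 0)
  ro2 <- ro
  scale_by <- c(2, 10, 0.5, 7)[match(ro2$sample_id, unique(ro2$sample_id))]
  ro2$lum <- ro2$lum * scale_by
  m2 <- build_index_matrix(ro2, catalog, min_signal = 0)
  expect_equal(m1$index, m2$index, tolerance = 1e-12)
  expect_equal(m1$rate, m2$rate, tolerance = 1e-12)
})

test_that("replicate concordance matches the textbook Pearson formula and is affine-invariant", {
  a <- c(0.1, 0.5, 2.0, 3.2, 1.1, 0.4)
  b <- c(0.2, 0.6, 1.7, 3.6, 0.9, 0.6)
  expect_equal(replicate_concordance(a, a), 1)
  expect_equal(replicate_concordance(a, 2 * a + 1), 1)
  expect_equal(replicate_concordance(a, b), oracle_pearson(a, b)^2)
  expect_error(replicate_concordance(c(1, 2, NA), c(1, NA, 3)), "fewer than 3")
})

test_that("group growth comparison reproduces the Welch t-test", {
  x <- c(0.8, 1.1, 1.4, 0.9, 2.0, 2.4, 1.9, 2.2)
  g <- rep(c("LGG", "GBM"), each = 4)
  res <- group_growth_comparison(x, g)
  ref <- t.test(x[g == "GBM"], x[g == "LGG"])
  expect_equal(res$p, ref$p.value)
  expect_equal(sort(unname(res$means)), sort(c(mean(x[1:4]), mean(x[5:8]))))

  same <- group_growth_comparison(rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(same$p, 1)
  expect_equal(same$t, 0)

  sep <- group_growth_comparison(c(0, 0, 0.001, 5, 5, 5.001),
                                 rep(c("a", "b"), each = 3))
  expect_lt(sep$p, 1e-4)
})

test_that("cohort proportions reproduce the printed screening-cohort percentages", {
  ann <- generate_cohort(72, seed = 21)
  pr <- cohort_proportions(ann)
  expect_equal(pr$pct[pr$metric == "lgg_ef_independent"], 73.7)
  expect_equal(pr$pct[pr$metric == "proneural_among_dependent_idh1wt"], 34.6)
  expect_equal(pr$pct[pr$metric == "gbm_idh1_mut"], 11.3)
  expect_equal(pr$pct[pr$metric == "lgg_codel"], 47.4)
})
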