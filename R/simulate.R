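# Synthetic cohorts: genotypes, plate readouts and expression matrices with
# planted ground truth, so every pipeline stage can be verified without
# access to raw screen data.
#
# The growth model is log-linear over the 6-day screening window: each sample
# grows (or declines) exponentially at a per-day log rate
#
#   r(sample, condition) = b_s + sum_f beta(f, sample) + synergy(pair, sample)
#
# where b_s is the sample's baseline rate in basal media, beta(f, .) the
# additive effect of each growth factor in the condition (EGF and bFGF count
# when the condition carries the E&F supplement), and designated pairs add an
# extra synergy term. Luminescence readouts are the expected cell mass times
# i.i.d. multiplicative log-normal noise.

#' Default genotype frequency specification for a simulated cohort
#'
#' Encodes the screened cohort's printed composition: 19/72 lower-grade
#' gliomas (LGG), all IDH1-mutant with 9/19 1p19q co-deleted and 14/19
#' EGF/bFGF-independent; 53 glioblastomas of which 6 are IDH1-mutant; among
#' IDH1-wild-type glioblastomas 26 EGF/bFGF-dependent (9 proneural, 7
#' mesenchymal, 10 classical) and 21 independent (2 proneural, 10
#' mesenchymal, 9 classical), with all 4 BRAF-mutant samples independent.
#' Frequencies without a printed value (ATRX, TP53, EGFR, PTEN, CIC, FUBP1,
#' NOTCH1 rates) are plausible cohort-level choices.
#'
#' @return a nested list of stratum frequencies, all in [0, 1].
#' @export
cohort_frequencies <- function() {
  list(
    lgg_fraction = 19 / 72,
    lgg = list(
      idh1_mut = 1.0,
      codel_given_mut = 9 / 19,
      ef_independent = 14 / 19,
      atrx_given_intact = 0.7,
      tp53_given_intact = 0.8,
      cic_given_codel = 0.6,
      fubp1_given_codel = 1 / 3,
      notch1 = 0.2
    ),
    gbm = list(
      idh1_mut = 6 / 53,
      ef_independent_given_mut = 4 / 6,
      ef_dependent_given_wt = 26 / 47,
      subtype_dependent_wt = c(proneural = 9, mesenchymal = 7, classical = 10) / 26,
      subtype_independent_wt = c(proneural = 2, mesenchymal = 10, classical = 9) / 21,
      subtype_mut = c(proneural = 4, mesenchymal = 1, classical = 1) / 6,
      braf_given_wt_independent = 4 / 21,
      atrx_given_mut = 4 / 6,
      tp53_given_mut = 5 / 6,
      tp53_given_wt = 0.3,
      egfr_given_wt = 0.45,
      pten_given_wt = 0.35
    )
  )
}

# Split n into integer counts proportional to probs (largest-remainder rule).
exact_counts <- function(n, probs) {
  stopifnot(abs(sum(probs) - 1) < 1e-8)
  raw <- n * probs
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# Randomly flag round(freq * |idx|) of the given indices.
flag_subset <- function(n_total, idx, freq) {
  out <- rep(FALSE, n_total)
  k <- round(freq * length(idx))
  if (k > 0) out[idx[sample.int(length(idx), k)]] <- TRUE
  out
}

validate_frequencies <- function(fr) {
  walk <- function(x, path) {
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v)) {
        walk(v, paste0(path, nm, "$"))
      } else {
        assert_prob(v, paste0(path, nm))
      }
    }
  }
  walk(fr, "")
  invisible(fr)
}

#' Generate a synthetic GSC cohort annotation table
#'
#' Draws `n` samples with diagnosis, genotype flags, a planted transcriptional
#' subtype (glioblastoma only) and a planted EGF/bFGF-dependency group.
#' Stratum counts are exact (largest-remainder rounding of the frequencies);
#' which samples carry each flag is randomised under `seed`. Invariants:
#' 1p19q co-deletion implies IDH1 mutation, and ATRX mutation and co-deletion
#' are mutually exclusive.
#'
#' @param n cohort size (default 72, the screened cohort).
#' @param frequencies frequency specification, see [cohort_frequencies()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with columns `sample_id`, `diagnosis` (LGG/GBM),
#'   mutation flags (`idh1_mut`, `codel_1p19q`, `atrx_mut`, `braf_mut`,
#'   `tp53_mut`, `egfr_mut`, `pten_mut`, `cic_mut`, `fubp1_mut`,
#'   `notch1_mut`), `true_subtype` (proneural/classical/mesenchymal or NA),
#'   `true_ef_group` (dependent/independent), plus derived logical columns
#'   (`ef_dependent`, `subtype_proneural`, `subtype_classical`,
#'   `subtype_mesenchymal`) for use in subgroup filters.
#' @examples
#' ann <- generate_cohort(n = 72, seed = 1)
#' table(ann$diagnosis, ann$idh1_mut)
#' @export
generate_cohort <- function(n = 72L, frequencies = cohort_frequencies(), seed) {
  stopifnot(n >= 1L)
  validate_frequencies(frequencies)
  fr <- frequencies
  with_seed(seed, {
    n_lgg <- round(n * fr$lgg_fraction)
    n_gbm <- n - n_lgg
    diagnosis <- c(rep("LGG", n_lgg), rep("GBM", n_gbm))
    idh1 <- codel <- atrx <- braf <- tp53 <- egfr <- pten <-
      cic <- fubp1 <- notch1 <- rep(FALSE, n)
    subtype <- rep(NA_character_, n)
    ef_group <- rep(NA_character_, n)

    lgg_idx <- which(diagnosis == "LGG")
    gbm_idx <- which(diagnosis == "GBM")

    if (n_lgg > 0) {
      idh1 <- idh1 | flag_subset(n, lgg_idx, fr$lgg$idh1_mut)
      lgg_mut <- intersect(lgg_idx, which(idh1))
      codel <- codel | flag_subset(n, lgg_mut, fr$lgg$codel_given_mut)
      indep <- flag_subset(n, lgg_idx, fr$lgg$ef_independent)
      ef_group[lgg_idx] <- ifelse(indep[lgg_idx], "independent", "dependent")
      intact_mut <- intersect(lgg_mut, which(!codel))
      atrx <- atrx | flag_subset(n, intact_mut, fr$lgg$atrx_given_intact)
      tp53 <- tp53 | flag_subset(n, intact_mut, fr$lgg$tp53_given_intact)
      codel_idx <- intersect(lgg_idx, which(codel))
      cic <- cic | flag_subset(n, codel_idx, fr$lgg$cic_given_codel)
      fubp1 <- fubp1 | flag_subset(n, codel_idx, fr$lgg$fubp1_given_codel)
      notch1 <- notch1 | flag_subset(n, lgg_idx, fr$lgg$notch1)
    }

    if (n_gbm > 0) {
      idh1 <- idh1 | flag_subset(n, gbm_idx, fr$gbm$idh1_mut)
      gbm_mut <- intersect(gbm_idx, which(idh1))
      gbm_wt <- setdiff(gbm_idx, gbm_mut)
      indep_mut <- flag_subset(n, gbm_mut, fr$gbm$ef_independent_given_mut)
      dep_wt <- flag_subset(n, gbm_wt, fr$gbm$ef_dependent_given_wt)
      ef_group[gbm_mut] <- ifelse(indep_mut[gbm_mut], "independent", "dependent")
      ef_group[gbm_wt] <- ifelse(dep_wt[gbm_wt], "dependent", "independent")

      assign_subtypes <- function(idx, probs) {
        if (length(idx) == 0) return()
        counts <- exact_counts(length(idx), probs)
        shuffled <- idx[sample.int(length(idx))]
        labels <- rep(names(probs), counts)
        subtype[shuffled] <<- labels
      }
      assign_subtypes(intersect(gbm_wt, which(ef_group == "dependent")),
                      fr$gbm$subtype_dependent_wt)
      assign_subtypes(intersect(gbm_wt, which(ef_group == "independent")),
                      fr$gbm$subtype_independent_wt)
      assign_subtypes(gbm_mut, fr$gbm$subtype_mut)

      wt_indep <- intersect(gbm_wt, which(ef_group == "independent"))
      braf <- braf | flag_subset(n, wt_indep, fr$gbm$braf_given_wt_independent)
      atrx <- atrx | flag_subset(n, gbm_mut, fr$gbm$atrx_given_mut)
      tp53 <- tp53 | flag_subset(n, gbm_mut, fr$gbm$tp53_given_mut)
      tp53 <- tp53 | flag_subset(n, gbm_wt, fr$gbm$tp53_given_wt)
      egfr <- egfr | flag_subset(n, gbm_wt, fr$gbm$egfr_given_wt)
      pten <- pten | flag_subset(n, gbm_wt, fr$gbm$pten_given_wt)
    }

    ann <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      diagnosis = diagnosis,
      idh1_mut = idh1, codel_1p19q = codel, atrx_mut = atrx, braf_mut = braf,
      tp53_mut = tp53, egfr_mut = egfr, pten_mut = pten, cic_mut = cic,
      fubp1_mut = fubp1, notch1_mut = notch1,
      true_subtype = subtype,
      true_ef_group = ef_group,
      stringsAsFactors = FALSE
    )
    ann$ef_dependent <- ann$true_ef_group == "dependent"
    ann$subtype_proneural <- !is.na(subtype) & subtype == "proneural"
    ann$subtype_classical <- !is.na(subtype) & subtype == "classical"
    ann$subtype_mesenchymal <- !is.na(subtype) & subtype == "mesenchymal"
    stopifnot(!any(ann$codel_1p19q & !ann$idh1_mut),
              !any(ann$codel_1p19q & ann$atrx_mut))
    ann
  })
}

#' Default growth-model parameters for the readout simulator
#'
#' Per-day log-growth rates. Baseline rates in basal media are drawn
#' uniformly per sample from genotype-dependent ranges (IDH1-mutant GSCs
#' decline in basal media; wild-type straddle zero). Each growth factor adds
#' a small base effect; genotype-restricted boosts and pair synergies plant
#' the screen's qualitative findings: PEDF+MDK is optimal for mesenchymal
#' IDH1-wild-type samples, PlGF+IL-6 for IDH1-mutant/1p19q-intact, PEDF+SHH
#' for IDH1-mutant/co-deleted, and TGF-\u03b2 preferentially helps
#' IDH1-mutant/ATRX-mutant samples. EGF and bFGF effects depend on the
#' sample's planted dependency group: 0.06/day each for dependent samples and
#' zero for independent ones (whose growth, by definition, is unaffected by
#' the supplement), plus a per-sample jitter of sd `ef_jitter_sd` on the
#' combined E&F response. Readout noise is multiplicative log-normal.
#'
#' @param noise_sd standard deviation of per-well log-normal readout noise.
#' @param ef_jitter_sd per-sample sd of the combined EGF+bFGF response around
#'   its group mean (per-day log units).
#' @param lum_per_cell luminescence units per cell.
#' @param n_seeded cells seeded per well.
#' @param horizon screening window in days.
#' @return a list of class `growth_model_params`.
#' @export
growth_model_params <- function(noise_sd = 0.04, ef_jitter_sd = 0.012,
                                lum_per_cell = 20,
                                n_seeded = 1000, horizon = 6) {
  stopifnot(noise_sd >= 0, ef_jitter_sd >= 0, lum_per_cell > 0, n_seeded > 0,
            horizon > 0)
  structure(list(
    baseline_ranges = data.frame(
      filter = c("idh1_mut", "!idh1_mut"),
      min = c(-0.09, -0.04),
      max = c(-0.01, 0.06),
      stringsAsFactors = FALSE
    ),
    base_effects = c(
      IGF1 = 0.010, "NRG-1" = 0.008, HGF = 0.006, PDGF = 0.012,
      PlGF = 0.004, PEDF = 0.010, Sema3A = 0.000, "TGF-\u03b2" = 0.002,
      "IL-6" = 0.006, SHH = 0.004, MDK = 0.012,
      EGF = 0, bFGF = 0
    ),
    genotype_effects = data.frame(
      gf = c("EGF", "bFGF",
             "PEDF", "MDK",
             "PlGF", "IL-6",
             "PEDF", "SHH",
             "TGF-\u03b2"),
      filter = c("ef_dependent", "ef_dependent",
                 "!idh1_mut & subtype_mesenchymal",
                 "!idh1_mut & subtype_mesenchymal",
                 "idh1_mut & !codel_1p19q", "idh1_mut & !codel_1p19q",
                 "idh1_mut & codel_1p19q", "idh1_mut & codel_1p19q",
                 "idh1_mut & atrx_mut"),
      effect = c(0.060, 0.060, 0.015, 0.015, 0.025, 0.025, 0.025, 0.025,
                 0.035),
      stringsAsFactors = FALSE
    ),
    synergy_effects = data.frame(
      gf1 = c("MDK", "IL-6", "PEDF"),
      gf2 = c("PEDF", "PlGF", "SHH"),
      filter = c("!idh1_mut & subtype_mesenchymal",
                 "idh1_mut & !codel_1p19q",
                 "idh1_mut & codel_1p19q"),
      effect = c(0.020, 0.060, 0.060),
      stringsAsFactors = FALSE
    ),
    noise_sd = noise_sd,
    ef_jitter_sd = ef_jitter_sd,
    lum_per_cell = lum_per_cell,
    n_seeded = n_seeded,
    horizon = horizon
  ), class = "growth_model_params")
}

# Per-day log growth rate of every sample under every catalog condition
# (noise-free). Returns a samples x conditions matrix including controls.
expected_rate_matrix <- function(cohort, catalog, params) {
  cond <- catalog$conditions
  panel_ids <- resolve_gf_alias(catalog$panel$id)
  known <- union(names(params$base_effects), panel_ids)
  eff_gfs <- unique(c(params$genotype_effects$gf,
                      params$synergy_effects$gf1, params$synergy_effects$gf2))
  unknown <- setdiff(resolve_gf_alias(eff_gfs), known)
  if (length(unknown) > 0) {
    stop_gfscan(sprintf("effect table references unknown growth factor(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  n <- nrow(cohort)

  # per-sample effect of each growth factor: base + matching genotype boosts;
  # panel factors without a declared base effect are neutral
  base <- setNames(rep(0, length(known)), known)
  base[names(params$base_effects)] <- params$base_effects
  beta <- matrix(rep(base, each = n),
                 nrow = n, dimnames = list(cohort$sample_id, known))
  ge <- params$genotype_effects
  for (i in seq_len(nrow(ge))) {
    match_s <- parse_subgroup_filter(ge$filter[i])(cohort)
    beta[match_s, resolve_gf_alias(ge$gf[i])] <-
      beta[match_s, resolve_gf_alias(ge$gf[i])] + ge$effect[i]
  }

  # per-sample baseline: first matching range wins
  b <- rep(NA_real_, n)
  for (i in seq_len(nrow(params$baseline_ranges))) {
    match_s <- parse_subgroup_filter(params$baseline_ranges$filter[i])(cohort)
    open <- match_s & is.na(b)
    b[open] <- runif(sum(open), params$baseline_ranges$min[i],
                     params$baseline_ranges$max[i])
  }
  if (anyNA(b)) stop_gfscan("baseline_ranges do not cover every sample")

  rates <- matrix(b, nrow = n, ncol = nrow(cond),
                  dimnames = list(cohort$sample_id, cond$condition_id))
  ef_effect <- beta[, "EGF"] + beta[, "bFGF"]
  if ((params$ef_jitter_sd %||% 0) > 0) {
    # mean shift keeps the multiplicative 6-day E&F response mean-one for a
    # zero group effect: E[exp(horizon * j)] = 1
    mu <- -params$horizon * params$ef_jitter_sd^2 / 2
    ef_effect <- ef_effect + rnorm(n, mu, params$ef_jitter_sd)
  }
  se <- params$synergy_effects
  synergy_match <- lapply(seq_len(nrow(se)), function(i) {
    parse_subgroup_filter(se$filter[i])(cohort)
  })
  for (j in seq_len(nrow(cond))) {
    fs <- stats::na.omit(c(cond$factor_1[j], cond$factor_2[j]))
    if (length(fs) > 0) {
      rates[, j] <- rates[, j] + rowSums(beta[, fs, drop = FALSE])
    }
    if (cond$with_ef[j]) rates[, j] <- rates[, j] + ef_effect
    if (length(fs) == 2L && nrow(se) > 0) {
      for (i in seq_len(nrow(se))) {
        if (setequal(fs, resolve_gf_alias(c(se$gf1[i], se$gf2[i])))) {
          rates[synergy_match[[i]], j] <- rates[synergy_match[[i]], j] + se$effect[i]
        }
      }
    }
  }
  list(rates = rates, baseline = setNames(b, cohort$sample_id))
}

#' Simulate plate luminescence readouts for a cohort
#'
#' For every sample x condition x replicate, emits day-0 (`D0`) and day-6
#' (`D6`) luminescence; the basal-media `NO_GF` control wells are read on
#' day 6 as the `N6` role (the reference of the cell growth index). Expected
#' D6 equals D0 times exp(horizon x rate) under the log-linear growth model;
#' every well reading is multiplied by independent log-normal noise.
#'
#' @param cohort annotation table from [generate_cohort()].
#' @param catalog a `condition_catalog`.
#' @param params a `growth_model_params` list.
#' @param seed integer seed.
#' @param n_replicates technical replicates per condition (default 2).
#' @return data.frame (`sample_id`, `condition_id`, `replicate`, `role`,
#'   `lum`) with attributes `rate_matrix` (true per-day log rates) and
#'   `baseline` (true basal rates) for ground-truth checks.
#' @export
simulate_readouts <- function(cohort, catalog, params = growth_model_params(),
                              seed, n_replicates = 2L) {
  stopifnot(inherits(catalog, "condition_catalog"), nrow(cohort) >= 1L,
            n_replicates >= 1L)
  cond <- catalog$conditions
  with_seed(seed, {
    truth <- expected_rate_matrix(cohort, catalog, params)
    rates <- truth$rates
    d0_expect <- params$n_seeded * params$lum_per_cell
    n_s <- nrow(cohort)
    n_c <- nrow(cond)

    grid <- expand.grid(replicate = seq_len(n_replicates),
                        cond_j = seq_len(n_c),
                        sample_i = seq_len(n_s))
    role_day6 <- ifelse(cond$kind[grid$cond_j] == "control_no_gf", "N6", "D6")
    day6_expect <- d0_expect *
      exp(params$horizon * rates[cbind(grid$sample_i, grid$cond_j)])
    n_rows <- nrow(grid)
    noise <- function(k) {
      if (params$noise_sd == 0) rep(1, k) else exp(rnorm(k, 0, params$noise_sd))
    }
    out <- data.frame(
      sample_id = rep(cohort$sample_id[grid$sample_i], 2L),
      condition_id = rep(cond$condition_id[grid$cond_j], 2L),
      replicate = rep(grid$replicate, 2L),
      role = c(rep("D0", n_rows), role_day6),
      lum = c(d0_expect * noise(n_rows), day6_expect * noise(n_rows)),
      stringsAsFactors = FALSE
    )
    out <- out[order(match(out$sample_id, cohort$sample_id),
                     match(out$condition_id, cond$condition_id),
                     out$replicate, out$role), ]
    rownames(out) <- NULL
    attr(out, "rate_matrix") <- rates
    attr(out, "baseline") <- truth$baseline
    out
  })
}

#' Simulate paired GSC and tissue expression matrices
#'
#' Generates log2(RPKM + 1)-scale matrices for the cohort's GSCs and their
#' parental tissues. Tumor-intrinsic genes share a latent per-sample signal
#' between the two matrices (high paired Spearman correlation);
#' microenvironment genes are independent between GSC and tissue. Three
#' disjoint marker blocks are shifted upward in samples of the matching
#' planted subtype (both matrices, so they stay intrinsic). A designated
#' fraction of genes is zeroed in most samples to exercise the
#' expressed-fraction filter, and a fraction is flagged unannotated.
#'
#' @param cohort annotation table from [generate_cohort()].
#' @param n_genes total genes (>= 10).
#' @param intrinsic_fraction fraction of genes sharing the latent signal.
#' @param seed integer seed.
#' @param noise_sd sd of gene-level measurement noise around the latent
#'   signal (latent sd is 1).
#' @param n_markers marker genes per subtype block.
#' @param subtype_shift upward shift of a marker gene in samples of its
#'   subtype (log2 units).
#' @param zero_fraction fraction of genes zeroed in > half the samples.
#' @param unannotated_fraction fraction of genes flagged unannotated.
#' @return list with `gsc` and `tissue` matrices (genes x samples, identical
#'   column order = implicit pairing), and `truth` data.frame (`gene`,
#'   `class`, `subtype_marker`, `annotated`, `zero_inflated`).
#' @export
simulate_expression <- function(cohort, n_genes = 1000L,
                                intrinsic_fraction = 0.6, seed,
                                noise_sd = 0.4, n_markers = 30L,
                                subtype_shift = 2.0,
                                zero_fraction = 0.08,
                                unannotated_fraction = 0.05) {
  stopifnot(n_genes >= 10L, intrinsic_fraction > 0, intrinsic_fraction < 1,
            noise_sd >= 0)
  n_s <- nrow(cohort)
  n_int <- round(n_genes * intrinsic_fraction)
  subtypes <- c("proneural", "classical", "mesenchymal")
  if (3L * n_markers > n_int) {
    stop_gfscan("3 * n_markers must not exceed the intrinsic gene count")
  }
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    class <- c(rep("intrinsic", n_int),
               rep("microenvironment", n_genes - n_int))
    marker <- rep(NA_character_, n_genes)
    for (k in seq_along(subtypes)) {
      marker[((k - 1L) * n_markers + 1L):(k * n_markers)] <- subtypes[k]
    }

    mu <- rnorm(n_genes, mean = 4, sd = 1)
    shared <- matrix(rnorm(n_genes * n_s), n_genes, n_s)
    gsc <- mu + shared + rnorm(n_genes * n_s, 0, noise_sd)
    tissue_latent <- shared
    micro <- class == "microenvironment"
    tissue_latent[micro, ] <- rnorm(sum(micro) * n_s)
    tissue <- mu + tissue_latent + rnorm(n_genes * n_s, 0, noise_sd)

    for (k in seq_along(subtypes)) {
      in_sub <- !is.na(cohort$true_subtype) & cohort$true_subtype == subtypes[k]
      rows <- which(!is.na(marker) & marker == subtypes[k])
      if (any(in_sub)) {
        gsc[rows, in_sub] <- gsc[rows, in_sub] + subtype_shift
        tissue[rows, in_sub] <- tissue[rows, in_sub] + subtype_shift
      }
    }

    non_marker <- which(is.na(marker))
    zero_inflated <- rep(FALSE, n_genes)
    n_zero <- round(zero_fraction * n_genes)
    if (n_zero > 0) {
      zg <- sample(non_marker, n_zero)
      zero_inflated[zg] <- TRUE
      for (g in zg) {
        off <- sample(n_s, ceiling(0.7 * n_s))
        gsc[g, off] <- 0
        tissue[g, off] <- 0
      }
    }
    annotated <- rep(TRUE, n_genes)
    n_unann <- round(unannotated_fraction * n_genes)
    if (n_unann > 0) {
      annotated[sample(setdiff(non_marker, which(zero_inflated)), n_unann)] <- FALSE
    }

    gsc <- pmax(gsc, 0)
    tissue <- pmax(tissue, 0)
    dimnames(gsc) <- dimnames(tissue) <- list(genes, cohort$sample_id)
    truth <- data.frame(gene = genes, class = class, subtype_marker = marker,
                        annotated = annotated, zero_inflated = zero_inflated,
                        stringsAsFactors = FALSE)
    list(gsc = gsc, tissue = tissue, truth = truth)
  })
}
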