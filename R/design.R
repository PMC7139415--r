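# Condition catalog: combinatorial design of the growth-factor screen.
#
# The screen tests every unordered pair and every single of a panel of
# non-basal growth factors, each duplicated with and without the basal
# EGF + bFGF supplement ("E&F"), plus two controls: basal media with no
# growth factor at all ("NO_GF", the day-6 reference for the growth index)
# and the conventional NBE condition (media + E&F only).

EF_SUFFIX <- "E&F"
NO_GF_ID <- "NO_GF"
NBE_ID <- "NBE"

# ASCII aliases accepted on input for growth-factor ids that carry
# non-ASCII characters or punctuation variants in the canonical panel.
GF_ALIASES <- c(
  "TGFB"    = "TGF-\u03b2",
  "TGF-B"   = "TGF-\u03b2",
  "TGFBETA" = "TGF-\u03b2",
  "IL6"     = "IL-6",
  "NRG1"    = "NRG-1",
  "SEMA3A"  = "Sema3A",
  "PLGF"    = "PlGF"
)

#' Resolve ASCII aliases of growth-factor ids
#'
#' Input tables are allowed to spell ids in plain ASCII (e.g. `TGFB`, `IL6`);
#' this maps them onto the canonical panel spelling (`TGF-\u03b2`, `IL-6`).
#' Ids without an alias entry pass through unchanged.
#'
#' @param ids character vector of growth-factor ids.
#' @return character vector of canonical ids.
#' @export
resolve_gf_alias <- function(ids) {
  key <- toupper(ids)
  hit <- key %in% names(GF_ALIASES)
  ids[hit] <- unname(GF_ALIASES[key[hit]])
  ids
}

#' The default growth-factor panel
#'
#' Eleven glioma-associated growth factors at 1 ng/mL plus the two basal
#' factors EGF and bFGF at 5 ng/mL. Concentrations are carried as metadata
#' only; no computation depends on them.
#'
#' @return a data.frame with columns `id`, `name`, `concentration` (ng/mL)
#'   and `is_basal`.
#' @examples
#' gf_panel()
#' @export
gf_panel <- function() {
  data.frame(
    id = c("EGF", "bFGF",
           "IGF1", "NRG-1", "HGF", "PDGF", "PlGF", "PEDF", "Sema3A",
           "TGF-\u03b2", "IL-6", "SHH", "MDK"),
    name = c("epidermal growth factor", "basic fibroblast growth factor",
             "insulin-like growth factor 1", "neuregulin 1",
             "hepatocyte growth factor", "platelet-derived growth factor",
             "placental growth factor", "pigment epithelium-derived factor",
             "semaphorin 3A", "transforming growth factor beta",
             "interleukin 6", "sonic hedgehog", "midkine"),
    concentration = c(5, 5, rep(1, 11)),
    is_basal = c(TRUE, TRUE, rep(FALSE, 11)),
    stringsAsFactors = FALSE
  )
}

# Case-insensitive, locale-independent alphabetical order of GF ids.
canonical_gf_order <- function(ids) {
  ids <- enc2utf8(ids)
  ids[order(tolower(ids), method = "radix")]
}

#' Canonical label of a screen condition
#'
#' Factors are listed in case-insensitive alphabetical order, joined by `/`,
#' with an `/E&F` suffix when the basal supplement is present. The two
#' controls are labelled `NO_GF` and `NBE`. Labels round-trip through
#' [parse_condition_label()].
#'
#' @param factors character vector of non-basal growth-factor ids
#'   (length 0, 1 or 2).
#' @param with_ef logical; is EGF + bFGF included?
#' @return a single label string.
#' @examples
#' canonical_label(c("PEDF", "MDK"), with_ef = TRUE)  # "MDK/PEDF/E&F"
#' canonical_label(character(0), with_ef = TRUE)      # "NBE"
#' @export
canonical_label <- function(factors, with_ef) {
  stopifnot(is.logical(with_ef), length(with_ef) == 1L)
  factors <- resolve_gf_alias(as.character(factors))
  if (length(factors) == 0L) {
    return(if (with_ef) NBE_ID else NO_GF_ID)
  }
  if (anyDuplicated(factors)) {
    stop_gfscan("condition factors must be distinct")
  }
  parts <- canonical_gf_order(factors)
  if (with_ef) parts <- c(parts, EF_SUFFIX)
  paste(parts, collapse = "/")
}

#' Parse a condition label back into its parts
#'
#' Inverse of [canonical_label()]; ASCII aliases in factor names are honoured.
#'
#' @param label a condition label string.
#' @return a list with `factors` (character), `with_ef` (logical) and `kind`.
#' @export
parse_condition_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (label == NO_GF_ID) {
    return(list(factors = character(0), with_ef = FALSE, kind = "control_no_gf"))
  }
  if (label == NBE_ID) {
    return(list(factors = character(0), with_ef = TRUE, kind = "control_nbe"))
  }
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  with_ef <- identical(parts[length(parts)], EF_SUFFIX)
  if (with_ef) parts <- parts[-length(parts)]
  parts <- resolve_gf_alias(parts)
  if (length(parts) < 1L || length(parts) > 2L || anyDuplicated(parts)) {
    stop_gfscan(sprintf("malformed condition label: '%s'", label))
  }
  list(factors = canonical_gf_order(parts), with_ef = with_ef,
       kind = if (length(parts) == 1L) "single" else "pair")
}

#' Enumerate the full condition catalog of a growth-factor panel
#'
#' For m non-basal factors the catalog holds all C(m, 2) unordered pairs and
#' all m singles, each with and without the E&F basal supplement
#' (2 * (C(m, 2) + m) non-control conditions), plus the two controls `NO_GF`
#' (basal media, no growth factor) and `NBE` (E&F only). With the default
#' 11-factor panel this yields the screen's 132 + 2 conditions.
#'
#' @param panel a growth-factor panel data.frame as returned by [gf_panel()];
#'   must contain exactly two basal factors (EGF and bFGF) and unique ids.
#' @return an object of class `condition_catalog`: a list with
#'   * `conditions`: data.frame (`condition_id`, `factor_1`, `factor_2`,
#'     `with_ef`, `kind`),
#'   * `ef_pairing`: named character vector mapping each without-E&F
#'     non-control condition id to its with-E&F twin,
#'   * `panel`: the input panel.
#' @examples
#' cat132 <- enumerate_conditions(gf_panel())
#' sum(!cat132$conditions$kind %in% c("control_no_gf", "control_nbe"))  # 132
#' @export
enumerate_conditions <- function(panel = gf_panel()) {
  stopifnot(is.data.frame(panel),
            all(c("id", "is_basal") %in% names(panel)))
  panel$id <- resolve_gf_alias(panel$id)
  if (anyDuplicated(panel$id)) {
    stop_gfscan("duplicate growth-factor id in panel")
  }
  if (sum(panel$is_basal) != 2L) {
    stop_gfscan("panel must contain exactly 2 basal factors (EGF, bFGF)")
  }
  if (any(panel$concentration %||% 1 <= 0)) {
    stop_gfscan("growth-factor concentrations must be positive")
  }
  gfs <- canonical_gf_order(panel$id[!panel$is_basal])
  m <- length(gfs)

  singles <- if (m > 0) lapply(gfs, function(g) g) else list()
  pairs <- if (m >= 2) {
    cmb <- combn(gfs, 2, simplify = FALSE)
    lapply(cmb, canonical_gf_order)
  } else {
    list()
  }
  sets <- c(singles, pairs)

  rows <- list(
    data.frame(condition_id = NO_GF_ID, factor_1 = NA_character_,
               factor_2 = NA_character_, with_ef = FALSE,
               kind = "control_no_gf", stringsAsFactors = FALSE),
    data.frame(condition_id = NBE_ID, factor_1 = NA_character_,
               factor_2 = NA_character_, with_ef = TRUE,
               kind = "control_nbe", stringsAsFactors = FALSE)
  )
  pairing <- character(0)
  for (fs in sets) {
    kind <- if (length(fs) == 1L) "single" else "pair"
    id_plain <- canonical_label(fs, with_ef = FALSE)
    id_ef <- canonical_label(fs, with_ef = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      condition_id = c(id_plain, id_ef),
      factor_1 = fs[1], factor_2 = if (length(fs) == 2L) fs[2] else NA_character_,
      with_ef = c(FALSE, TRUE), kind = kind, stringsAsFactors = FALSE)
    pairing[id_plain] <- id_ef
  }
  conditions <- do.call(rbind, rows)
  rownames(conditions) <- NULL
  if (anyDuplicated(conditions$condition_id)) {
    stop_gfscan("internal error: duplicate condition labels in catalog")
  }
  structure(list(conditions = conditions, ef_pairing = pairing, panel = panel),
            class = "condition_catalog")
}

#' @export
print.condition_catalog <- function(x, ...) {
  n_nc <- sum(!x$conditions$kind %in% c("control_no_gf", "control_nbe"))
  cat(sprintf(
    "condition_catalog: %d conditions (%d non-control: %d singles, %d pairs, each +/- E&F) + 2 controls\n",
    nrow(x$conditions), n_nc,
    sum(x$conditions$kind == "single") / 2,
    sum(x$conditions$kind == "pair") / 2))
  invisible(x)
}

#' Non-control condition ids of a catalog
#'
#' @param catalog a `condition_catalog`.
#' @param with_ef optional logical filter on the E&F flag.
#' @return character vector of condition ids.
#' @export
screen_conditions <- function(catalog, with_ef = NULL) {
  cond <- catalog$conditions
  keep <- !cond$kind %in% c("control_no_gf", "control_nbe")
  if (!is.null(with_ef)) keep <- keep & cond$with_ef == with_ef
  cond$condition_id[keep]
}

#' Deterministic 384-well plate layout for a catalog
#'
#' Assigns every condition x replicate to a well of one or more 384-well
#' plates (rows A-P, columns 1-24), filling row-major in catalog order with
#' replicates adjacent. 134 conditions in duplicate occupy 268 wells of a
#' single plate.
#'
#' @param catalog a `condition_catalog`.
#' @param n_replicates number of technical replicates per condition (>= 1).
#' @return data.frame with columns `plate`, `well` (e.g. "A01"),
#'   `condition_id`, `replicate`.
#' @export
plate_layout <- function(catalog, n_replicates = 2L) {
  stopifnot(inherits(catalog, "condition_catalog"),
            n_replicates >= 1L, n_replicates == as.integer(n_replicates))
  ids <- catalog$conditions$condition_id
  n <- length(ids) * n_replicates
  idx <- seq_len(n) - 1L
  plate <- idx %/% 384L + 1L
  pos <- idx %% 384L
  row <- pos %/% 24L + 1L
  col <- pos %% 24L + 1L
  data.frame(
    plate = plate,
    well = sprintf("%s%02d", LETTERS[row], col),
    condition_id = rep(ids, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(ids)),
    stringsAsFactors = FALSE
  )
}
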