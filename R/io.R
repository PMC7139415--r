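# Readers and writers for the pipeline's TSV / GMT interchange formats.
# All files are UTF-8 TSV; '#'-prefixed header comments are skipped on read
# and written by the pipeline to stamp outputs with version and config hash.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_gfscan(sprintf("%s file not found: %s", what, path))
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   encoding = "UTF-8")
  for (nm in names(df)) {
    if (is.character(df[[nm]])) df[[nm]] <- enc2utf8(df[[nm]])
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_gfscan(sprintf("%s file %s lacks column(s): %s", what, path,
                        paste(missing, collapse = ", ")))
  }
  df
}

write_tsv_stamped <- function(df, path, comment = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

output_stamp <- function(config = NULL) {
  hash <- fnv1a_hash(paste(deparse(config), collapse = ""))
  sprintf("gfscan %s; config_hash=%s",
          as.character(packageVersion("gfscan")), hash)
}

#' Read a plate readout table
#'
#' Expects UTF-8 TSV columns `sample_id`, `condition_id`, `replicate`,
#' `role` (D0/D6/N6), `lum`; ASCII growth-factor aliases in condition ids
#' (e.g. `TGFB`) are resolved. Malformed rows (unknown role, negative
#' luminescence, duplicate keys) raise errors naming the row.
#'
#' @param path file path.
#' @return validated readout data.frame.
#' @export
read_readouts <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "condition_id", "replicate",
                                 "role", "lum"), "readout")
  df$condition_id <- normalize_condition_ids(df$condition_id)
  df$replicate <- as.integer(df$replicate)
  df$lum <- as.numeric(df$lum)
  validate_readouts(df)
  df
}

# Re-canonicalise condition labels (alias resolution + ordering); controls
# pass through.
normalize_condition_ids <- function(ids) {
  u <- unique(ids)
  mapped <- vapply(u, function(lbl) {
    parts <- parse_condition_label(lbl)
    canonical_label(parts$factors, parts$with_ef)
  }, character(1))
  unname(mapped[match(ids, u)])
}

#' @rdname read_readouts
#' @param readouts readout table to write.
#' @export
write_readouts <- function(readouts, path) {
  write_tsv_stamped(readouts, path)
}

#' Read / write a sample annotation table
#'
#' TSV with `sample_id`, `diagnosis` and logical flag columns (`TRUE`/`FALSE`).
#'
#' @param path file path.
#' @return annotation data.frame with logical mutation columns.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "diagnosis"), "annotation")
  if (anyDuplicated(df$sample_id)) {
    stop_gfscan(sprintf("duplicate sample_id '%s' in %s",
                        df$sample_id[duplicated(df$sample_id)][1], path))
  }
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v) && all(v %in% c("TRUE", "FALSE", "NA"))) {
      df[[nm]] <- as.logical(v)
    }
  }
  df
}

#' @rdname read_annotations
#' @param annotations annotation table to write.
#' @export
write_annotations <- function(annotations, path) {
  write_tsv_stamped(annotations, path)
}

#' Read / write an expression matrix
#'
#' TSV with gene ids in the first column (`gene`) and one column per sample,
#' values on the log2(RPKM + 1) scale.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path, "gene", "expression")
  if (anyDuplicated(df$gene)) {
    stop_gfscan(sprintf("duplicate gene id '%s' in %s",
                        df$gene[duplicated(df$gene)][1], path))
  }
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  validate_expression(m)
  m
}

#' @rdname read_expression
#' @param e expression matrix to write.
#' @export
write_expression <- function(e, path) {
  df <- data.frame(gene = rownames(e), e, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_stamped(df, path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors (set name -> members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_gfscan(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop_gfscan(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop_gfscan(sprintf("GMT set '%s' (line %d) has no members", parts[1], i))
    }
    sets[[parts[1]]] <- members
  }
  if (anyDuplicated(names(sets))) stop_gfscan("duplicate set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene sets to write.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read / write a condition catalog
#'
#' TSV with columns `condition_id`, `factor_1`, `factor_2`, `with_ef`,
#' `kind`. Reading rebuilds the E&F pairing from the rows.
#'
#' @param path file path.
#' @param panel growth-factor panel to attach (default [gf_panel()]).
#' @return a `condition_catalog`.
#' @export
read_catalog <- function(path, panel = gf_panel()) {
  df <- read_tsv_checked(path, c("condition_id", "factor_1", "factor_2",
                                 "with_ef", "kind"), "catalog")
  df$condition_id <- normalize_condition_ids(df$condition_id)
  df$with_ef <- as.logical(df$with_ef)
  for (col in c("factor_1", "factor_2")) {
    not_na <- !is.na(df[[col]]) & df[[col]] != "NA"
    df[[col]][!not_na] <- NA_character_
    df[[col]][not_na] <- resolve_gf_alias(df[[col]][not_na])
  }
  nc <- df[!df$kind %in% c("control_no_gf", "control_nbe"), ]
  plain <- nc$condition_id[!nc$with_ef]
  pairing <- setNames(
    vapply(plain, function(id) {
      parts <- parse_condition_label(id)
      canonical_label(parts$factors, with_ef = TRUE)
    }, character(1)),
    plain)
  if (!all(pairing %in% df$condition_id)) {
    stop_gfscan("catalog is missing with-E&F twins for some conditions")
  }
  structure(list(conditions = df, ef_pairing = pairing, panel = panel),
            class = "condition_catalog")
}

#' @rdname read_catalog
#' @param catalog a `condition_catalog` to write.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv_stamped(catalog$conditions, path)
}

#' Write a growth index matrix (plus QC report)
#'
#' @param m a `growth_index_matrix`.
#' @param path output TSV (samples x conditions); the QC well report is
#'   written next to it with suffix `.qc.tsv` unless `qc_path` is given.
#' @param qc_path optional explicit path for the QC report.
#' @param comment optional header comment (version/config stamp).
#' @export
write_index_matrix <- function(m, path, qc_path = NULL, comment = NULL) {
  df <- data.frame(sample_id = m$samples, m$index, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_stamped(df, path, comment)
  qc_path <- qc_path %||% sub("\\.tsv$", ".qc.tsv", path)
  write_tsv_stamped(m$qc, qc_path, comment)
  invisible(path)
}

#' Read a growth index matrix written by [write_index_matrix()]
#'
#' @param path the index TSV.
#' @return a `growth_index_matrix` with index values only (rates and QC
#'   provenance are not round-tripped).
#' @export
read_index_matrix <- function(path) {
  df <- read_tsv_checked(path, "sample_id", "index matrix")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  colnames(m) <- normalize_condition_ids(colnames(m))
  storage.mode(m) <- "double"
  structure(list(index = m, rate = NULL, qc_pass = !is.na(m),
                 n_replicates = NULL, n6 = NULL, qc = NULL,
                 samples = rownames(m), conditions = colnames(m)),
            class = "growth_index_matrix")
}
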