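# Subgroup filter expressions.
#
# Subgroups of a cohort are selected with a tiny boolean expression language
# over the logical columns of the sample annotation table, e.g.
# "idh1_mut & !codel_1p19q". Grammar (precedence low to high):
#
#   expr   := term ('|' term)*
#   term   := factor ('&' factor)*
#   factor := '!' factor | '(' expr ')' | identifier
#
# Identifiers are annotation column names ([A-Za-z0-9_.]+) and must refer to
# logical columns. The parser is a hand-written recursive descent; no host
# language eval is involved.

tokenize_filter <- function(expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  out <- character(0)
  i <- 1L
  chars <- strsplit(expr, "")[[1]]
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("!", "&", "|", "(", ")")) {
      out <- c(out, ch)
      i <- i + 1L
    } else if (grepl("^[A-Za-z0-9_.]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_.]$", chars[j])) j <- j + 1L
      out <- c(out, paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    } else {
      stop_gfscan(sprintf("unexpected character '%s' in filter '%s'", ch, expr))
    }
  }
  out
}

#' Parse a subgroup filter expression
#'
#' Compiles a boolean expression over logical annotation columns (operators
#' `!`, `&`, `|` and parentheses) into a predicate function.
#'
#' @param expr filter string, e.g. `"idh1_mut & !codel_1p19q"`.
#' @return a function taking an annotation data.frame and returning a logical
#'   vector (one element per row).
#' @examples
#' f <- parse_subgroup_filter("idh1_mut & !codel_1p19q")
#' f(data.frame(idh1_mut = c(TRUE, TRUE), codel_1p19q = c(FALSE, TRUE)))
#' @export
parse_subgroup_filter <- function(expr) {
  tokens <- tokenize_filter(expr)
  if (length(tokens) == 0L) stop_gfscan("empty filter expression")
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok)) stop_gfscan(sprintf("unexpected end of filter '%s'", expr))
    if (tok == "!") {
      advance()
      inner <- parse_factor()
      return(function(ann) !inner(ann))
    }
    if (tok == "(") {
      advance()
      inner <- parse_expr()
      if (!identical(peek(), ")")) {
        stop_gfscan(sprintf("missing ')' in filter '%s'", expr))
      }
      advance()
      return(inner)
    }
    if (tok %in% c("&", "|", ")")) {
      stop_gfscan(sprintf("unexpected '%s' in filter '%s'", tok, expr))
    }
    advance()
    col <- tok
    function(ann) {
      if (!col %in% names(ann)) {
        stop_gfscan(sprintf("filter references unknown annotation column '%s'", col))
      }
      v <- ann[[col]]
      if (!is.logical(v)) {
        stop_gfscan(sprintf("filter column '%s' is not logical", col))
      }
      v & !is.na(v)
    }
  }
  parse_term <- function() {
    lhs <- parse_factor()
    while (identical(peek(), "&")) {
      advance()
      rhs <- parse_factor()
      lhs <- local({
        l <- lhs; r <- rhs
        function(ann) l(ann) & r(ann)
      })
    }
    lhs
  }
  parse_expr <- function() {
    lhs <- parse_term()
    while (identical(peek(), "|")) {
      advance()
      rhs <- parse_term()
      lhs <- local({
        l <- lhs; r <- rhs
        function(ann) l(ann) | r(ann)
      })
    }
    lhs
  }
  fn <- parse_expr()
  if (!is.na(peek())) {
    stop_gfscan(sprintf("trailing tokens in filter '%s'", expr))
  }
  fn
}

# Resolve a subgroup argument (NULL, filter string, logical vector or
# character vector of sample ids) to a character vector of sample ids.
resolve_subgroup <- function(subgroup, annotations, all_samples) {
  if (is.null(subgroup)) return(all_samples)
  if (is.function(subgroup)) {
    stopifnot(!is.null(annotations))
    return(annotations$sample_id[subgroup(annotations)])
  }
  if (is.logical(subgroup)) {
    stopifnot(length(subgroup) == length(all_samples))
    return(all_samples[subgroup])
  }
  if (is.character(subgroup) && length(subgroup) == 1L &&
      !subgroup %in% all_samples) {
    if (is.null(annotations)) {
      stop_gfscan("a filter-string subgroup needs the annotation table")
    }
    f <- parse_subgroup_filter(subgroup)
    return(annotations$sample_id[f(annotations)])
  }
  as.character(subgroup)
}
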