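# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring global RNG state
#'
#' All randomised operations in the package take an explicit `seed` argument
#' and run through this helper, so no call mutates the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash of a character scalar; used to stamp pipeline
# outputs with a short configuration fingerprint without adding a digest
# dependency. Arithmetic stays below 2^53 so the result is exact.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 17
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

stop_gfscan <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_gfscan(sprintf("'%s' must be a probability in [0, 1]", name))
  }
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two labelings of the same samples, corrected for chance;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#' Used to compare recovered EGF/bFGF-dependency groups against planted truth.
#'
#' @param a,b vectors of cluster/group labels of equal length.
#' @return a single number in [-1, 1].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(ifelse(sum_ij == expected, 1, 0))
  }
  (sum_ij - expected) / (max_index - expected)
}
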