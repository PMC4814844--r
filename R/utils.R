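`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so seeded helpers do not disturb an outer
#' random stream. With `seed = NULL` the expression runs on the current
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("%s must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, minimum = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < minimum || x != floor(x))
    stop(sprintf("%s must be a single integer >= %s", name, format(minimum)),
         call. = FALSE)
  invisible(as.integer(x))
}

## 0-based half-open interval helpers -----------------------------------

iv_check <- function(x, name, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(NULL)
    stop(name, " must be supplied", call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
      any(x != floor(x)) || x[1] >= x[2])
    stop(name, " must be an integer interval c(start, end) with start < end ",
         "(0-based, half-open)", call. = FALSE)
  as.integer(x)
}

iv_within <- function(a, b) a[1] >= b[1] && a[2] <= b[2]

iv_disjoint <- function(a, b) a[2] <= b[1] || b[2] <= a[1]

iv_overlaps <- function(a, b) !iv_disjoint(a, b)

## DNA helpers -----------------------------------------------------------

check_dna <- function(seq, name = "seq", min_len = 1L) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(name, " must be a single character string", call. = FALSE)
  s <- toupper(seq)
  if (nchar(s) < min_len)
    stop(name, " must have at least ", min_len, " bases", call. = FALSE)
  if (grepl("[^ACGT]", s))
    stop(name, " may only contain A, C, G, T (ambiguity codes rejected)",
         call. = FALSE)
  s
}

revcomp_chr <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}
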