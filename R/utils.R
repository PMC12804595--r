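#' Derive a reproducible child seed
#'
#' Every stochastic component of the framework draws its seed from a single
#' top-level seed through this function, so that a whole pipeline is
#' reproducible from one integer while components stay independent.
#' The derivation is a polynomial rolling hash of the key
#' `paste(seed, ..., sep = ":")` modulo 2^31 - 1.
#'
#' @param seed Integer top-level seed.
#' @param ... Component labels (strings or integers), e.g.
#'   `derive_seed(1, "layer", 2, "unit", 3)`.
#' @return A positive integer strictly below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = ":")
  h <- 0
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h + 1L)
}

# Evaluate expr under a temporary RNG state; the caller's RNG is untouched.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}

stop_cffat <- function(...) stop(sprintf(...), call. = FALSE)

check_matrix <- function(X, name = "X") {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop_cffat("%s must be a numeric matrix", name)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop_cffat("%s contains missing or non-finite values", name)
  }
  invisible(X)
}

# Uniform-random fold assignment: n row labels in 1..k, sizes as equal as
# possible, permuted under `seed`.
assign_folds <- function(n, k, seed) {
  base <- rep_len(seq_len(k), n)
  with_seed(seed, base[sample.int(n)])
}
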