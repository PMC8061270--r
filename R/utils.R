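#' Derive a reproducible sub-stream seed
#'
#' All stochastic routines in the package take one integer seed and derive
#' independent sub-stream seeds from it, so a single top-level seed fixes an
#' entire analysis. The derivation is a fixed affine map modulo 2^31 - 1,
#' keeping every derived seed a valid 32-bit R integer.
#'
#' @param seed integer master seed.
#' @param offset integer sub-stream index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  as.integer((abs(seed) %% m + 104729 * (offset %% 20011) + 7) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_popland <- function(...) stop(sprintf(...), call. = FALSE)

# upper-triangle index pairs (i < j) for k items
pair_index <- function(k) {
  if (k < 2) return(matrix(integer(0), ncol = 2))
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Construct a permutation-test result
#'
#' Container for an observed statistic, its permutation null sample and the
#' add-one p-value. The add-one rule, p = (1 + #{null at least as extreme}) /
#' (1 + n_perm), guarantees p > 0 and exact validity under exchangeability.
#'
#' @param observed observed statistic (scalar).
#' @param null_values numeric vector of null replicates.
#' @param tail one of "upper", "lower", "two-sided".
#' @param seed seed used to generate the null.
#' @param null_model text descriptor of the null model.
#' @return an object of class `perm_result` with elements `observed`,
#'   `null_values`, `p_value`, `n_perm`, `tail`, `seed`, `null_model`.
#' @export
perm_result <- function(observed, null_values, tail = c("upper", "lower", "two-sided"),
                        seed = NA_integer_, null_model = "unspecified") {
  tail <- match.arg(tail)
  stopifnot(length(observed) == 1L, is.numeric(null_values), length(null_values) >= 1L)
  n <- length(null_values)
  p_up <- (1 + sum(null_values >= observed)) / (1 + n)
  p_lo <- (1 + sum(null_values <= observed)) / (1 + n)
  p <- switch(tail,
    upper = p_up,
    lower = p_lo,
    `two-sided` = min(1, 2 * min(p_up, p_lo))
  )
  structure(
    list(observed = observed, null_values = null_values, p_value = p,
         n_perm = n, tail = tail, seed = seed, null_model = null_model),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s null, %s tail)\n", x$null_model, x$tail))
  cat(sprintf("  observed = %.6g, n_perm = %d, p = %.4g\n",
              x$observed, x$n_perm, x$p_value))
  invisible(x)
}

#' Write a permutation result to JSON
#'
#' @param x a `perm_result`.
#' @param path output file.
#' @param keep_null persist the full null vector (default TRUE).
#' @export
write_perm_result <- function(x, path, keep_null = TRUE) {
  stopifnot(inherits(x, "perm_result"))
  out <- x[c("observed", "p_value", "n_perm", "tail", "seed", "null_model")]
  if (keep_null) out$null_values <- x$null_values
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
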