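#' Logistic (sigmoid) function
#'
#' Numerically stable logistic used by the conditional distributions of the
#' restricted Boltzmann machine.
#'
#' @param x numeric vector or matrix.
#' @return values of `1 / (1 + exp(-x))` with the same shape as `x`.
#' @keywords internal
sigmoid <- function(x) {
  # plogis is the stable base-R logistic; keeps shapes (incl. matrices)
  out <- stats::plogis(x)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. seed = NULL leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Derive a reproducible child seed from a base seed; stays below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}

stop_if_not_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  invisible(m)
}

check_symmetric <- function(m, tol = 1e-8) {
  isTRUE(max(abs(m - t(m))) <= tol)
}
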