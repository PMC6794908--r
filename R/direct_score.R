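#' Project the structural template onto the target length
#'
#' Bilinearly resizes the template weight matrix to `target_length` x
#' `target_length` using the same continuous-index convention as
#' [resize_distance_matrix()], symmetrises, clips to [0, 1] and zeroes the
#' diagonal. Predictions are reported in target coordinates, so the template
#' is brought to the target rather than the reverse.
#'
#' @param w template weight matrix (entries in [0, 1]).
#' @param target_length number of nucleotides in the target RNA (>= 2).
#' @return `target_length` x `target_length` weight matrix.
#' @export
project_weight <- function(w, target_length) {
  stop_if_not_square(w, "template weight")
  if (target_length < 2L) stop("invalid length", call. = FALSE)
  out <- if (nrow(w) == target_length) unname(as.matrix(w)) else
    resize_distance_matrix(unclass(as.matrix(w)), target_length)
  out <- (out + t(out)) / 2
  out[out < 0] <- 0
  out[out > 1] <- 1
  diag(out) <- 0
  out
}

#' Reweight coupling scores by the structural template
#'
#' The combined score is `DIRECT(i, j) = DI(i, j) * w(i, j)^exponent`, with
#' the squared template weight as the default: the second power balances the
#' sequence-coevolution and structural-template contributions (powers 1-4 are
#' supported).
#'
#' @param di symmetric direct-information matrix (L x L).
#' @param w_projected projected template weight of the same size.
#' @param exponent power applied to the weight (default 2).
#' @return symmetric score matrix.
#' @export
direct_reweight <- function(di, w_projected, exponent = 2L) {
  if (!all(dim(di) == dim(w_projected))) stop("dimension error", call. = FALSE)
  unclass(as.matrix(di)) * unclass(as.matrix(w_projected))^exponent
}

#' Rank candidate contacts from a score matrix
#'
#' Upper-triangle pairs separated by more than `min_separation` nucleotides,
#' sorted by descending score; ties broken deterministically by smaller `i`,
#' then smaller `j`. Output is 1-based with `i < j`.
#'
#' @param scores symmetric score matrix.
#' @param min_separation sequence-separation filter (pairs with
#'   `|i - j| <= min_separation` are excluded; default 4).
#' @param top_n keep this many top pairs (`Inf` = all).
#' @param scheme label recorded on the result (`"DI"` or `"DIRECT"`).
#' @return a `scored_contacts` tibble with columns `i`, `j`, `score`.
#' @export
rank_contacts <- function(scores, min_separation = 4L, top_n = Inf,
                          scheme = "DIRECT") {
  stop_if_not_square(scores, "score matrix")
  L <- nrow(scores)
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) > min_separation
  idx <- idx[keep, , drop = FALSE]
  s <- scores[idx]
  ord <- order(-s, idx[, 1], idx[, 2])
  n <- min(length(ord), top_n)
  ord <- ord[seq_len(n)]
  out <- tibble::tibble(i = as.integer(idx[ord, 1]),
                        j = as.integer(idx[ord, 2]),
                        score = as.numeric(s[ord]))
  attr(out, "scheme") <- scheme
  attr(out, "min_separation") <- as.integer(min_separation)
  class(out) <- c("scored_contacts", class(out))
  out
}

#' Score contacts of a target RNA with the DIRECT scheme
#'
#' Convenience wrapper: computes DI from the alignment, projects the template
#' weight to the alignment length, applies the reweighting and ranks.
#'
#' @param msa an `msa` for the target family.
#' @param template a `template_weight` (or any weight matrix); `NULL` gives
#'   the unweighted DI ranking.
#' @param exponent template power (default 2).
#' @param min_separation tertiary-contact separation filter.
#' @param top_n ranked pairs to keep.
#' @param ... forwarded to [dca()].
#' @return list with `contacts` (a `scored_contacts` tibble), `di`,
#'   `weight_projected`.
#' @export
direct_predict <- function(msa, template = NULL, exponent = 2L,
                           min_separation = 4L, top_n = 100L, ...) {
  res <- dca(msa, ...)
  L <- nrow(res$di)
  if (is.null(template)) {
    wp <- matrix(1, L, L)
    scores <- unclass(as.matrix(res$di))
    scheme <- "DI"
  } else {
    wp <- project_weight(template, L)
    scores <- direct_reweight(res$di, wp, exponent)
    scheme <- "DIRECT"
  }
  list(contacts = rank_contacts(scores, min_separation, top_n, scheme = scheme),
       di = res$di, weight_projected = wp)
}
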