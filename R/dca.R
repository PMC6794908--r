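# Mean-field direct coupling analysis over the 5-letter nucleotide alphabet
# (A, C, G, U, gap). The gap is the 5th state and serves as the gauge state:
# it is dropped when the connected-correlation matrix is built and carries
# zero couplings/fields.

DCA_ALPHABET <- c("A", "C", "G", "U", "-")
DCA_Q <- 5L

msa_to_int <- function(msa) {
  m <- as.matrix(msa)
  out <- matrix(match(m, DCA_ALPHABET), nrow(m), ncol(m))
  if (anyNA(out)) stop("alignment contains symbols outside A/C/G/U/-", call. = FALSE)
  out
}

#' Remove heavily gapped sequences from an alignment
#'
#' Rows whose gap fraction strictly exceeds `max_gap_fraction` (default 50%)
#' are dropped before coupling analysis; a row with exactly the threshold
#' fraction is retained. Columns are never filtered.
#'
#' @param msa an `msa`.
#' @param max_gap_fraction maximum tolerated per-row gap fraction.
#' @return the filtered `msa`.
#' @export
preprocess_msa <- function(msa, max_gap_fraction = 0.5) {
  stopifnot(inherits(msa, "msa"))
  gapfrac <- vapply(strsplit(msa$rows, "", fixed = TRUE),
                    function(ch) mean(ch == "-"), numeric(1))
  keep <- gapfrac <= max_gap_fraction
  if (!any(keep)) stop("empty after filtering: all rows exceed the gap threshold",
                       call. = FALSE)
  new_msa(msa$ids[keep], msa$rows[keep])
}

#' Sequence reweighting by neighbourhood density
#'
#' Standard redundancy correction: the weight of a sequence is the reciprocal
#' of the number of alignment rows (itself included) with fractional identity
#' at least `identity_threshold` to it. The sum of weights is the effective
#' sequence number.
#'
#' @param msa an `msa` (already gap-filtered).
#' @param identity_threshold similarity level defining a neighbour.
#' @return numeric weight per row, with attribute `n_effective`.
#' @export
sequence_weights <- function(msa, identity_threshold = 0.8) {
  X <- msa_to_int(msa)
  n <- nrow(X); L <- ncol(X)
  # one-hot trick: pairwise identical-position counts = M M'
  M <- matrix(0, n, L * DCA_Q)
  M[cbind(rep(seq_len(n), L), (rep(seq_len(L), each = n) - 1L) * DCA_Q + as.vector(X))] <- 1
  sim <- tcrossprod(M) / L
  w <- 1 / rowSums(sim >= identity_threshold)
  attr(w, "n_effective") <- sum(w)
  w
}

#' Pseudocounted, reweighted frequency model
#'
#' Weighted empirical single-column and column-pair frequencies over the five
#' states, mixed with the uniform distribution:
#' `f = (1 - lambda) f_emp + lambda / q` for singles and `lambda / q^2` for
#' pairs. Self-pair joints are kept diagonal-consistent
#' (`f_ii(A, B) = delta(A, B) f_i(A)`). Pair marginals reproduce the single
#' frequencies exactly by construction.
#'
#' @param msa an `msa`.
#' @param weights per-row weights (default: uniform).
#' @param pseudocount_weight mixing weight `lambda` in `[0, 1)`.
#' @return a `freq_model`: list with `f_single` (L x q), `f_pair`
#'   (L x L x q x q), `sequence_weights`, `n_effective`, `pseudocount_weight`.
#' @export
msa_frequencies <- function(msa, weights = NULL, pseudocount_weight = 0.5) {
  lam <- pseudocount_weight
  if (!is.numeric(lam) || lam < 0 || lam >= 1) {
    stop("invalid pseudocount: must be in [0, 1)", call. = FALSE)
  }
  X <- msa_to_int(msa)
  n <- nrow(X); L <- ncol(X); q <- DCA_Q
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n)
  neff <- sum(weights)
  M <- matrix(0, n, L * q)
  M[cbind(rep(seq_len(n), L), (rep(seq_len(L), each = n) - 1L) * q + as.vector(X))] <- 1
  f1_flat <- colSums(M * weights) / neff                  # L*q
  f2_flat <- crossprod(M * weights, M) / neff             # (L*q) x (L*q)
  f_single <- (1 - lam) * matrix(f1_flat, L, q, byrow = TRUE) + lam / q
  f_pair <- array(0, dim = c(L, L, q, q))
  for (a in seq_len(q)) for (b in seq_len(q)) {
    rows <- (seq_len(L) - 1L) * q + a
    cols <- (seq_len(L) - 1L) * q + b
    f_pair[, , a, b] <- (1 - lam) * f2_flat[rows, cols] + lam / q^2
  }
  # self-pairs: diagonal in the states, consistent with the singles
  for (i in seq_len(L)) {
    f_pair[i, i, , ] <- diag(f_single[i, ], q, q)
  }
  structure(list(f_single = f_single, f_pair = f_pair,
                 sequence_weights = weights, n_effective = neff,
                 pseudocount_weight = lam),
            class = "freq_model")
}

#' @export
print.freq_model <- function(x, ...) {
  cat("<freq_model>", nrow(x$f_single), "columns, q =", ncol(x$f_single),
      sprintf(", n_eff %.1f, pseudocount %.2f\n", x$n_effective,
              x$pseudocount_weight))
  invisible(x)
}

#' Mean-field couplings from the inverse correlation matrix
#'
#' Builds the connected-correlation matrix
#' `C_ij(A, B) = f_ij(A, B) - f_i(A) f_j(B)` over the first `q - 1` states
#' per column (gap-state gauge) and takes couplings as the negated inverse:
#' `e_ij(A, B) = -(C^-1)_ij(A, B)`. Couplings involving the gap state are
#' zero by gauge choice.
#'
#' @param fm a `freq_model`.
#' @return a `coupling_model`: list with `e` (L x L x q x q array, gap
#'   row/column zero), `L`, `q`.
#' @export
mean_field_couplings <- function(fm) {
  stopifnot(inherits(fm, "freq_model"))
  L <- nrow(fm$f_single); q <- DCA_Q; r <- q - 1L
  C <- matrix(0, L * r, L * r)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    block <- fm$f_pair[i, j, 1:r, 1:r] -
      outer(fm$f_single[i, 1:r], fm$f_single[j, 1:r])
    C[((i - 1) * r + 1):(i * r), ((j - 1) * r + 1):(j * r)] <- block
  }
  invC <- tryCatch(solve(C), error = function(e)
    stop("pseudocount too small / alignment degenerate: correlation matrix is singular",
         call. = FALSE))
  e <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    e[i, j, 1:r, 1:r] <- -invC[((i - 1) * r + 1):(i * r),
                               ((j - 1) * r + 1):(j * r)]
  }
  structure(list(e = e, L = L, q = q), class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat("<coupling_model>", x$L, "columns, q =", x$q, "\n")
  invisible(x)
}

# iterative proportional fit of the two-site fields; W = exp(e_ij) (q x q)
two_site_fit <- function(W, fi, fj, tol = 1e-6, max_iter = 1000L) {
  q <- length(fi)
  mu1 <- rep(1 / q, q); mu2 <- rep(1 / q, q)
  for (it in seq_len(max_iter)) {
    nu1 <- fi / as.numeric(W %*% mu2);  mu1 <- nu1 / sum(nu1)
    nu2 <- fj / as.numeric(crossprod(W, mu1)); mu2 <- nu2 / sum(nu2)
    P <- W * outer(mu1, mu2)
    Z <- sum(P)
    P <- P / Z
    err <- max(abs(rowSums(P) - fi), abs(colSums(P) - fj))
    if (err < tol) {
      return(list(P = P, h_i = log(mu1), h_j = log(mu2), Z = Z,
                  iterations = it, marginal_error = err))
    }
  }
  stop("two-site fit failed to converge", call. = FALSE)
}

#' Isolated two-site model for one column pair
#'
#' Fits the local fields of `P_ij(A, B) = exp(e_ij(A, B) + h_i(A) + h_j(B)) / Z_ij`
#' by alternating proportional updates until both marginals match the
#' single-column frequencies within `tol`.
#'
#' @param cm a `coupling_model`.
#' @param fm the matching `freq_model`.
#' @param i,j column indices.
#' @param tol maximum allowed marginal mismatch.
#' @param max_iter iteration cap.
#' @return list with the joint `P` (q x q), fitted fields `h_i`, `h_j`,
#'   normaliser `Z`, `iterations`, `marginal_error`.
#' @export
fit_two_site <- function(cm, fm, i, j, tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(cm, "coupling_model"), inherits(fm, "freq_model"))
  two_site_fit(exp(cm$e[i, j, , ]), fm$f_single[i, ], fm$f_single[j, ],
               tol = tol, max_iter = max_iter)
}

#' Direct information of a fitted pair distribution
#'
#' `DI = sum_AB P(A, B) ln [P(A, B) / (f_i(A) f_j(B))]` — the mutual
#' information of the isolated two-site model against the independent product
#' of its marginals (natural log). Terms with `P(A, B) = 0` contribute zero.
#'
#' @param P joint distribution (q x q, sums to 1).
#' @param fi,fj marginal distributions.
#' @return scalar DI in nats.
#' @export
di_pair <- function(P, fi, fj) {
  ref <- outer(fi, fj)
  nz <- P > 0
  sum(P[nz] * log(P[nz] / ref[nz]))
}

#' Direct-information matrix
#'
#' Fits the isolated two-site model for every column pair and evaluates the
#' direct information. Symmetric, non-negative (up to float noise), zero
#' diagonal. All pairs are computed; the sequence-separation mask is applied
#' later at ranking time, keeping DI a pure function of the alignment.
#'
#' @param fm a `freq_model`.
#' @param cm the matching `coupling_model`.
#' @param tol,max_iter forwarded to the two-site fit.
#' @return a `di_matrix` (L x L numeric matrix).
#' @export
direct_information <- function(fm, cm, tol = 1e-6, max_iter = 1000L) {
  L <- cm$L
  di <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    fi <- fm$f_single[i, ]
    for (j in (i + 1L):L) {
      fit <- tryCatch(
        two_site_fit(exp(cm$e[i, j, , ]), fi, fm$f_single[j, ],
                     tol = tol, max_iter = max_iter),
        error = function(e) stop("two-site fit failed for pair (", i, ", ", j,
                                 "): ", conditionMessage(e), call. = FALSE))
      di[i, j] <- di[j, i] <- di_pair(fit$P, fi, fm$f_single[j, ])
    }
  }
  structure(di, class = c("di_matrix", class(di)))
}

#' @export
print.di_matrix <- function(x, ...) {
  cat("<di_matrix>", nrow(x), "x", ncol(x),
      sprintf("- max DI %.4f\n", max(x)))
  invisible(x)
}

#' Mean-field DCA in one call
#'
#' Chains the preprocessing, reweighting, frequency estimation, mean-field
#' inversion and direct-information steps with the standard defaults.
#'
#' @param msa an `msa`.
#' @param pseudocount pseudocount weight lambda.
#' @param reweight_threshold sequence-identity level for redundancy weights.
#' @param max_gap_fraction row gap-filter level.
#' @return list with `di` (a `di_matrix`), `frequencies`, `couplings`,
#'   `weights`, `n_effective`, `msa` (the filtered alignment).
#' @export
dca <- function(msa, pseudocount = 0.5, reweight_threshold = 0.8,
                max_gap_fraction = 0.5) {
  msa <- preprocess_msa(msa, max_gap_fraction)
  w <- sequence_weights(msa, reweight_threshold)
  fm <- msa_frequencies(msa, weights = w, pseudocount_weight = pseudocount)
  cm <- mean_field_couplings(fm)
  di <- direct_information(fm, cm)
  list(di = di, frequencies = fm, couplings = cm, weights = w,
       n_effective = attr(w, "n_effective"), msa = msa)
}
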