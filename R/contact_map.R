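#' Minimal heavy-atom distance matrix of a chain
#'
#' Entry (i, j) is the minimum Euclidean distance in Angstrom over all pairs
#' of heavy atoms, one from residue i and one from residue j. Symmetric with a
#' zero diagonal by construction.
#'
#' @param chain a `structure_chain` from [read_structure()].
#' @return numeric L x L matrix with residue labels `"number[insert]"` as
#'   dimnames.
#' @export
distance_matrix <- function(chain) {
  stopifnot(inherits(chain, "structure_chain"))
  L <- length(chain$residues)
  empty <- vapply(chain$residues, function(r) nrow(r$atoms) == 0L, logical(1))
  if (any(empty)) stop("empty residue: no heavy atoms", call. = FALSE)
  d <- matrix(0, L, L)
  coords <- lapply(chain$residues, function(r) r$atoms)
  for (i in seq_len(L)) {
    a <- coords[[i]]
    for (j in seq_len(L)) {
      if (j <= i) next
      b <- coords[[j]]
      # squared cross-distances between the two atom sets
      cross <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
      d[i, j] <- d[j, i] <- sqrt(max(0, min(cross)))
    }
  }
  labs <- vapply(chain$residues, function(r)
    paste0(r$number, ifelse(nzchar(r$insert) && r$insert != "", r$insert, "")),
    character(1))
  dimnames(d) <- list(labs, labs)
  d
}

#' Binary contact map from a distance matrix
#'
#' A pair is in contact when its minimal heavy-atom distance is strictly less
#' than `cutoff` (8 Angstrom by default; a distance of exactly 8 is a
#' non-contact) and the two positions are more than `min_separation`
#' nucleotides apart in sequence. Set `min_separation = 0` to keep the full
#' map including near-diagonal pairs, as used when building training maps for
#' the template machine; the tertiary-contact filter (`> 4` nt) is applied at
#' prediction and evaluation time.
#'
#' @param d symmetric distance matrix (Angstrom).
#' @param cutoff contact distance cutoff in Angstrom.
#' @param min_separation pairs with `|i - j| <= min_separation` are zeroed.
#' @return a `contact_map`: binary integer matrix with attributes `cutoff` and
#'   `min_separation`.
#' @examples
#' d <- matrix(10, 6, 6); d[1, 6] <- d[6, 1] <- 5; diag(d) <- 0
#' contact_map(d)[1, 6]
#' @export
contact_map <- function(d, cutoff = 8.0, min_separation = 4L) {
  stop_if_not_square(d, "distance matrix")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("invalid cutoff", call. = FALSE)
  }
  L <- nrow(d)
  m <- (d < cutoff) * 1L
  sep <- abs(row(m) - col(m))
  m[sep <= min_separation] <- 0L
  new_contact_map(m, cutoff = cutoff, min_separation = as.integer(min_separation))
}

new_contact_map <- function(m, cutoff = NA_real_, min_separation = 0L) {
  m <- unname(m)
  storage.mode(m) <- "integer"
  structure(m, cutoff = cutoff, min_separation = min_separation,
            class = c("contact_map", class(m)))
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map>", nrow(x), "x", ncol(x), "-", sum(x) / 2L, "contacts",
      if (!is.na(attr(x, "cutoff"))) paste0("(cutoff ", attr(x, "cutoff"),
                                            " A, min sep ",
                                            attr(x, "min_separation"), ")"),
      "\n")
  invisible(x)
}

#' Resize a distance matrix to a fixed template size
#'
#' Bilinear interpolation over the continuous index grid: source index
#' `i` in `1..L` corresponds to target coordinate `i * M / L`, so a target
#' pixel `t` samples the source at `t * L / M` (edges clamped). For an RNA of
#' 50 nucleotides resized to 100 x 100, a feature between nucleotides 1 and 4
#' therefore appears between target positions 2 and 8 — sequence separations
#' scale with the resize factor, which preserves the spatial pattern. The
#' result is symmetrised by averaging with its transpose. Resizing acts on
#' distances, not on the binary map: the contact cutoff is applied after.
#'
#' @param d square distance matrix (size >= 2).
#' @param target_size output size M (default 100).
#' @return target_size x target_size symmetric matrix.
#' @export
resize_distance_matrix <- function(d, target_size = 100L) {
  stop_if_not_square(d, "distance matrix")
  L <- nrow(d)
  M <- as.integer(target_size)
  if (L < 2L || M < 2L) stop("degenerate matrix: size must be >= 2", call. = FALSE)
  if (L == M) return(unname(d))
  s <- pmin(pmax(seq_len(M) * L / M, 1), L)
  rows <- t(apply(d, 1, function(r) approx(seq_len(L), r, xout = s, rule = 2)$y))
  out <- apply(rows, 2, function(col) approx(seq_len(L), col, xout = s, rule = 2)$y)
  (out + t(out)) / 2
}

# row-major ordering of the strict lower triangle: (2,1), (3,1), (3,2), ...
lower_tri_index <- function(M) {
  idx <- which(lower.tri(matrix(0, M, M)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Flatten a contact map to its lower-triangle bit vector
#'
#' The strict lower triangle is read in row-major order into a 0/1 vector of
#' length M(M-1)/2 — 4950 entries for the default 100 x 100 template — the
#' visible-layer encoding used to train the template machine.
#'
#' @param m square binary (symmetric) matrix.
#' @return integer 0/1 vector of length `M(M-1)/2`.
#' @export
flatten_map <- function(m) {
  stop_if_not_square(m, "contact map")
  idx <- lower_tri_index(nrow(m))
  as.integer(m[idx])
}

#' Rebuild a symmetric contact map from a flattened vector
#'
#' @param v 0/1 vector of length `M(M-1)/2`.
#' @param size map size M.
#' @return a `contact_map` (symmetric, zero diagonal).
#' @export
unflatten_map <- function(v, size) {
  M <- as.integer(size)
  if (length(v) != M * (M - 1L) / 2L) {
    stop("size mismatch: expected length ", M * (M - 1L) / 2L, call. = FALSE)
  }
  m <- matrix(0L, M, M)
  idx <- lower_tri_index(M)
  m[idx] <- as.integer(v)
  m <- m + t(m)
  new_contact_map(m)
}

#' Sequence-range class of a contact
#'
#' Contacts are binned by sequence separation `s = |i - j|`: `excluded`
#' (`s <= 4`, the pairs removed by the tertiary-contact filter), `short`
#' (5-12 nt), `medium` (13-24 nt), `long` (25+ nt).
#'
#' @param i,j 1-based positions (vectorised).
#' @return character vector in `{excluded, short, medium, long}`.
#' @export
classify_range <- function(i, j) {
  if (any(i == j)) stop("self pair", call. = FALSE)
  s <- abs(i - j)
  out <- rep("long", length(s))
  out[s <= 24] <- "medium"
  out[s <= 12] <- "short"
  out[s <= 4] <- "excluded"
  out
}

#' Secondary-structure category of a contact
#'
#' Given a nested secondary structure, each position pair falls in exactly one
#' category: `base_pair` (the pair is in the structure's pair list — checked
#' first so Watson-Crick pairs are never counted as stem-stem), `loop_loop`
#' (both unpaired), `stem_loop` (one paired, one unpaired), `intra_stem_stem`
#' (both in the same stem but not paired with each other), `inter_stem_stem`
#' (in different stems).
#'
#' @param i,j 1-based positions (vectorised, equal length).
#' @param ss a `secondary_structure`.
#' @return character vector of categories.
#' @export
classify_category <- function(i, j, ss) {
  stopifnot(inherits(ss, "secondary_structure"))
  n <- nchar(ss$dotbracket)
  if (any(i < 1 | i > n | j < 1 | j > n)) {
    stop("index out of range", call. = FALSE)
  }
  partner <- integer(n)
  if (nrow(ss$pairs) > 0L) {
    partner[ss$pairs[, 1]] <- ss$pairs[, 2]
    partner[ss$pairs[, 2]] <- ss$pairs[, 1]
  }
  sid <- ss$stem_id
  mapply(function(a, b) {
    if (partner[a] == b) return("base_pair")
    pa <- !is.na(sid[a]); pb <- !is.na(sid[b])
    if (!pa && !pb) return("loop_loop")
    if (xor(pa, pb)) return("stem_loop")
    if (sid[a] == sid[b]) "intra_stem_stem" else "inter_stem_stem"
  }, i, j, USE.NAMES = FALSE)
}
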