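# Synthetic fixtures with the statistical structure the method assumes:
# families of RNA-like contact maps that share tertiary loop-loop blocks (the
# template machine's training stand-in), alignments with planted pairwise
# couplings at true contacts (the coupling analysis' stand-in), and toy 3D
# chains for the coordinate-reading path.

#' RNA-like synthetic contact map with stems and tertiary blocks
#'
#' Lays out `n_stems` nested hairpin stems (anti-diagonal contact bands with
#' their Watson-Crick pairs) along the sequence and places
#' `n_tertiary_blocks` 2 x 2 contact patches between loop regions of distinct
#' hairpins, emulating long-range loop-loop interactions. A consistent
#' pseudo-distance matrix is emitted — contacts drawn in [3, 8) Angstrom,
#' non-contacts in (8, 30] — so that thresholding the distances at 8 Angstrom
#' reproduces the map exactly and the full distance-to-map path can be
#' exercised.
#'
#' @param length number of nucleotides (>= 20).
#' @param n_stems number of hairpins.
#' @param n_tertiary_blocks number of loop-loop contact patches.
#' @param seed RNG seed.
#' @param stem_len base pairs per stem (default 5).
#' @return list with `map` (a `contact_map`, no separation filter), `ss`
#'   (the `secondary_structure`), `distances` (pseudo-distance matrix),
#'   `tertiary_pairs` (two-column matrix of the patch contacts).
#' @export
synth_contact_map <- function(length, n_stems = 3L, n_tertiary_blocks = 2L,
                              seed = 1L, stem_len = 5L) {
  L <- as.integer(length)
  if (L < 20L) stop("length must be >= 20", call. = FALSE)
  loop_min <- 4L
  unit <- L %/% n_stems
  stem_len <- min(stem_len, (unit - loop_min) %/% 2L)
  if (stem_len < 3L) stop("cannot place stems: too many stems for this length",
                          call. = FALSE)
  loop_len <- if (unit - 2L * stem_len >= 5L) 5L else loop_min
  slack <- unit - 2L * stem_len - loop_len   # seeded per-hairpin offset range
  db <- rep(".", L)
  pairs <- NULL
  loops <- list()
  offsets <- with_seed(child_seed(seed, 3L),
                       sample.int(slack + 1L, n_stems, replace = TRUE) - 1L)
  for (k in seq_len(n_stems)) {
    a <- (k - 1L) * unit + 1L + offsets[k]
    b <- a + 2L * stem_len + loop_len - 1L
    t <- seq_len(stem_len) - 1L
    pairs <- rbind(pairs, cbind(a + t, b - t))
    db[a + t] <- "("
    db[b - t] <- ")"
    loops[[k]] <- (a + stem_len):(b - stem_len)
  }
  ss <- read_dotbracket(paste(db, collapse = ""))

  m <- matrix(0L, L, L)
  m[pairs] <- 1L
  m[pairs[, c(2, 1)]] <- 1L

  tert <- matrix(integer(0), 0, 2)
  if (n_tertiary_blocks > 0L) {
    combos <- utils::combn(n_stems, 2)
    if (ncol(combos) < 1L) stop("cannot place tertiary blocks with one stem",
                                call. = FALSE)
    with_seed(child_seed(seed, 7L), {
      pick <- ((seq_len(n_tertiary_blocks) - 1L) %% ncol(combos)) + 1L
      for (bl in seq_len(n_tertiary_blocks)) {
        l1 <- loops[[combos[1, pick[bl]]]]
        l2 <- loops[[combos[2, pick[bl]]]]
        p <- l1[sample.int(length(l1) - 1L, 1L)]
        q <- l2[sample.int(length(l2) - 1L, 1L)]
        cells <- expand.grid(i = c(p, p + 1L), j = c(q, q + 1L))
        cells <- cells[abs(cells$i - cells$j) > 4L, , drop = FALSE]
        tert <- rbind(tert, as.matrix(cells))
      }
    })
    m[tert] <- 1L
    m[tert[, c(2, 1)]] <- 1L
  }
  diag(m) <- 0L

  d <- with_seed(child_seed(seed, 11L), {
    d <- matrix(0, L, L)
    lo <- which(lower.tri(d))
    d[lo] <- runif(length(lo), 8 + 1e-6, 30)
    d <- d + t(d)
    contact_cells <- which(m == 1L & lower.tri(m))
    d[contact_cells] <- runif(length(contact_cells), 3, 8 - 1e-6)
    d <- pmin(d, t(d))  # symmetric; contact cells take the in-range value
    diag(d) <- 0
    d
  })
  list(map = new_contact_map(m, cutoff = 8.0, min_separation = 0L),
       ss = ss, distances = d, tertiary_pairs = tert)
}

#' Perturbed family of contact maps around a template
#'
#' Each member is the template with independent symmetric bit flips at
#' `flip_rate`, applied only off the stem bands (real structural families all
#' keep their stems; the shared tertiary blocks are what degrades). The
#' protected cells default to the base pairs of `ss` when given.
#'
#' @param template a binary `contact_map`.
#' @param n_members family size.
#' @param flip_rate per-cell flip probability in `[0, 0.5)`.
#' @param seed RNG seed.
#' @param ss optional `secondary_structure` whose base pairs are protected.
#' @return list of `contact_map`s.
#' @export
synth_family <- function(template, n_members = 20L, flip_rate = 0.1,
                         seed = 1L, ss = NULL) {
  if (flip_rate < 0 || flip_rate >= 0.5) {
    stop("flip_rate must be in [0, 0.5)", call. = FALSE)
  }
  L <- nrow(template)
  protect <- matrix(FALSE, L, L)
  if (!is.null(ss) && nrow(ss$pairs) > 0L) {
    protect[ss$pairs] <- TRUE
    protect[ss$pairs[, c(2, 1)]] <- TRUE
  }
  eligible <- which(lower.tri(template) & !protect)
  with_seed(child_seed(seed, 13L), {
    lapply(seq_len(n_members), function(k) {
      m <- unclass(template)
      flips <- eligible[runif(length(eligible)) < flip_rate]
      m[flips] <- 1L - m[flips]
      m[upper.tri(m)] <- t(m)[upper.tri(m)]
      new_contact_map(m, cutoff = attr(template, "cutoff"), min_separation = 0L)
    })
  })
}

# 4x4 compatibility table over A/C/G/U with weight exp(s) on the paired
# states (A-U, G-C, G-U and their mirrors) and 1 elsewhere
pair_table <- function(coupling_strength) {
  tab <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                         c("A", "C", "G", "U")))
  for (p in list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"),
                 c("G", "U"), c("U", "G"))) {
    tab[p[1], p[2]] <- exp(coupling_strength)
  }
  tab
}

#' Alignment with planted pairwise couplings at true contacts
#'
#' Planted column pairs are sampled jointly from a 4 x 4 compatibility table
#' that favours base-pairing states (A-U, G-C, G-U) with weight
#' `exp(coupling_strength)`; all other columns are i.i.d. uniform over
#' A/C/G/U. Gaps are inserted i.i.d. at `gap_rate`. Each column may belong to
#' at most one planted pair.
#'
#' @param native_map binary `contact_map` the planted pairs must come from
#'   (pass `NULL` to skip the containment check).
#' @param planted_pairs two-column matrix of 1-based column pairs.
#' @param n_sequences alignment depth.
#' @param coupling_strength log-weight of compatible states (0 = independent).
#' @param gap_rate per-character gap probability.
#' @param seed RNG seed.
#' @param length alignment width; defaults to the native map size (or the
#'   largest planted column when no map is given).
#' @return an `msa` with attribute `planted_pairs`.
#' @export
synth_msa <- function(native_map, planted_pairs, n_sequences = 500L,
                      coupling_strength = 3.0, gap_rate = 0.05, seed = 1L,
                      length = NULL) {
  planted_pairs <- as.matrix(planted_pairs)
  if (nrow(planted_pairs) > 0 &&
      anyDuplicated(as.vector(planted_pairs[, 1:2]))) {
    stop("column reuse: each column may appear in at most one planted pair",
         call. = FALSE)
  }
  L <- if (!is.null(length)) as.integer(length)
  else if (!is.null(native_map)) nrow(native_map)
  else max(planted_pairs)
  if (!is.null(native_map) && nrow(planted_pairs) > 0L) {
    ok <- native_map[planted_pairs[, 1:2, drop = FALSE]] == 1L
    if (!all(ok)) stop("planted pairs must be native contacts", call. = FALSE)
  }
  nt <- c("A", "C", "G", "U")
  tab <- pair_table(coupling_strength)
  p_joint <- as.vector(tab) / sum(tab)
  with_seed(child_seed(seed, 17L), {
    X <- matrix(sample(nt, n_sequences * L, replace = TRUE), n_sequences, L)
    if (nrow(planted_pairs) > 0L) {
      for (r in seq_len(nrow(planted_pairs))) {
        draw <- sample.int(16L, n_sequences, replace = TRUE, prob = p_joint)
        a <- ((draw - 1L) %% 4L) + 1L       # row index of the 4x4 table
        b <- ((draw - 1L) %/% 4L) + 1L      # column index
        X[, planted_pairs[r, 1]] <- nt[a]
        X[, planted_pairs[r, 2]] <- nt[b]
      }
    }
    if (gap_rate > 0) {
      gaps <- matrix(runif(n_sequences * L) < gap_rate, n_sequences, L)
      X[gaps] <- "-"
    }
    rows <- apply(X, 1, paste, collapse = "")
    out <- new_msa(sprintf("seq%04d", seq_len(n_sequences)), rows)
    attr(out, "planted_pairs") <- planted_pairs
    out
  })
}

#' Toy 3D chain for the coordinate-reading path
#'
#' Residues placed along a smooth helical curve with three heavy atoms each
#' (P, C4', N1) jittered around the backbone point. No stereochemical realism
#' is claimed; this exists to exercise PDB round-trips.
#'
#' @param n_residues chain length.
#' @param seed RNG seed.
#' @param chain_id chain identifier.
#' @return a `structure_chain`.
#' @export
synth_structure <- function(n_residues, seed = 1L, chain_id = "A") {
  with_seed(child_seed(seed, 19L), {
    t <- seq_len(n_residues)
    base <- cbind(4 * cos(t / 2), 4 * sin(t / 2), 1.5 * t)
    residues <- lapply(t, function(k) {
      offs <- matrix(rnorm(9, sd = 0.6), 3, 3)
      atoms <- sweep(offs, 2, base[k, ], `+`)
      rownames(atoms) <- c("P", "C4'", "N1")
      colnames(atoms) <- c("x", "y", "z")
      list(number = k, insert = "", name = sample(c("A", "C", "G", "U"), 1),
           atoms = atoms)
    })
    structure(list(chain_id = chain_id, residues = residues),
              class = "structure_chain")
  })
}

# greedy column-disjoint subset of a map's eligible contacts (|i-j| > 4),
# tertiary patch pairs first so they are always represented
disjoint_native_pairs <- function(map, tertiary_pairs = NULL, min_separation = 4L) {
  idx <- which(upper.tri(map) & map == 1L, arr.ind = TRUE)
  idx <- idx[abs(idx[, 1] - idx[, 2]) > min_separation, , drop = FALSE]
  if (!is.null(tertiary_pairs) && nrow(tertiary_pairs) > 0L) {
    tp <- t(apply(tertiary_pairs, 1, sort))
    key <- paste(idx[, 1], idx[, 2])
    tkey <- paste(tp[, 1], tp[, 2])
    idx <- rbind(tp[tkey %in% key, , drop = FALSE],
                 idx[!(key %in% tkey), , drop = FALSE])
  }
  used <- logical(nrow(map))
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (!used[i] && !used[j]) {
      keep[r] <- TRUE
      used[i] <- used[j] <- TRUE
    }
  }
  unname(idx[keep, , drop = FALSE])
}

#' Full synthetic study instance
#'
#' Bundles everything one end-to-end run needs: a native contact map with
#' secondary structure and pseudo-distances, a family of perturbed maps
#' sharing the native tertiary blocks (template training set), and an
#' alignment with couplings planted at a column-disjoint subset of the native
#' tertiary-eligible contacts. Fully reproducible from `seed`.
#'
#' @param length nucleotides (default 70).
#' @param n_stems,n_tertiary_blocks native-map layout.
#' @param n_members family size (default 20).
#' @param flip_rate family perturbation rate (default 0.1).
#' @param n_sequences alignment depth (default 500).
#' @param coupling_strength planted-coupling strength (default 3).
#' @param gap_rate alignment gap rate (default 0.05).
#' @param seed RNG seed.
#' @return a `synthetic_instance`: list with `native_map`, `ss`, `distances`,
#'   `family_maps`, `msa`, `planted_pairs`, `tertiary_pairs`, `config`.
#' @export
synth_instance <- function(length = 70L, n_stems = 3L, n_tertiary_blocks = 2L,
                           n_members = 20L, flip_rate = 0.1,
                           n_sequences = 500L, coupling_strength = 3.0,
                           gap_rate = 0.05, seed = 1L) {
  base <- synth_contact_map(length, n_stems, n_tertiary_blocks, seed = seed)
  planted <- disjoint_native_pairs(base$map, base$tertiary_pairs)
  fam <- synth_family(base$map, n_members, flip_rate, seed = seed, ss = base$ss)
  msa <- synth_msa(base$map, planted, n_sequences, coupling_strength,
                   gap_rate, seed = seed)
  structure(list(native_map = base$map, ss = base$ss,
                 distances = base$distances, family_maps = fam, msa = msa,
                 planted_pairs = planted, tertiary_pairs = base$tertiary_pairs,
                 config = list(length = length, n_stems = n_stems,
                               n_tertiary_blocks = n_tertiary_blocks,
                               n_members = n_members, flip_rate = flip_rate,
                               n_sequences = n_sequences,
                               coupling_strength = coupling_strength,
                               gap_rate = gap_rate, seed = seed)),
            class = "synthetic_instance")
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat("<synthetic_instance> L =", nrow(x$native_map), "-",
      length(x$family_maps), "family maps,", length(x$msa), "sequences,",
      nrow(x$planted_pairs), "planted pairs\n")
  invisible(x)
}
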