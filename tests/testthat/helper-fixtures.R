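# Shared fixtures: all built in code, seeded.

# small random machine for enumeration oracles
tiny_rbm <- function(nv, nh, seed = 1, w_sd = 0.3, b_sd = 0.2) {
  set.seed(seed)
  rbm_model(nv, nh,
            weight = matrix(rnorm(nv * nh, sd = w_sd), nv, nh),
            visible_bias = rnorm(nv, sd = b_sd),
            hidden_bias = rnorm(nh, sd = b_sd))
}

random_binary_matrix <- function(n, m, seed = 1, p = 0.5) {
  set.seed(seed)
  (matrix(runif(n * m), n, m) < p) * 1
}

random_symmetric_map <- function(L, seed = 1, p = 0.2) {
  set.seed(seed)
  m <- matrix(0L, L, L)
  lo <- which(lower.tri(m))
  m[lo] <- as.integer(runif(length(lo)) < p)
  m + t(m)
}

# two-residue PDB fixture, 3 heavy atoms each, optional hydrogens
minimal_pdb <- function(with_h = FALSE) {
  lines <- c(
    "ATOM      1  P     G A   1       0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  C4'   G A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N1    G A   1       0.000   1.000   0.000  1.00  0.00           N",
    if (with_h) "ATOM      4  H1    G A   1       0.100   1.100   0.000  1.00  0.00           H",
    "ATOM      5  P     C A   2       3.000   4.000   0.000  1.00  0.00           P",
    "ATOM      6  C4'   C A   2       4.000   4.000   0.000  1.00  0.00           C",
    "ATOM      7  N3    C A   2       3.000   5.000   0.000  1.00  0.00           N",
    if (with_h) "ATOM      8  H3    C A   2       3.100   5.100   0.000  1.00  0.00           H",
    "END")
  paste(lines[!vapply(lines, is.null, logical(1))], collapse = "\n")
}

# single-atom-per-residue chain at given coordinates
point_chain <- function(coords) {
  residues <- lapply(seq_len(nrow(coords)), function(k) {
    atoms <- coords[k, , drop = FALSE]
    rownames(atoms) <- "P"
    list(number = k, insert = "", name = "A", atoms = atoms)
  })
  structure(list(chain_id = "A", residues = residues),
            class = "structure_chain")
}
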