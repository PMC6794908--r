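#' Read one chain of an RNA structure from PDB-format text
#'
#' Parses `ATOM`/`HETATM` records with [bio3d::read.pdb()], keeps the requested
#' chain, drops hydrogens and waters, and groups the remaining heavy atoms by
#' residue. Modified nucleotides are retained as long as they carry at least
#' one heavy atom: the contact definition needs only heavy-atom coordinates,
#' not base identity. Insertion codes are preserved in the residue ordering.
#'
#' @param text character scalar with PDB-format content, or a path to a PDB
#'   file.
#' @param chain single chain identifier (e.g. `"A"`).
#' @return A `structure_chain` object: a list with `chain_id` and `residues`,
#'   where `residues` is an ordered list of entries holding `number`, `insert`,
#'   `name`, and an `atoms` matrix (rows = heavy atoms, columns x/y/z in
#'   Angstrom, rownames = atom names).
#' @examples
#' pdb <- write_structure_pdb(synth_structure(5, seed = 1))
#' ch <- read_structure(pdb, chain = "A")
#' length(ch$residues)
#' @export
read_structure <- function(text, chain = "A") {
  path <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text
  } else {
    tf <- tempfile(fileext = ".pdb")
    writeLines(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]], tf)
    tf
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain not found: ", chain, call. = FALSE)
  # waters out; hydrogens (and deuterium) out by element symbol, falling back
  # to the atom-name convention (leading digits then H) when elesy is blank
  at <- at[!(at$resid %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  elesy <- trimws(ifelse(is.na(at$elesy), "", at$elesy))
  is_h <- elesy %in% c("H", "D") |
    (elesy == "" & grepl("^[0-9]*[HD]", trimws(at$elety)))
  at <- at[!is_h, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty chain: no heavy atoms after filtering", call. = FALSE)

  ins <- ifelse(is.na(at$insert) | at$insert == "", " ", at$insert)
  key <- paste(at$resno, ins, sep = "|")
  # preserve file order of residues (PDB order is sequence order incl. icodes)
  keys <- unique(key)
  residues <- lapply(keys, function(k) {
    rows <- at[key == k, , drop = FALSE]
    atoms <- as.matrix(rows[, c("x", "y", "z")])
    rownames(atoms) <- trimws(rows$elety)
    list(
      number = rows$resno[1],
      insert = trimws(ins[key == k][1]),
      name   = trimws(rows$resid[1]),
      atoms  = atoms
    )
  })
  structure(list(chain_id = chain, residues = residues),
            class = "structure_chain")
}

#' @export
print.structure_chain <- function(x, ...) {
  natoms <- vapply(x$residues, function(r) nrow(r$atoms), integer(1))
  cat("<structure_chain> chain", x$chain_id, "-", length(x$residues),
      "residues,", sum(natoms), "heavy atoms\n")
  invisible(x)
}

#' @export
length.structure_chain <- function(x) length(x$residues)

#' Write a toy chain as PDB-format text
#'
#' Formats per-residue heavy-atom coordinates as `ATOM` records. Used by the
#' synthetic generator to exercise the full coordinate-reading path; makes no
#' claim of stereochemical realism.
#'
#' @param chain a `structure_chain`.
#' @return character scalar of PDB-format text (with final `END`).
#' @export
write_structure_pdb <- function(chain) {
  stopifnot(inherits(chain, "structure_chain"))
  lines <- character(0)
  serial <- 0L
  for (r in chain$residues) {
    for (a in seq_len(nrow(r$atoms))) {
      serial <- serial + 1L
      nm <- rownames(r$atoms)[a]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, substr(nm, 1, 4), substr(r$name, 1, 3), chain$chain_id,
        r$number, r$atoms[a, 1], r$atoms[a, 2], r$atoms[a, 3],
        substr(nm, 1, 1)))
    }
  }
  paste(c(lines, "END", ""), collapse = "\n")
}
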