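#' Read a multiple sequence alignment (FASTA or Stockholm)
#'
#' Auto-detects the format from the first non-blank line (`>` for FASTA,
#' `# STOCKHOLM` for Stockholm). Rows are normalised onto the nucleotide
#' alphabet `{A, C, G, U, -}`: letters are uppercased, `T` becomes `U`, and
#' every remaining symbol (`.`, `~`, `N`, other ambiguity codes) becomes a
#' gap. Stockholm markup lines (`#=GF`, `#=GC`, ...) are ignored; only the
#' aligned sequence lines are read, with multi-block alignments concatenated
#' per identifier.
#'
#' @param text character with alignment content (one string or a vector of
#'   lines), or a path to an alignment file.
#' @return An `msa` object: list with `ids`, `rows` (equal-length strings over
#'   A/C/G/U/-), and `L` (alignment width).
#' @examples
#' aln <- read_msa(">s1\nACGU\n>s2\nAC-U")
#' aln$L
#' @export
read_msa <- function(text) {
  lines <- msa_input_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no sequences", call. = FALSE)
  first <- trimws(lines[1])
  if (startsWith(first, "#") && grepl("STOCKHOLM", first)) {
    parsed <- parse_stockholm(lines)
  } else if (startsWith(first, ">")) {
    parsed <- parse_fasta(lines)
  } else {
    stop("unrecognised alignment format (expected FASTA '>' or '# STOCKHOLM')",
         call. = FALSE)
  }
  if (length(parsed$rows) == 0L) stop("no sequences", call. = FALSE)
  rows <- normalize_rna(parsed$rows)
  if (length(unique(nchar(rows))) != 1L) {
    stop("unequal lengths: alignment is ragged", call. = FALSE)
  }
  new_msa(parsed$ids, rows)
}

new_msa <- function(ids, rows) {
  structure(list(ids = ids, rows = unname(rows), L = nchar(rows[1])),
            class = "msa")
}

msa_input_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else {
    strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
}

parse_fasta <- function(lines) {
  # delegate FASTA to Biostrings; generic B-string set so any symbol survives
  # to our own normalisation step
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  set <- Biostrings::readBStringSet(tf)
  list(ids = names(set), rows = as.character(set))
}

parse_stockholm <- function(lines) {
  body <- lines[-1]
  body <- body[!startsWith(trimws(body), "#")]
  body <- body[trimws(body) != "//"]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(list(ids = character(0), rows = character(0)))
  parts <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)\\s*$", body))
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) stop("malformed Stockholm sequence line", call. = FALSE)
  ids <- vapply(parts, `[`, character(1), 2)
  seqs <- vapply(parts, `[`, character(1), 3)
  # concatenate multi-block (interleaved) alignments per id, keeping first-seen order
  uid <- unique(ids)
  rows <- vapply(uid, function(i) paste(seqs[ids == i], collapse = ""), character(1))
  list(ids = uid, rows = unname(rows))
}

normalize_rna <- function(rows) {
  rows <- toupper(rows)
  rows <- chartr("T", "U", rows)
  vapply(rows, function(r) gsub("[^ACGU-]", "-", r), character(1), USE.NAMES = FALSE)
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa>", length(x$rows), "sequences x", x$L, "columns\n")
  invisible(x)
}

#' @export
length.msa <- function(x) length(x$rows)

#' Alignment as a character matrix
#'
#' @param x an `msa`.
#' @param ... unused.
#' @return character matrix, sequences in rows, columns = alignment columns.
#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Write an alignment as FASTA text
#'
#' @param msa an `msa` object.
#' @param path optional file path; when `NULL` the text is returned invisibly.
#' @return the FASTA text, invisibly.
#' @export
write_msa <- function(msa, path = NULL) {
  stopifnot(inherits(msa, "msa"))
  txt <- paste0(">", msa$ids, "\n", msa$rows, collapse = "\n")
  txt <- paste0(txt, "\n")
  if (!is.null(path)) writeLines(txt, path, sep = "")
  invisible(txt)
}
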