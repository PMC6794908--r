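#' Write a ranked contact list as TSV
#'
#' One line per predicted pair in rank order, 1-based indices with `i < j`.
#' With `include_labels = TRUE` the evaluation columns (`range`, `category`,
#' `is_native`) are written when present.
#'
#' @param contacts a `scored_contacts` tibble (see [rank_contacts()]).
#' @param path optional output path; when `NULL` the text is returned.
#' @param include_labels write classification columns if available.
#' @return TSV text, invisibly when written to `path`.
#' @export
write_contacts <- function(contacts, path = NULL, include_labels = FALSE) {
  cols <- c("i", "j", "score")
  if (include_labels) {
    cols <- c(cols, intersect(c("range", "category", "is_native"),
                              names(contacts)))
  }
  df <- as.data.frame(contacts)[, cols, drop = FALSE]
  if (nrow(df) > 0L) df$score <- sprintf("%.10g", df$score)
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(df) > 0L)
               do.call(paste, c(unname(as.list(df)), sep = "\t")))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Read a contact list written by [write_contacts()]
#'
#' @param text TSV text or a file path.
#' @return a `scored_contacts` tibble (columns `i`, `j`, `score`, plus any
#'   label columns present in the file), in file order.
#' @export
read_contacts <- function(text) {
  lines <- msa_input_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty contact file", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1L) {
    out <- tibble::as_tibble(setNames(
      lapply(header, function(h)
        if (h %in% c("i", "j")) integer(0)
        else if (h %in% c("score")) numeric(0)
        else if (h == "is_native") logical(0)
        else character(0)),
      header))
  } else {
    df <- read.table(text = paste(lines[-1], collapse = "\n"), sep = "\t",
                     col.names = header, stringsAsFactors = FALSE)
    out <- tibble::as_tibble(df)
  }
  class(out) <- c("scored_contacts", class(out))
  out
}

#' Write a square matrix (contact map, weight, distances) as dense TSV
#'
#' @param m square numeric matrix.
#' @param path optional output path.
#' @return TSV text, invisibly when written.
#' @export
write_matrix_tsv <- function(m, path = NULL) {
  stop_if_not_square(m)
  lines <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = "\t"))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Read a dense square matrix from TSV
#'
#' @param text TSV text or file path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(text) {
  lines <- msa_input_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
  stop_if_not_square(m, "matrix file")
  m
}

#' Save / load a trained RBM
#'
#' The archive stores weights, biases, shapes, the training configuration and
#' the seed, so a saved model documents exactly how it was produced.
#'
#' @param model an `rbm_model`.
#' @param path file path for the model archive.
#' @return `save_rbm` returns `path` invisibly; `load_rbm` the model.
#' @export
save_rbm <- function(model, path) {
  stopifnot(inherits(model, "rbm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_rbm
#' @export
load_rbm <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rbm_model")) stop("not an RBM model archive", call. = FALSE)
  model
}
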