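#' Parse a dot-bracket secondary structure
#'
#' Extracts base pairs by stack matching over `(`/`)` and labels stems: a stem
#' is a maximal run of stacked pairs (i, j), (i+1, j-1), ... Positions not in
#' any pair are loop positions. Pseudoknot notation (additional bracket types
#' `[ ] { } < >` or crossing pairs) is rejected with an error because the
#' contact-category classifier assumes a nested stem model.
#'
#' @param text dot-bracket string over `(`, `)`, `.`.
#' @return A `secondary_structure`: list with `dotbracket`, `pairs` (two-column
#'   matrix, 1-based, i < j, ordered by i), and `stem_id` (integer vector,
#'   `NA` at loop positions).
#' @examples
#' ss <- read_dotbracket("((..))")
#' ss$pairs
#' @export
read_dotbracket <- function(text) {
  db <- trimws(paste(text, collapse = ""))
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  if (any(chars %in% c("[", "]", "{", "}", "<", ">"))) {
    stop("pseudoknot unsupported: only nested (/) pairs are handled", call. = FALSE)
  }
  if (!all(chars %in% c("(", ")", "."))) {
    stop("invalid dot-bracket character", call. = FALSE)
  }
  n <- length(chars)
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (k in seq_len(n)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets", call. = FALSE)
      pi <- c(pi, stack[length(stack)])
      pj <- c(pj, k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) stop("unbalanced brackets", call. = FALSE)
  pairs <- cbind(i = pi, j = pj)
  if (nrow(pairs) > 0L) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]

  stem_id <- rep(NA_integer_, n)
  if (nrow(pairs) > 0L) {
    partner <- integer(n)
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
    sid <- 0L
    cur <- 0L
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      stacked_on_prev <- i > 1 && partner[i - 1] == j + 1 && j + 1 <= n
      if (!stacked_on_prev) {
        sid <- sid + 1L
        cur <- sid
      }
      stem_id[i] <- cur
      stem_id[j] <- cur
    }
  }
  structure(list(dotbracket = db, pairs = pairs, stem_id = stem_id),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  ns <- if (all(is.na(x$stem_id))) 0L else max(x$stem_id, na.rm = TRUE)
  cat("<secondary_structure>", nchar(x$dotbracket), "nt,",
      nrow(x$pairs), "pairs,", ns, "stems\n")
  invisible(x)
}

is_paired <- function(ss, k) !is.na(ss$stem_id[k])
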