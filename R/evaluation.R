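#' Positive predictive value of the top-N predictions
#'
#' `PPV = |TP| / (|TP| + |FP|)`: the fraction of the first `n` ranked pairs
#' that are native contacts. The native map must use the same cutoff and
#' separation conventions as the prediction (8 Angstrom, `|i - j| > 4` by
#' default throughout).
#'
#' @param predicted a `scored_contacts` tibble (ranked).
#' @param native binary native `contact_map`.
#' @param n evaluate the top `n` predictions (default: all).
#' @return scalar PPV in [0, 1].
#' @examples
#' native <- unflatten_map(rep(1, 10), 5)
#' preds <- rank_contacts(matrix(1, 5, 5), min_separation = 0, top_n = 4)
#' ppv(preds, native)
#' @export
ppv <- function(predicted, native, n = nrow(predicted)) {
  if (n == 0L || nrow(predicted) == 0L) stop("no predictions", call. = FALSE)
  top <- head(predicted, n)
  mean(native[cbind(top$i, top$j)] == 1L)
}

#' Cumulative true-positive curve
#'
#' Number of native contacts among the top-k predictions, for each rank
#' k = 1..n_max. Non-decreasing; `ppv(n) * n = tp_curve[n]` for every n.
#'
#' @param predicted ranked `scored_contacts`.
#' @param native binary native `contact_map`.
#' @param n_max maximum rank (default 100; capped at the list length).
#' @return tibble with columns `rank`, `true_positives`, `ppv`.
#' @export
tp_curve <- function(predicted, native, n_max = 100L) {
  n_max <- min(n_max, nrow(predicted))
  top <- head(predicted, n_max)
  hit <- native[cbind(top$i, top$j)] == 1L
  tp <- cumsum(hit)
  tibble::tibble(rank = seq_len(n_max), true_positives = tp,
                 ppv = tp / seq_len(n_max))
}

#' Evaluation report with range and category breakdowns
#'
#' Evaluates the top `n` predictions against the native map and partitions the
#' true positives by sequence range (short 5-12 nt, medium 13-24 nt, long 25+
#' nt) and, when a secondary structure is supplied, by structural category
#' (base pair, stem-loop, loop-loop, intra/inter stem-stem). Both breakdowns
#' partition the true-positive set exactly.
#'
#' @param predicted ranked `scored_contacts`.
#' @param native binary native `contact_map`.
#' @param ss optional `secondary_structure` for the category breakdown.
#' @param n rank cutoff (default 100, capped at the list length).
#' @return an `evaluation_report`: list with `n`, `ppv_at_n`, `tp_curve`,
#'   `contacts` (per-pair tibble with labels), `range_breakdown`,
#'   `category_breakdown` (`NULL` without `ss`).
#' @export
contact_breakdown <- function(predicted, native, ss = NULL, n = 100L) {
  n <- min(n, nrow(predicted))
  if (n == 0L) stop("no predictions", call. = FALSE)
  top <- head(predicted, n)
  hit <- native[cbind(top$i, top$j)] == 1L
  rng <- classify_range(top$i, top$j)
  cat_lab <- if (!is.null(ss)) classify_category(top$i, top$j, ss) else NA_character_
  contacts <- tibble::tibble(i = top$i, j = top$j, score = top$score,
                             is_native = hit, range = rng, category = cat_lab)
  range_levels <- c("short", "medium", "long")
  range_breakdown <- setNames(
    vapply(range_levels, function(lv) sum(hit & rng == lv), integer(1)),
    range_levels)
  category_breakdown <- NULL
  if (!is.null(ss)) {
    cat_levels <- c("base_pair", "stem_loop", "loop_loop",
                    "intra_stem_stem", "inter_stem_stem")
    category_breakdown <- setNames(
      vapply(cat_levels, function(lv) sum(hit & cat_lab == lv), integer(1)),
      cat_levels)
  }
  structure(list(n = n, ppv_at_n = mean(hit),
                 tp_curve = tp_curve(predicted, native, n),
                 contacts = contacts,
                 range_breakdown = range_breakdown,
                 category_breakdown = category_breakdown),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> top", x$n, sprintf("PPV %.3f\n", x$ppv_at_n))
  cat("  range TP:", paste(names(x$range_breakdown), x$range_breakdown,
                           sep = "=", collapse = " "), "\n")
  if (!is.null(x$category_breakdown)) {
    cat("  category TP:", paste(names(x$category_breakdown),
                                x$category_breakdown,
                                sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @describeIn contact_breakdown per-pair tidy view of the report.
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @export
tidy.evaluation_report <- function(x, ...) x$contacts

#' @describeIn contact_breakdown one-row summary of the report.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(n = x$n, ppv = x$ppv_at_n,
                 true_positives = sum(x$contacts$is_native),
                 tp_short = x$range_breakdown[["short"]],
                 tp_medium = x$range_breakdown[["medium"]],
                 tp_long = x$range_breakdown[["long"]])
}

#' Serialise an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path optional output path.
#' @return JSON text, invisibly when written.
#' @export
write_report_json <- function(report, path = NULL) {
  payload <- list(
    n = report$n,
    ppv_at_n = report$ppv_at_n,
    tp_curve = report$tp_curve$true_positives,
    range_breakdown = as.list(report$range_breakdown),
    category_breakdown = if (is.null(report$category_breakdown)) NULL
    else as.list(report$category_breakdown),
    contacts = report$contacts
  )
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
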