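#' Nominate novel related miRNAs from enriched categories
#'
#' Every member of a significantly over-represented category that is absent
#' from the input list is a candidate novel related miRNA: the category ties
#' it to the same family, cluster, function, disease or tissue programme as
#' the input hits. One record is emitted per (miRNA, significant category)
#' pair; a miRNA backed by several significant categories appears once per
#' category. Depletion (under-representation) runs never nominate
#' candidates.
#'
#' Nomination is gated on the raw p-value by default: category-level
#' follow-up is exploratory and a conservative family-wise correction over
#' hundreds of sets would suppress modest but real signals (set
#' \code{use_fdr = TRUE} to gate on the BH-adjusted value instead).
#'
#' @param results A [mirsea()] fit, or an enrichment results data.frame as
#'   returned by [read_results()] (which must then carry
#'   \code{unmatched_members}).
#' @param input_hits Optional character vector of normalized input hits; only
#'   needed when \code{results} is a bare data.frame. Used to assert that no
#'   nominated miRNA is an input hit.
#' @param alpha Significance level for nominating categories; default 0.05.
#' @param use_fdr Gate on the BH-adjusted value instead of the raw p-value?
#'   Default \code{FALSE}.
#' @return data.frame of class \code{"mirsea_predictions"} with columns
#'   \code{mirna}, \code{source_category}, \code{class}, \code{category_p},
#'   \code{category_fdr}, ordered by \code{category_p} (ties by category id)
#'   then miRNA name. Empty (zero rows) when no category passes \code{alpha}.
#' @examples
#' fx <- ami_fixture()
#' fit <- mirsea(c(fx$up, fx$down), fx$catalog)
#' predict_related(fit, alpha = 0.05)
#' @export
predict_related <- function(results, input_hits = NULL, alpha = 0.05,
                            use_fdr = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    validation_error("alpha must lie in (0, 1)")
  }
  if (inherits(results, "mirsea")) {
    direction <- results$config$direction
    if (is.null(input_hits)) input_hits <- results$input_hits
    res <- results$results
    unmatched <- results$unmatched
  } else {
    res <- as.data.frame(results)
    if (!"unmatched_members" %in% names(res)) {
      usage_error("results table lacks unmatched_members; re-run the enrichment")
    }
    direction <- attr(results, "direction") %||% "over"
    unmatched <- lapply(strsplit(res$unmatched_members, ",", fixed = TRUE),
                        function(v) v[nzchar(v)])
    names(unmatched) <- res$category_id
  }
  if (!identical(direction, "over")) {
    usage_error("predictions require an over-representation run; depleted sets do not nominate candidates")
  }
  crit <- if (use_fdr) res$fdr else res$p_value
  sig <- which(crit <= alpha)
  rows <- lapply(sig, function(i) {
    cand <- unmatched[[res$category_id[i]]]
    if (length(cand) == 0L) return(NULL)
    cand <- cand[natural_order(cand)]
    data.frame(mirna = cand, source_category = res$category_id[i],
               class = res$class[i], category_p = res$p_value[i],
               category_fdr = res$fdr[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna = character(0), source_category = character(0),
                      class = character(0), category_p = numeric(0),
                      category_fdr = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$category_p, out$source_category, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(input_hits) && any(out$mirna %in% input_hits)) {
    analysis_error("internal inconsistency: a nominated miRNA is an input hit")
  }
  class(out) <- c("mirsea_predictions", "data.frame")
  out
}

#' @rdname predict_related
#' @param object A [mirsea()] fit.
#' @param summary Collapse to one row per unique miRNA (see
#'   [summarize_predictions()])? Default \code{FALSE}.
#' @param ... Unused.
#' @export
predict.mirsea <- function(object, alpha = object$config$alpha,
                           use_fdr = FALSE, summary = FALSE, ...) {
  out <- predict_related(object, alpha = alpha, use_fdr = use_fdr)
  if (summary) summarize_predictions(out) else out
}

#' Collapse predictions to one row per miRNA
#'
#' A miRNA nominated by several significant categories is collapsed to a
#' single row ranked by its best (smallest) category p-value, ties broken by
#' the number of supporting categories (more first), then name.
#'
#' @param predictions A [predict_related()] table.
#' @return data.frame with columns \code{mirna}, \code{n_categories},
#'   \code{best_p}, \code{best_fdr}, \code{source_categories}
#'   (comma-joined).
#' @export
summarize_predictions <- function(predictions) {
  stopifnot(is.data.frame(predictions))
  if (nrow(predictions) == 0L) {
    return(data.frame(mirna = character(0), n_categories = integer(0),
                      best_p = numeric(0), best_fdr = numeric(0),
                      source_categories = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- split(predictions, predictions$mirna)
  out <- do.call(rbind, lapply(parts, function(g) {
    data.frame(mirna = g$mirna[1], n_categories = nrow(g),
               best_p = min(g$category_p), best_fdr = min(g$category_fdr),
               source_categories = paste(g$source_category, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  name_rank <- integer(nrow(out))
  name_rank[natural_order(out$mirna)] <- seq_len(nrow(out))
  out <- out[order(out$best_p, -out$n_categories, name_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a prediction table as TSV
#'
#' @param predictions A [predict_related()] or [summarize_predictions()] table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- as.data.frame(predictions)
  for (nm in intersect(c("category_p", "category_fdr", "best_p", "best_fdr"),
                       names(out))) {
    out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
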