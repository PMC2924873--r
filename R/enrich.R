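#' Resolve the reference population for an analysis
#'
#' Without a background list the population defaults to the catalog universe
#' (every miRNA appearing in any category). With a background list, the
#' population is the normalized background intersected with the universe;
#' background names outside the universe cannot inform the urn model and are
#' returned in \code{dropped} with a warning, never silently discarded.
#'
#' @param cl A [catalog()].
#' @param background Optional character vector of background miRNA names.
#' @return List with \code{population} (character vector) and \code{dropped}.
#' @export
resolve_population <- function(cl, background = NULL) {
  stopifnot(inherits(cl, "mirsea_catalog"))
  if (is.null(background)) {
    return(list(population = cl$universe, dropped = character(0)))
  }
  keys <- unique(normalize_name(background))
  population <- intersect(keys, cl$universe)
  dropped <- setdiff(keys, cl$universe)
  if (length(dropped)) {
    warning(sprintf("%d background miRNA(s) not in the catalog universe: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  if (length(population) == 0L) {
    analysis_error("background shares no miRNA with the catalog universe")
  }
  list(population = sort(population, method = "radix"), dropped = dropped)
}

#' Match an input miRNA list against a population
#'
#' @param input Character vector of miRNA names (non-empty).
#' @param population Character vector of normalized population keys.
#' @return List with \code{hits} (normalized unique input found in the
#'   population) and \code{dropped} (input keys outside it).
#' @export
match_input <- function(input, population) {
  if (length(input) == 0L) analysis_error("input miRNA list is empty")
  keys <- unique(normalize_name(input))
  hits <- intersect(keys, population)
  dropped <- setdiff(keys, population)
  if (length(hits) == 0L) {
    analysis_error(paste(
      "no input miRNA matches the reference population;",
      "check the identifiers (species prefixes are stripped automatically)"))
  }
  list(hits = sort(hits, method = "radix"), dropped = dropped)
}

#' miRNA set enrichment analysis
#'
#' Scores every catalog category for over- or under-representation of an
#' input miRNA list with the hypergeometric test, and adjusts the p-values by
#' Bonferroni and Benjamini-Hochberg corrections. The analysis proceeds in
#' four steps: (1) normalize and match the input list, (2) resolve the
#' reference population (catalog universe, or a user background intersected
#' with it), (3) compute the tail probability for each category from its
#' contingency counts, (4) correct, sort by raw p-value, and report.
#'
#' Category sizes are recomputed within the population: members outside a
#' custom background leave the urn entirely, so that all four counts refer to
#' the same population. Categories smaller than \code{min_category_size}
#' after this truncation are skipped (and recorded in the returned object);
#' a one-member set cannot be informatively enriched. All remaining
#' categories are returned unfiltered — significance thresholds belong to
#' downstream steps such as [predict.mirsea()].
#'
#' @param input Character vector of miRNA names to analyse.
#' @param cl A [catalog()] of categories.
#' @param background Optional character vector defining the reference
#'   population; default is the whole catalog universe.
#' @param direction \code{"over"} (upper tail, enrichment; default) or
#'   \code{"under"} (lower tail, depletion).
#' @param alpha Significance level carried to downstream prediction; default
#'   0.05.
#' @param correction_scope \code{"global"} (one correction family across all
#'   tested categories; default) or \code{"per_class"} (correct within each
#'   of the five class labels separately).
#' @param min_category_size Smallest in-population category size tested;
#'   default 2.
#' @return An object of class \code{"mirsea"}; see Details. Its
#'   \code{results} element is a data.frame with one row per tested category,
#'   sorted by raw p-value (ties broken by category id), with columns
#'   \code{category_id}, \code{class}, \code{HS}, \code{S}, \code{HP},
#'   \code{P}, \code{percent_matched} (100*HS/HP), \code{fold}
#'   ((HS/HP)/(S/P)), \code{p_value}, \code{bonferroni}, \code{fdr},
#'   \code{matched_members}, plus \code{percent_of_category} (100*HS/S).
#' @examples
#' fx <- ami_fixture()
#' fit <- mirsea(c(fx$up, fx$down), fx$catalog)
#' fit
#' head(as.data.frame(fit))
#' predict(fit)
#' @export
mirsea <- function(input, cl, background = NULL,
                   direction = c("over", "under"), alpha = 0.05,
                   correction_scope = c("global", "per_class"),
                   min_category_size = 2) {
  direction <- match.arg(direction)
  correction_scope <- match.arg(correction_scope)
  stopifnot(inherits(cl, "mirsea_catalog"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    validation_error("alpha must lie in (0, 1)")
  }
  pop <- resolve_population(cl, background)
  population <- pop$population
  mi <- match_input(input, population)
  hits <- mi$hits
  P <- length(population)
  HP <- length(hits)

  rows <- list(); matched <- list(); unmatched <- list()
  skipped <- character(0)
  for (cc in cl$categories) {
    members <- intersect(cc$members, population)
    S <- length(members)
    if (S < min_category_size) {
      skipped <- c(skipped, cc$id)
      next
    }
    hit_members <- intersect(members, hits)
    HS <- length(hit_members)
    counts <- contingency_counts(P = P, HP = HP, S = S, HS = HS)
    p <- if (direction == "over") p_over(counts) else p_under(counts)
    rows[[length(rows) + 1L]] <- data.frame(
      category_id = cc$id, class = cc$class_label,
      HS = HS, S = S, HP = HP, P = P,
      percent_matched = 100 * HS / HP,
      percent_of_category = 100 * HS / S,
      fold = (HS / HP) / (S / P),
      p_value = p, stringsAsFactors = FALSE)
    matched[[cc$id]] <- hit_members
    unmatched[[cc$id]] <- setdiff(members, hit_members)
  }
  if (length(rows) == 0L) {
    analysis_error(sprintf(
      "no category of size >= %d within the population", min_category_size))
  }
  res <- do.call(rbind, rows)
  if (correction_scope == "global") {
    res$bonferroni <- bonferroni_adjust(res$p_value)
    res$fdr <- bh_fdr_adjust(res$p_value)
  } else {
    res$bonferroni <- NA_real_; res$fdr <- NA_real_
    for (cls in unique(res$class)) {
      sel <- res$class == cls
      res$bonferroni[sel] <- bonferroni_adjust(res$p_value[sel])
      res$fdr[sel] <- bh_fdr_adjust(res$p_value[sel])
    }
  }
  ord <- order(res$p_value, res$category_id, method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res$matched_members <- vapply(
    res$category_id, function(id) paste(matched[[id]], collapse = ","),
    character(1), USE.NAMES = FALSE)
  res$unmatched_members <- vapply(
    res$category_id, function(id) paste(unmatched[[id]], collapse = ","),
    character(1), USE.NAMES = FALSE)
  structure(list(
    results = res,
    matched = matched,
    unmatched = unmatched,
    input_hits = hits,
    dropped_input = mi$dropped,
    dropped_background = pop$dropped,
    skipped_categories = skipped,
    population = population,
    config = list(direction = direction, alpha = alpha,
                  correction_scope = correction_scope,
                  min_category_size = min_category_size),
    call = match.call()
  ), class = "mirsea")
}

#' @export
as.data.frame.mirsea <- function(x, ...) x$results

#' @export
print.mirsea <- function(x, digits = 3, max_rows = 10, ...) {
  cat(sprintf("miRNA set %s-representation analysis\n", x$config$direction))
  cat(sprintf("  population P = %d, input hits HP = %d, categories tested = %d\n",
              x$results$P[1], x$results$HP[1], nrow(x$results)))
  if (length(x$dropped_input)) {
    cat(sprintf("  input miRNAs outside the population: %d\n",
                length(x$dropped_input)))
  }
  if (length(x$skipped_categories)) {
    cat(sprintf("  categories below the size floor: %d\n",
                length(x$skipped_categories)))
  }
  n <- min(max_rows, nrow(x$results))
  cols <- c("category_id", "class", "HS", "S", "fold", "p_value",
            "bonferroni", "fdr")
  cat(sprintf("  top %d categories by raw p-value:\n", n))
  print(format(x$results[seq_len(n), cols], digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mirsea <- function(object, alpha = object$config$alpha, ...) {
  res <- object$results
  per_class <- table(factor(res$class, levels = CLASS_LABELS))
  sig <- res[res$p_value <= alpha, , drop = FALSE]
  out <- list(direction = object$config$direction,
              P = res$P[1], HP = res$HP[1],
              n_tested = nrow(res), per_class = per_class,
              alpha = alpha, n_significant_raw = nrow(sig),
              n_significant_fdr = sum(res$fdr <= alpha),
              n_significant_bonferroni = sum(res$bonferroni <= alpha),
              significant = sig)
  class(out) <- "summary.mirsea"
  out
}

#' @export
print.summary.mirsea <- function(x, ...) {
  cat(sprintf("%s-representation of %d input miRNAs in a population of %d\n",
              x$direction, x$HP, x$P))
  cat(sprintf("categories tested: %d (", x$n_tested))
  cat(paste(sprintf("%s %d", names(x$per_class), as.integer(x$per_class)),
            collapse = ", "), ")\n", sep = "")
  cat(sprintf("significant at alpha = %g: %d raw, %d FDR, %d Bonferroni\n",
              x$alpha, x$n_significant_raw, x$n_significant_fdr,
              x$n_significant_bonferroni))
  invisible(x)
}

#' Bar plot of the most enriched categories
#'
#' Horizontal bars of -log10 raw p-value for the \code{top} categories,
#' coloured by class label.
#'
#' @param x A [mirsea()] fit.
#' @param top Number of categories to show; default 10.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mirsea <- function(x, top = 10, ...) {
  res <- utils::head(x$results, top)
  cols <- c(family = "firebrick", cluster = "darkorange", `function` = "gold",
            disease = "forestgreen", tissue = "steelblue")
  op <- graphics::par(mar = c(5, 10, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(rev(-log10(pmax(res$p_value, 1e-300))),
                    names.arg = rev(res$category_id), horiz = TRUE, las = 1,
                    col = rev(cols[res$class]),
                    xlab = expression(-log[10] ~ p), ...)
  invisible(x)
}

#' Write an enrichment result table as TSV
#'
#' Column order: category_id, class, HS, S, HP, P, percent_matched, fold,
#' p_value, bonferroni, fdr, matched_members, percent_of_category. Rows are
#' in the fit's order (ascending raw p). The file round-trips through
#' [read_results()].
#'
#' @param x A [mirsea()] fit or its results data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(x, path) {
  res <- if (inherits(x, "mirsea")) x$results else x
  direction <- if (inherits(x, "mirsea")) x$config$direction
               else attr(x, "direction") %||% "over"
  cols <- c("category_id", "class", "HS", "S", "HP", "P", "percent_matched",
            "fold", "p_value", "bonferroni", "fdr", "matched_members",
            "unmatched_members", "percent_of_category")
  out <- res[, cols]
  for (nm in c("percent_matched", "fold", "p_value", "bonferroni", "fdr",
               "percent_of_category")) {
    out[[nm]] <- formatC(out[[nm]], digits = 15, format = "g")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# direction=%s", direction), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read back a TSV written by [write_results()]
#'
#' @param path TSV path.
#' @return data.frame in the written row order.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = c(matched_members = "character",
                                         unmatched_members = "character"))
  need <- c("category_id", "class", "HS", "S", "HP", "P", "p_value",
            "bonferroni", "fdr", "matched_members", "unmatched_members")
  if (!all(need %in% names(df))) {
    format_error(sprintf("not an enrichment result table: %s", path))
  }
  if (grepl("^# direction=", first)) {
    attr(df, "direction") <- sub("^# direction=", "", first)
  }
  df
}
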