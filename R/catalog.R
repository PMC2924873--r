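CLASS_LABELS <- c("family", "cluster", "function", "disease", "tissue")

#' Create a miRNA category
#'
#' A category is one named set of miRNAs carrying a class label that records
#' which classification scheme produced it: sequence family, genomic cluster,
#' curated function, associated disease, or tissue specificity.
#'
#' @param id Unique short identifier for the set.
#' @param class_label One of \code{"family"}, \code{"cluster"},
#'   \code{"function"}, \code{"disease"}, \code{"tissue"}.
#' @param members Character vector of miRNA names; normalized via
#'   [normalize_name()] unless \code{normalize = FALSE}. Duplicates (after
#'   normalization) are dropped with a warning.
#' @param display_name Human-readable name; defaults to \code{id}.
#' @param normalize Normalize member names? Default \code{TRUE}.
#' @return An object of class \code{"mirsea_category"}: a list with fields
#'   \code{id}, \code{class_label}, \code{display_name} and \code{members}
#'   (sorted, unique, normalized keys).
#' @examples
#' category("muscle-development", "function", c("miR-1", "miR-499", "miR-133a"))
#' @export
category <- function(id, class_label, members, display_name = id,
                     normalize = TRUE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(trimws(id))) {
    validation_error("category id must be a non-empty string")
  }
  if (!is.character(class_label) || length(class_label) != 1L ||
      !(class_label %in% CLASS_LABELS)) {
    validation_error(sprintf(
      "class label must be one of: %s", paste(CLASS_LABELS, collapse = ", ")))
  }
  if (length(members) == 0L) {
    validation_error(sprintf("category '%s' has no members", id))
  }
  keys <- if (normalize) normalize_name(members) else as.character(members)
  if (anyDuplicated(keys)) {
    warning(sprintf("category '%s': %d duplicate member name(s) dropped",
                    id, sum(duplicated(keys))), call. = FALSE)
    keys <- unique(keys)
  }
  structure(
    list(id = id, class_label = class_label,
         display_name = as.character(display_name),
         members = sort(keys, method = "radix")),
    class = "mirsea_category"
  )
}

#' @export
print.mirsea_category <- function(x, ...) {
  cat(sprintf("<miRNA category '%s' [%s], %d members>\n",
              x$id, x$class_label, length(x$members)))
  cat(" ", paste(display_mirna(x$members), collapse = ", "), "\n")
  invisible(x)
}

#' Create a catalog of miRNA categories
#'
#' A catalog bundles an ordered list of categories together with its member
#' universe: the union of all category members. The universe is the default
#' reference population for the hypergeometric test (the \eqn{P} of the
#' contingency counts).
#'
#' @param categories List of [category()] objects with unique ids.
#' @return An object of class \code{"mirsea_catalog"}: list with
#'   \code{categories} (named by id, order preserved) and \code{universe}
#'   (sorted character vector).
#' @examples
#' cat1 <- category("a", "family", c("miR-1", "miR-499"))
#' cat2 <- category("b", "cluster", c("miR-21", "miR-1"))
#' cl <- catalog(list(cat1, cat2))
#' cl$universe
#' @export
catalog <- function(categories) {
  if (!is.list(categories) || length(categories) == 0L) {
    validation_error("a catalog needs at least one category")
  }
  ok <- vapply(categories, inherits, logical(1), what = "mirsea_category")
  if (!all(ok)) validation_error("all elements must be mirsea_category objects")
  ids <- vapply(categories, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    validation_error(sprintf("duplicate category id(s): %s",
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(categories) <- ids
  universe <- sort(unique(unlist(lapply(categories, `[[`, "members"),
                                 use.names = FALSE)), method = "radix")
  structure(list(categories = categories, universe = universe),
            class = "mirsea_catalog")
}

#' @export
print.mirsea_catalog <- function(x, ...) {
  tab <- table(factor(vapply(x$categories, `[[`, character(1), "class_label"),
                      levels = CLASS_LABELS))
  cat(sprintf("<miRNA catalog: %d categories, universe of %d miRNAs>\n",
              length(x$categories), length(x$universe)))
  print(tab)
  invisible(x)
}

#' @export
length.mirsea_catalog <- function(x) length(x$categories)

catalog_class_counts <- function(cl) {
  table(factor(vapply(cl$categories, `[[`, character(1), "class_label"),
               levels = CLASS_LABELS))
}

#' Read a catalog from a GMT-dialect set file
#'
#' The on-disk format is tab-separated GMT with the class label carried in the
#' description column:
#' \preformatted{<category_id>\tclass=<label>[;name=<display name>]\t<member1>\t<member2>...}
#' Lines starting with \code{#} are comments; blank lines are skipped; LF and
#' CRLF both work. Member names are normalized on read.
#'
#' @param path Path to the set file.
#' @return A [catalog()] with one category per data line, file order preserved.
#' @seealso [write_catalog()]
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) == 0L) format_error(sprintf("no set lines in %s", path))
  cats <- vector("list", length(keep))
  seen <- character(0)
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      format_error("set line needs id, description and at least one member",
                   line = ln)
    }
    id <- fields[1]
    if (id %in% seen) {
      format_error(sprintf("duplicate category id '%s'", id), line = ln)
    }
    seen <- c(seen, id)
    desc <- parse_gmt_description(fields[2], ln)
    cats[[i]] <- withCallingHandlers(
      category(id, desc$class, fields[-(1:2)], display_name = desc$name %||% id),
      warning = function(w) {
        message(conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }
  catalog(cats)
}

parse_gmt_description <- function(desc, line) {
  parts <- strsplit(desc, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1)
  if (!"class" %in% keys) {
    format_error("description column must carry 'class=<label>'", line = line)
  }
  vals <- lapply(kv, function(p) paste(p[-1], collapse = "="))
  names(vals) <- keys
  cls <- vals[["class"]]
  if (!cls %in% CLASS_LABELS) {
    format_error(sprintf("unknown class label '%s'", cls), line = line)
  }
  list(class = cls, name = vals[["name"]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a catalog to a GMT-dialect set file
#'
#' Members are written sorted, so output is byte-stable: writing the same
#' catalog twice yields identical files, and [read_catalog()] on the result
#' reconstructs an identical catalog.
#'
#' @param cl A [catalog()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_catalog <- function(cl, path) {
  stopifnot(inherits(cl, "mirsea_catalog"))
  lines <- vapply(cl$categories, function(cc) {
    desc <- sprintf("class=%s", cc$class_label)
    if (!identical(cc$display_name, cc$id)) {
      desc <- sprintf("%s;name=%s", desc, cc$display_name)
    }
    paste(c(cc$id, desc, cc$members), collapse = "\t")
  }, character(1))
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) io_error(sprintf("cannot write catalog to %s", path))
  invisible(path)
}
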