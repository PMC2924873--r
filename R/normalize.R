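#' Normalize miRNA identifiers
#'
#' Maps raw miRNA names onto the normalized keys used throughout the package
#' for set membership and matching. Normalization lowercases the name, removes
#' all whitespace, and strips a leading 3-4 letter species prefix (e.g.
#' \code{"hsa-"}, \code{"rno-"}, \code{"mmu-"}) when the remainder starts with
#' \code{"mir"} or \code{"let"}. Arm suffixes (\code{-5p}/\code{-3p}) and
#' lettered or numbered variants are kept: \code{"miR-133a"} and
#' \code{"miR-133b"} stay distinct mature species. The function is
#' idempotent: normalizing a normalized key returns it unchanged.
#'
#' The prefix rule is deliberately conservative. Only an alphabetic token of
#' 3-4 letters before the first hyphen is considered a species code, and only
#' when what follows is itself a miRNA stem, so \code{"let-7a"} is never
#' mangled into \code{"7a"}.
#'
#' @param raw Character vector of miRNA identifiers. Each element must be
#'   non-empty after stripping whitespace.
#' @return Character vector of normalized keys, same length as \code{raw}.
#' @examples
#' normalize_name(c("hsa-miR-199a", "rno-miR-29b", "let-7a", "miR-1"))
#' @export
normalize_name <- function(raw) {
  if (!is.character(raw)) {
    invalid_identifier_error("miRNA identifiers must be a character vector")
  }
  x <- gsub("[[:space:]]+", "", raw)
  if (length(x) == 0L) return(character(0))
  if (anyNA(x) || any(!nzchar(x))) {
    invalid_identifier_error("empty or missing miRNA identifier")
  }
  x <- tolower(x)
  sub("^[a-z]{3,4}-(?=(mir|let)(-|$))", "", x, perl = TRUE)
}

# "mir-199a" -> "miR-199a" for display names; keys stay lowercase.
display_mirna <- function(key) {
  sub("^mir", "miR", key)
}

# Order strings treating digit runs numerically ("mir-9" before "mir-21").
natural_order <- function(x) {
  keys <- vapply(x, function(s) {
    m <- gregexpr("[0-9]+", s)
    runs <- regmatches(s, m)[[1]]
    if (length(runs)) {
      regmatches(s, m) <- list(formatC(as.numeric(runs), width = 12,
                                       format = "d", flag = "0"))
    }
    s
  }, character(1), USE.NAMES = FALSE)
  order(keys, x, method = "radix")
}
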