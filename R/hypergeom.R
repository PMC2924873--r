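#' Contingency counts for the hypergeometric test
#'
#' The urn model behind category enrichment. \code{P} is the reference
#' population of miRNAs (all catalog members, or a user background
#' intersected with it), \code{HP} the input miRNAs found in that population,
#' \code{S} the size of the category under test within the population, and
#' \code{HS} the overlap between input and category. All four are
#' non-negative integers with \code{HS <= min(S, HP)}, \code{S <= P},
#' \code{HP <= P}.
#'
#' @param P,HP,S,HS Non-negative integer counts.
#' @return Object of class \code{"mirsea_counts"}.
#' @examples
#' contingency_counts(P = 20, HP = 5, S = 4, HS = 2)
#' @export
contingency_counts <- function(P, HP, S, HS) {
  v <- stats::setNames(as.numeric(c(P, HP, S, HS)), c("P", "HP", "S", "HS"))
  if (anyNA(v) || !is.numeric(v) || any(v != round(v)) || any(v < 0)) {
    validation_error("counts must be non-negative integers")
  }
  if (S > P || HP > P || HS > min(S, HP)) {
    validation_error(sprintf(
      "inconsistent counts: need HS <= min(S, HP), S <= P, HP <= P (got P=%d HP=%d S=%d HS=%d)",
      P, HP, S, HS))
  }
  structure(as.list(v), class = "mirsea_counts")
}

# log of one hypergeometric term C(HP,h) C(P-HP,S-h) / C(P,S); -Inf off-support
log_hyper_term <- function(P, HP, S, h) {
  suppressWarnings(
    lchoose(HP, h) + lchoose(P - HP, S - h) - lchoose(P, S)
  )
}

# numerically safe sum of exp(logs): factor out the max
sum_exp <- function(logs) {
  logs <- logs[logs > -Inf]
  if (length(logs) == 0L) return(0)
  m <- max(logs)
  min(1, exp(m) * sum(exp(logs - m)))
}

#' Hypergeometric point probability
#'
#' The probability of observing exactly \code{HS} input miRNAs in a category
#' of size \code{S}: \deqn{P(x = HS) = \frac{C(HP, HS)\, C(P-HP, S-HS)}{C(P, S)}}
#' Off-support combinations (e.g. \code{S - HS > P - HP}) have probability 0.
#' Computed in log space for numerical stability at any realistic catalog
#' size.
#'
#' @param counts A [contingency_counts()] object.
#' @return Probability in [0, 1].
#' @examples
#' hypergeom_pmf(contingency_counts(20, 5, 4, 2))  # 70/323
#' @export
hypergeom_pmf <- function(counts) {
  stopifnot(inherits(counts, "mirsea_counts"))
  with(counts, exp(log_hyper_term(P, HP, S, HS)))
}

#' Over-representation (upper-tail) probability
#'
#' \deqn{P(\mathrm{over}) = \sum_{h = HS}^{S} P(x = h)} The sum runs
#' literally to \code{S}; terms with \code{h > HP} are over-draws whose
#' binomial coefficient is zero, so they contribute nothing. \code{HS = 0}
#' gives exactly 1.
#'
#' @inheritParams hypergeom_pmf
#' @return Probability in [0, 1].
#' @examples
#' p_over(contingency_counts(20, 5, 4, 1))  # 232/323
#' @export
p_over <- function(counts) {
  stopifnot(inherits(counts, "mirsea_counts"))
  with(counts, {
    if (HS == 0L) return(1)
    h <- seq.int(HS, S)
    sum_exp(log_hyper_term(P, HP, S, h))
  })
}

#' Under-representation (lower-tail) probability
#'
#' \deqn{P(\mathrm{under}) = \sum_{h = 0}^{HS} P(x = h)} Terms below the
#' support floor \code{max(0, S - (P - HP))} are zero and drop out of the
#' log-space sum. \code{HS = min(S, HP)} gives exactly 1.
#'
#' @inheritParams hypergeom_pmf
#' @return Probability in [0, 1].
#' @examples
#' p_under(contingency_counts(20, 5, 4, 0))  # 91/323
#' @export
p_under <- function(counts) {
  stopifnot(inherits(counts, "mirsea_counts"))
  with(counts, {
    if (HS == min(S, HP)) return(1)
    h <- seq.int(0, HS)
    sum_exp(log_hyper_term(P, HP, S, h))
  })
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size and caps at 1; order preserved.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(pvals) {
  check_pvals(pvals)
  if (length(pvals) == 0L) return(numeric(0))
  stats::p.adjust(pvals, method = "bonferroni")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up q-values: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}, mapped back to the
#' input order. Monotone (never below the raw p), capped at 1, rank
#' preserving; tied p-values receive equal q.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
bh_fdr_adjust <- function(pvals) {
  check_pvals(pvals)
  if (length(pvals) == 0L) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

check_pvals <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) ||
      any(pvals < 0) || any(pvals > 1)) {
    validation_error("p-values must be numbers in [0, 1]")
  }
  invisible(TRUE)
}
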