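# Independent oracles. Each deliberately uses a different route than the
# package implementation: stats::dhyper/phyper term enumeration for the tail
# sums (the package sums lchoose terms in log space), explicit O(n^2)/O(m^2)
# loops for clustering and the step-up correction.

# upper/lower tails by direct enumeration of hypergeometric terms
oracle_p_over <- function(P, HP, S, HS) {
  if (HS == 0) return(1)
  sum(stats::dhyper(HS:S, m = HP, n = P - HP, k = S))
}

oracle_p_under <- function(P, HP, S, HS) {
  sum(stats::dhyper(0:HS, m = HP, n = P - HP, k = S))
}

oracle_pmf <- function(P, HP, S, HS) {
  stats::dhyper(HS, m = HP, n = P - HP, k = S)
}

# all valid (HP, S, HS) tuples for one population size
valid_tuples <- function(P, stride = 1L) {
  out <- list()
  for (HP in seq(0, P, by = stride)) {
    for (S in seq(1, P, by = stride)) {
      for (HS in 0:min(S, HP)) {
        out[[length(out) + 1L]] <- c(P = P, HP = HP, S = S, HS = HS)
      }
    }
  }
  do.call(rbind, out)
}

# brute-force single-linkage components over loci; returns canonical
# partition: sorted vector of comma-joined member sets (>= 2 distinct miRNAs)
oracle_cluster_partition <- function(loci, max_gap, same_strand = FALSE) {
  n <- nrow(loci)
  linked <- function(i, j) {
    if (loci$chrom[i] != loci$chrom[j]) return(FALSE)
    if (same_strand && loci$strand[i] != loci$strand[j]) return(FALSE)
    gap <- max(loci$start[i], loci$start[j]) - min(loci$end[i], loci$end[j]) - 1
    gap <= max_gap
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && linked(i, j)) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sets <- lapply(split(seq_len(n), comp), function(idx) {
    sort(unique(loci$mirna[idx]))
  })
  sets <- Filter(function(s) length(s) >= 2, sets)
  unname(sort(vapply(sets, paste, character(1), collapse = ",")))
}

cluster_partition_of <- function(cats) {
  unname(sort(vapply(cats, function(cc) paste(sort(cc$members), collapse = ","),
                     character(1))))
}

# O(m^2) step-up: q_(i) = min_{j >= i} min(1, p_(j) * m / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

oracle_bonferroni <- function(p) pmin(1, p * length(p))

random_pvals <- function(m) {
  p <- stats::runif(m)
  # sprinkle ties and extremes
  if (m >= 4) p[sample(m, 2)] <- p[sample(m, 1)]
  if (m >= 6) p[sample(m, 1)] <- 0
  p
}

catalogs_equal <- function(a, b) {
  ids_a <- vapply(a$categories, `[[`, character(1), "id")
  ids_b <- vapply(b$categories, `[[`, character(1), "id")
  if (!identical(ids_a, ids_b)) return(FALSE)
  if (!identical(a$universe, b$universe)) return(FALSE)
  all(vapply(ids_a, function(id) {
    ca <- a$categories[[id]]; cb <- b$categories[[id]]
    identical(ca$class_label, cb$class_label) &&
      setequal(ca$members, cb$members)
  }, logical(1)))
}
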