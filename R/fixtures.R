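# Deterministic synthetic-data generators plus the packaged AMI worked
# example. Generators are pure functions of their spec: the seed travels in
# the spec and the caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for synthetic fixtures
#'
#' @param seed Integer RNG seed; identical specs produce identical fixtures.
#' @param n_per_class Categories per class label in [make_random_catalog()].
#' @param size_range Two integers: smallest and largest category size.
#' @param universe_size Size of the synthetic miRNA namespace
#'   (\code{"mir-s1"}, \code{"mir-s2"}, ...).
#' @param n_loci Number of loci from [make_random_loci()].
#' @param n_chrom Number of chromosomes the loci spread over.
#' @return List of class \code{"mirsea_fixture_spec"}.
#' @export
fixture_spec <- function(seed = 1L, n_per_class = 5L, size_range = c(2L, 8L),
                         universe_size = 50L, n_loci = 20L, n_chrom = 3L) {
  if (any(c(n_per_class, size_range, universe_size, n_loci, n_chrom) < 1L)) {
    validation_error("all fixture sizes must be >= 1")
  }
  if (size_range[2] > universe_size) {
    validation_error("category size range exceeds the universe size")
  }
  structure(list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
                 size_range = as.integer(size_range),
                 universe_size = as.integer(universe_size),
                 n_loci = as.integer(n_loci), n_chrom = as.integer(n_chrom)),
            class = "mirsea_fixture_spec")
}

#' Generate a random catalog
#'
#' Samples \code{n_per_class} categories for each of the five class labels,
#' with members drawn from the reserved synthetic namespace \code{"mir-s#"}
#' (which never collides with real miRNA names in mixed tests).
#'
#' @param spec A [fixture_spec()].
#' @return A [catalog()].
#' @export
make_random_catalog <- function(spec) {
  stopifnot(inherits(spec, "mirsea_fixture_spec"))
  universe <- sprintf("mir-s%d", seq_len(spec$universe_size))
  with_seed(spec$seed, {
    cats <- list()
    for (cls in CLASS_LABELS) {
      for (i in seq_len(spec$n_per_class)) {
        size <- sample(seq(spec$size_range[1], spec$size_range[2]), 1L)
        cats[[length(cats) + 1L]] <- category(
          sprintf("%s-%02d", cls, i), cls,
          sample(universe, size), normalize = FALSE)
      }
    }
    catalog(cats)
  })
}

#' Generate random miRNA loci
#'
#' Walks along each chromosome placing short hairpin-sized intervals
#' separated by gaps drawn from a two-component mixture, one component below
#' and one above the clustering boundary, so generated data exercises both
#' sides of the 50 kb rule.
#'
#' @param spec A [fixture_spec()].
#' @param p_short Probability that a gap comes from the short component;
#'   \code{1} forces every gap below the boundary (one cluster per
#'   chromosome), \code{0} forces every gap above it (no clusters).
#' @param short_gap,long_gap Two-element ranges (bp) for the two components.
#'   Defaults straddle 50 kb.
#' @return A [genomic_loci()] table.
#' @export
make_random_loci <- function(spec, p_short = 0.5,
                             short_gap = c(1000, 40000),
                             long_gap = c(60000, 150000)) {
  stopifnot(inherits(spec, "mirsea_fixture_spec"))
  with_seed(spec$seed + 1L, {
    chrom_of <- sort(rep_len(seq_len(spec$n_chrom), spec$n_loci))
    starts <- integer(spec$n_loci); ends <- integer(spec$n_loci)
    pos <- 0L
    for (i in seq_len(spec$n_loci)) {
      if (i > 1L && chrom_of[i] != chrom_of[i - 1L]) pos <- 0L
      gap <- if (pos == 0L) {
        sample(1000:10000, 1L)
      } else if (stats::runif(1) < p_short) {
        sample(short_gap[1]:short_gap[2], 1L)
      } else {
        sample(long_gap[1]:long_gap[2], 1L)
      }
      starts[i] <- pos + gap + 1L
      ends[i] <- starts[i] + sample(60:120, 1L)
      pos <- ends[i]
    }
    genomic_loci(sprintf("mir-s%d", seq_len(spec$n_loci)),
                 sprintf("chr%d", chrom_of), starts, ends,
                 sample(c("+", "-"), spec$n_loci, replace = TRUE))
  })
}

#' Write loci as GFF3
#'
#' @param loci A [genomic_loci()] table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmirsea\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     loci$chrom, loci$start, loci$end, loci$strand,
                     loci$mirna, loci$mirna))
  writeLines(lines, path)
  invisible(path)
}

#' Write a plain-text miRNA list (one name per line)
#'
#' @param mirnas Character vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mirna_list <- function(mirnas, path) {
  writeLines(mirnas, path)
  invisible(path)
}

#' Read a plain-text miRNA list
#'
#' One identifier per line; blank lines and \code{#} comments are skipped.
#' Names are returned raw (normalization happens at analysis time).
#'
#' @param path Input path.
#' @return Character vector.
#' @export
read_mirna_list <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  x <- trimws(sub("\r$", "", readLines(path, warn = FALSE)))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) format_error(sprintf("no miRNA names in %s", path))
  x
}

#' The packaged acute myocardial infarction worked example
#'
#' Sixteen miRNAs deregulated in the myocardium of rats with acute myocardial
#' infarction (AMI) — eight up- and eight downregulated — together with the
#' eleven-member muscle-development category in which two of them (miR-1 and
#' miR-499) fall. The fixture catalog holds the muscle-development set, the
#' two AMI deregulation sets, and synthetic filler categories
#' (\code{"mir-syn###"} namespace) padding the universe to 531 miRNAs — the
#' reference-population size at which the upper-tail p of the
#' muscle-development overlap (HS = 2, S = 11, HP = 16) equals 0.04, the
#' significance this worked example is calibrated to reproduce.
#'
#' @return List with elements \code{up} and \code{down} (8 raw names each),
#'   \code{input} (all 16), \code{muscle_members} (11 raw names),
#'   \code{muscle_category} (a [category()]) and \code{catalog} (a
#'   [catalog()] with universe size 531).
#' @examples
#' fx <- ami_fixture()
#' fit <- mirsea(fx$input, fx$catalog)
#' predict(fit)
#' @export
ami_fixture <- function() {
  up <- c("miR-31", "miR-18a", "miR-18b", "miR-214", "miR-223", "miR-923",
          "miR-711", "miR-199a")
  down <- c("miR-499", "miR-29b", "miR-126", "miR-1", "miR-181d", "miR-181c",
            "miR-451", "miR-26b")
  muscle <- c("miR-1", "miR-499", "miR-24", "miR-124", "miR-133a", "miR-23a",
              "miR-133b", "miR-206", "miR-221", "miR-222", "miR-208b")
  muscle_cat <- category("muscle-development", "function", muscle,
                         display_name = "Muscle development")
  n_real <- length(unique(normalize_name(c(up, down, muscle))))  # 25
  n_filler <- 531L - n_real
  filler <- sprintf("mir-syn%03d", seq_len(n_filler))
  chunks <- split(filler, cut(seq_len(n_filler), 5, labels = FALSE))
  filler_cats <- lapply(seq_along(chunks), function(i) {
    category(sprintf("synthetic-background-%d", i), "disease", chunks[[i]],
             display_name = sprintf("Synthetic background block %d", i),
             normalize = FALSE)
  })
  cl <- catalog(c(
    list(muscle_cat,
         category("ami-upregulated", "disease", up,
                  display_name = "Upregulated in AMI"),
         category("ami-downregulated", "disease", down,
                  display_name = "Downregulated in AMI")),
    filler_cats))
  list(up = up, down = down, input = c(up, down),
       muscle_members = muscle, muscle_category = muscle_cat, catalog = cl)
}
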