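#' Assemble a table of miRNA genomic loci
#'
#' @param mirna Character vector of miRNA names (normalized on construction).
#' @param chrom Chromosome names.
#' @param start,end 1-based inclusive coordinates, \code{start <= end}.
#' @param strand \code{"+"}, \code{"-"} or \code{"."} (unknown).
#' @return A data.frame of class \code{"mirsea_loci"} with columns
#'   \code{mirna}, \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @export
genomic_loci <- function(mirna, chrom, start, end,
                         strand = rep(".", length(mirna))) {
  n <- length(mirna)
  if (length(chrom) != n || length(start) != n || length(end) != n ||
      length(strand) != n) {
    validation_error("locus columns must have equal length")
  }
  if (n == 0L) {
    df <- data.frame(mirna = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     strand = character(0), stringsAsFactors = FALSE)
    class(df) <- c("mirsea_loci", "data.frame")
    return(df)
  }
  start <- as.integer(start); end <- as.integer(end)
  chrom <- as.character(chrom); strand <- as.character(strand)
  if (any(!nzchar(chrom)) || anyNA(chrom)) {
    validation_error("chromosome names must be non-empty")
  }
  if (anyNA(start) || anyNA(end) || any(start < 1L) || any(start > end)) {
    validation_error("need 1 <= start <= end for every locus")
  }
  if (!all(strand %in% c("+", "-", "."))) {
    validation_error("strand must be '+', '-' or '.'")
  }
  key <- normalize_name(mirna)
  if (anyDuplicated(data.frame(key, chrom, start))) {
    validation_error("duplicate (miRNA, chromosome, start) locus")
  }
  df <- data.frame(mirna = key, chrom = chrom, start = start, end = end,
                   strand = strand, stringsAsFactors = FALSE)
  class(df) <- c("mirsea_loci", "data.frame")
  df
}

#' Read miRNA loci from a GFF3 file
#'
#' Coordinates are taken as they appear on disk (GFF3 is 1-based inclusive).
#' The miRNA name comes from the \code{Name} attribute, falling back to
#' \code{ID}.
#'
#' @param path GFF3 file.
#' @param feature Optional feature type filter (e.g. \code{"miRNA_primary_transcript"}).
#' @return A [genomic_loci()] table.
#' @export
read_gff_loci <- function(path, feature = NULL) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) format_error(
                   sprintf("cannot parse GFF3 %s: %s", path, conditionMessage(e))))
  if (!is.null(feature)) gr <- gr[gr$type %in% feature]
  if (length(gr) == 0L) format_error(sprintf("no usable records in %s", path))
  meta <- S4Vectors::mcols(gr)
  nm <- if ("Name" %in% names(meta)) as.character(meta$Name) else rep(NA, length(gr))
  if (anyNA(nm) && "ID" %in% names(meta)) {
    nm[is.na(nm)] <- as.character(meta$ID)[is.na(nm)]
  }
  if (anyNA(nm)) format_error(sprintf("records without Name= or ID= in %s", path))
  genomic_loci(nm, as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr),
               sub("\\*", ".", as.character(GenomicRanges::strand(gr))))
}

#' Build genomic cluster categories from miRNA loci
#'
#' Clusters are the connected components of single-linkage chaining along each
#' chromosome: two loci are linked when the gap between their intervals (bases
#' strictly between the end of the left interval and the start of the right;
#' 0 for touching or overlapping intervals) is at most \code{max_gap}. The
#' default 50 kb follows the classical observation that co-transcribed miRNAs
#' fall within 50 kb of each other. Components with at least two distinct
#' miRNAs become categories of class \code{"cluster"}, each named after its
#' natural-sort first member ("miR-199a cluster" style); singletons are
#' dropped. Output order is deterministic: chromosome (natural order), then
#' leftmost start.
#'
#' @param loci A [genomic_loci()] table.
#' @param max_gap Maximum inter-interval gap in bp to chain across
#'   (inclusive). Default 50000.
#' @param same_strand Chain only loci on the same strand? Default \code{FALSE}
#'   (strand is ignored).
#' @return List of [category()] objects (possibly empty).
#' @export
build_clusters <- function(loci, max_gap = 50000, same_strand = FALSE) {
  if (!inherits(loci, "mirsea_loci")) loci <- do.call(genomic_loci, as.list(loci))
  if (!is.numeric(max_gap) || length(max_gap) != 1L || max_gap < 0) {
    validation_error("max_gap must be a single non-negative number")
  }
  if (nrow(loci) == 0L) return(list())
  gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start, loci$end),
    strand = sub("\\.", "*", loci$strand))
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1,
                               ignore.strand = !same_strand,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  comp <- lapply(seq_along(red), function(i) {
    idx <- revmap[[i]]
    list(members = sort(unique(loci$mirna[idx]), method = "radix"),
         chrom = loci$chrom[idx[1]],
         start = min(loci$start[idx]))
  })
  comp <- Filter(function(cp) length(cp$members) >= 2L, comp)
  if (length(comp) == 0L) return(list())
  chroms <- vapply(comp, `[[`, character(1), "chrom")
  starts <- vapply(comp, `[[`, numeric(1), "start")
  chrom_rank <- match(chroms, unique(chroms[natural_order(chroms)]))
  comp <- comp[order(chrom_rank, starts)]
  ids <- vapply(comp, function(cp) cp$members[natural_order(cp$members)][1],
                character(1))
  ids <- make.unique(paste0(ids, "-cluster"), sep = ".")
  lapply(seq_along(comp), function(i) {
    first <- comp[[i]]$members[natural_order(comp[[i]]$members)][1]
    category(ids[i], "cluster", comp[[i]]$members,
             display_name = paste(display_mirna(first), "cluster"),
             normalize = FALSE)
  })
}

#' Read a miRBase-style family stanza file
#'
#' Parses the miFam dialect: stanzas of \code{AC} (accession), \code{ID}
#' (family name) and \code{MI} (member) lines terminated by \code{//}. The
#' third token of each \code{MI} line is the member miRNA name.
#'
#' @param path miFam-style file.
#' @return data.frame with columns \code{family_id}, \code{family_name},
#'   \code{member} (raw names, one row per membership).
#' @export
read_mifam <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  ac <- NA_character_; id <- NA_character_
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tag <- substr(ln, 1, 2)
    if (tag == "AC") {
      ac <- trimws(substring(ln, 3))
    } else if (tag == "ID") {
      id <- trimws(substring(ln, 3))
    } else if (tag == "MI") {
      toks <- strsplit(trimws(substring(ln, 3)), "[[:space:]]+")[[1]]
      if (length(toks) < 2L) format_error("MI line needs accession and name", line = i)
      if (is.na(id)) format_error("MI line before ID line", line = i)
      out[[length(out) + 1L]] <- data.frame(
        family_id = if (is.na(ac)) id else ac, family_name = id, member = toks[2],
        stringsAsFactors = FALSE)
    } else if (ln == "//") {
      ac <- NA_character_; id <- NA_character_
    }
  }
  if (length(out) == 0L) format_error(sprintf("no family records in %s", path))
  do.call(rbind, out)
}

#' Build family categories from a membership table
#'
#' One category per family with at least two distinct members after
#' normalization (and optional species filtering); singleton families are
#' dropped with a message, since a one-member set can never be informatively
#' enriched and only inflates the multiple-testing burden.
#'
#' @param records data.frame with columns \code{family_id},
#'   \code{family_name} (optional; falls back to \code{family_id}) and
#'   \code{member}, as from [read_mifam()].
#' @param species Optional species prefix (e.g. \code{"hsa"}): keep only
#'   members carrying it before normalization strips it.
#' @return List of [category()] objects with class label \code{"family"}.
#' @export
build_family_sets <- function(records, species = NULL) {
  records <- as.data.frame(records)
  if (!all(c("family_id", "member") %in% names(records))) {
    format_error("family table needs columns family_id and member")
  }
  if (is.null(records$family_name)) records$family_name <- records$family_id
  bad <- which(is.na(records$member) | !nzchar(trimws(records$member)) |
               is.na(records$family_id) | !nzchar(trimws(records$family_id)))
  if (length(bad)) format_error("empty family_id or member", line = bad[1])
  if (!is.null(species)) {
    keep <- grepl(paste0("^", tolower(species), "-"), tolower(records$member))
    records <- records[keep, , drop = FALSE]
  }
  if (nrow(records) == 0L) return(list())
  split_rows <- split(records, records$family_id)
  split_rows <- split_rows[unique(records$family_id)]  # preserve first-seen order
  out <- list()
  for (fam in split_rows) {
    members <- unique(normalize_name(fam$member))
    fname <- fam$family_name[1]
    if (length(members) < 2L) {
      message(sprintf("dropping singleton family '%s'", fname))
      next
    }
    out[[length(out) + 1L]] <- category(
      fname, "family", members,
      display_name = paste(display_mirna(fname), "family"),
      normalize = FALSE)
  }
  out
}

#' Build tissue-specificity categories
#'
#' Retains miRNAs whose tissue specificity index (TSI, in [0, 1]; 1 means
#' expressed in a single tissue) is at or above \code{threshold} — the
#' boundary is inclusive — and groups the retained miRNAs into one category
#' per tissue label. Tissues with no retained miRNA yield no category.
#'
#' @param tsi data.frame with columns \code{mirna} and \code{tsi}.
#' @param grouping data.frame with columns \code{mirna} and \code{tissue}.
#' @param threshold TSI cutoff in [0, 1]; default 0.7.
#' @return List of [category()] objects with class label \code{"tissue"}.
#' @export
build_tissue_sets <- function(tsi, grouping, threshold = 0.7) {
  tsi <- as.data.frame(tsi); grouping <- as.data.frame(grouping)
  if (!all(c("mirna", "tsi") %in% names(tsi))) {
    format_error("TSI table needs columns mirna and tsi")
  }
  if (!all(c("mirna", "tissue") %in% names(grouping))) {
    format_error("grouping table needs columns mirna and tissue")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    validation_error("threshold must lie in [0, 1]")
  }
  vals <- as.numeric(tsi$tsi)
  if (anyNA(vals) || any(vals < 0) || any(vals > 1)) {
    validation_error("TSI values must lie in [0, 1]")
  }
  retained <- normalize_name(tsi$mirna)[vals >= threshold]
  grouping$mirna <- normalize_name(grouping$mirna)
  grouping <- grouping[grouping$mirna %in% retained, , drop = FALSE]
  if (nrow(grouping) == 0L) return(list())
  split_rows <- split(grouping, grouping$tissue)
  split_rows <- split_rows[unique(grouping$tissue)]
  lapply(split_rows, function(g) {
    category(slugify(g$tissue[1]), "tissue", unique(g$mirna),
             display_name = paste(g$tissue[1], "specific"), normalize = FALSE)
  })
}

#' Build function or disease categories from a curated membership table
#'
#' @param records data.frame with columns \code{set_name}, \code{class_label}
#'   (each row \code{"function"} or \code{"disease"}) and \code{member}.
#' @param source_tag Optional provenance string recorded in the display name.
#' @return List of [category()] objects, one per distinct
#'   (\code{set_name}, \code{class_label}) pair, row order preserved.
#' @export
build_annotation_sets <- function(records, source_tag = "") {
  records <- as.data.frame(records)
  if (!all(c("set_name", "class_label", "member") %in% names(records))) {
    format_error("annotation table needs columns set_name, class_label, member")
  }
  bad <- which(is.na(records$member) | !nzchar(trimws(records$member)))
  if (length(bad)) format_error("empty member column", line = bad[1])
  if (!all(records$class_label %in% c("function", "disease"))) {
    format_error("class_label must be 'function' or 'disease'")
  }
  grp_key <- paste(records$set_name, records$class_label, sep = "\r")
  split_rows <- split(records, grp_key)
  split_rows <- split_rows[unique(grp_key)]
  out <- lapply(split_rows, function(g) {
    disp <- g$set_name[1]
    if (nzchar(source_tag)) disp <- sprintf("%s (%s)", disp, source_tag)
    category(slugify(g$set_name[1]), g$class_label[1], unique(g$member),
             display_name = disp)
  })
  names(out) <- NULL
  ids <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    for (i in which(duplicated(ids) | duplicated(ids, fromLast = TRUE))) {
      out[[i]]$id <- paste(out[[i]]$id, out[[i]]$class_label, sep = ".")
    }
  }
  out
}

slugify <- function(x) {
  s <- gsub("[^a-z0-9]+", "-", tolower(trimws(x)))
  gsub("^-|-$", "", s)
}

#' Merge catalogs into one
#'
#' Concatenates the categories of several catalogs (e.g. the five builder
#' outputs) and recomputes the universe. Colliding category ids are
#' disambiguated by suffixing the class label, then a counter.
#'
#' @param parts Non-empty list of [catalog()] objects.
#' @return A single [catalog()].
#' @export
merge_catalogs <- function(parts) {
  if (!is.list(parts) || length(parts) == 0L) {
    validation_error("need at least one catalog to merge")
  }
  ok <- vapply(parts, inherits, logical(1), what = "mirsea_catalog")
  if (!all(ok)) validation_error("all parts must be mirsea_catalog objects")
  cats <- unlist(lapply(parts, `[[`, "categories"), recursive = FALSE,
                 use.names = FALSE)
  ids <- vapply(cats, `[[`, character(1), "id")
  dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
  if (any(dup)) {
    for (i in which(dup)) {
      cats[[i]]$id <- paste(cats[[i]]$id, cats[[i]]$class_label, sep = ".")
    }
    ids <- vapply(cats, `[[`, character(1), "id")
    ids <- make.unique(ids, sep = ".")
    for (i in seq_along(cats)) cats[[i]]$id <- ids[i]
  }
  catalog(cats)
}
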