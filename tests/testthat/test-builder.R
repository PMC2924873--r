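test_that("gap-based chaining links loci at or below the distance cutoff", {
  loci <- genomic_loci(c("mir-a", "mir-b", "mir-c"), rep("chr1", 3),
                       c(1000, 45000, 120000), c(1100, 45100, 120100),
                       rep("+", 3))
  # gaps: 43899 bp (chained at 50 kb) and 74899 bp (not chained)
  cats <- build_clusters(loci, max_gap = 50000)
  expect_length(cats, 1L)
  expect_setequal(cats[[1]]$members, c("mir-a", "mir-b"))
  expect_identical(cluster_partition_of(cats),
                   oracle_cluster_partition(loci, 50000))

  # a single locus can never form a cluster
  expect_length(build_clusters(loci[1, , drop = FALSE]), 0L)
})

test_that("the distance cutoff is inclusive at exactly 50,000 bp", {
  # gap = start2 - end1 - 1 = 51101 - 1100 - 1 = 50000
  loci <- genomic_loci(c("mir-a", "mir-b"), c("chr1", "chr1"),
                       c(1000, 51101), c(1100, 51200))
  expect_length(build_clusters(loci, max_gap = 50000), 1L)
  # one base further and the chain breaks
  loci2 <- genomic_loci(c("mir-a", "mir-b"), c("chr1", "chr1"),
                        c(1000, 51102), c(1100, 51201))
  expect_length(build_clusters(loci2, max_gap = 50000), 0L)
})

test_that("cluster partitions match a brute-force components oracle and ignore input order", {
  for (seed in 1:4) {
    spec <- fixture_spec(seed = seed, n_loci = 28, n_chrom = 3)
    loci <- make_random_loci(spec, p_short = 0.6)
    for (max_gap in c(0, 10000, 50000, 100000)) {
      got <- cluster_partition_of(build_clusters(loci, max_gap = max_gap))
      expect_identical(got, oracle_cluster_partition(loci, max_gap),
                       label = sprintf("seed %d gap %d", seed, max_gap))
    }
    # permuting rows never changes the partition
    set.seed(seed + 100)
    shuffled <- loci[sample(nrow(loci)), , drop = FALSE]
    expect_identical(
      cluster_partition_of(build_clusters(shuffled, max_gap = 50000)),
      cluster_partition_of(build_clusters(loci, max_gap = 50000)))
  }
})

test_that("enlarging the gap only ever merges clusters", {
  loci <- make_random_loci(fixture_spec(seed = 11, n_loci = 24, n_chrom = 2),
                           p_short = 0.5)
  gaps <- c(5000, 20000, 50000, 80000, 200000)
  parts <- lapply(gaps, function(g) {
    lapply(build_clusters(loci, max_gap = g), `[[`, "members")
  })
  for (i in seq_along(gaps)[-1]) {
    for (small_set in parts[[i - 1]]) {
      containing <- Filter(function(big) all(small_set %in% big), parts[[i]])
      expect_length(containing, 1L)
    }
  }
})

test_that("strand-aware chaining separates opposite strands", {
  loci <- genomic_loci(c("mir-a", "mir-b", "mir-c"), rep("chr1", 3),
                       c(1000, 2000, 3000), c(1100, 2100, 3100),
                       c("+", "-", "+"))
  expect_length(build_clusters(loci, max_gap = 50000), 1L)  # strand ignored
  strict <- build_clusters(loci, max_gap = 50000, same_strand = TRUE)
  expect_length(strict, 1L)
  expect_setequal(strict[[1]]$members, c("mir-a", "mir-c"))
  expect_identical(cluster_partition_of(strict),
                   oracle_cluster_partition(loci, 50000, same_strand = TRUE))
})

test_that("clusters are named after their natural-sort first member and ordered genomically", {
  loci <- genomic_loci(c("mir-21", "mir-9", "mir-100", "mir-3"),
                       c("chr2", "chr2", "chr1", "chr1"),
                       c(5000, 1000, 9000, 1000),
                       c(5100, 1100, 9100, 1100))
  cats <- build_clusters(loci, max_gap = 50000)
  expect_length(cats, 2L)
  expect_identical(cats[[1]]$id, "mir-3-cluster")       # chr1 first
  expect_identical(cats[[1]]$display_name, "miR-3 cluster")
  expect_identical(cats[[2]]$id, "mir-9-cluster")       # mir-9 < mir-21 naturally
})

test_that("duplicate loci are rejected", {
  expect_error(
    genomic_loci(c("mir-a", "mir-a"), c("chr1", "chr1"),
                 c(100, 100), c(200, 300)),
    class = "mirsea_validation_error")
  expect_error(genomic_loci("mir-a", "chr1", 0, 10),
               class = "mirsea_validation_error")
  expect_error(genomic_loci("mir-a", "chr1", 100, 10),
               class = "mirsea_validation_error")
})

test_that("GFF3 loci round-trip and feed the cluster builder", {
  loci <- make_random_loci(fixture_spec(seed = 5, n_loci = 12, n_chrom = 2))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_loci_gff3(loci, gff)
  back <- read_gff_loci(gff)
  ord <- order(back$mirna)
  ord0 <- order(loci$mirna)
  expect_identical(back$start[ord], loci$start[ord0])
  expect_identical(back$end[ord], loci$end[ord0])
  expect_identical(back$chrom[ord], loci$chrom[ord0])
  expect_identical(
    cluster_partition_of(build_clusters(back, max_gap = 50000)),
    cluster_partition_of(build_clusters(loci, max_gap = 50000)))
})

test_that("family sets keep multi-member families and drop singletons", {
  records <- data.frame(
    family_id = c(rep("MIPF1", 4), "MIPF2", rep("MIPF3", 2)),
    family_name = c(rep("mir-181", 4), "mir-lonely", rep("mir-29", 2)),
    member = c("hsa-miR-181a", "hsa-miR-181b", "hsa-miR-181c", "hsa-miR-181d",
               "hsa-miR-999", "hsa-miR-29a", "hsa-miR-29a"))
  msgs <- capture_messages(cats <- build_family_sets(records))
  expect_true(any(grepl("singleton", msgs)))
  # mir-lonely is a singleton; mir-29 collapses to one member after dedup
  expect_length(cats, 1L)
  expect_identical(cats[[1]]$id, "mir-181")
  expect_identical(cats[[1]]$display_name, "miR-181 family")
  expect_length(cats[[1]]$members, 4L)
})

test_that("species filtering restricts family membership before normalization", {
  records <- data.frame(
    family_id = rep("MIPF1", 4), family_name = rep("mir-17", 4),
    member = c("hsa-miR-17", "hsa-miR-20a", "mmu-miR-17", "mmu-miR-93"))
  hsa <- suppressMessages(build_family_sets(records, species = "hsa"))
  expect_setequal(hsa[[1]]$members, c("mir-17", "mir-20a"))
  all_species <- build_family_sets(records)
  expect_setequal(all_species[[1]]$members, c("mir-17", "mir-20a", "mir-93"))
})

test_that("miFam stanza files parse into family records", {
  mifam <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("AC   MIPF0000001", "ID   mir-17",
               "MI   MI0000071  hsa-mir-17", "MI   MI0000093  hsa-mir-20a",
               "//",
               "AC   MIPF0000002", "ID   mir-181",
               "MI   MI0000269  hsa-mir-181a", "MI   MI0000270  hsa-mir-181b",
               "//"), mifam)
  rec <- read_mifam(mifam)
  expect_identical(nrow(rec), 4L)
  expect_setequal(unique(rec$family_name), c("mir-17", "mir-181"))
  cats <- build_family_sets(rec)
  expect_length(cats, 2L)
})

test_that("tissue sets apply the TSI threshold inclusively", {
  tsi <- data.frame(mirna = c("miR-1", "miR-21", "miR-124"),
                    tsi = c(0.9, 0.3, 0.7))
  grouping <- data.frame(mirna = c("miR-1", "miR-21", "miR-124"),
                         tissue = c("heart", "liver", "brain"))
  cats <- build_tissue_sets(tsi, grouping, threshold = 0.7)
  expect_length(cats, 2L)
  got <- lapply(cats, `[[`, "members")
  names(got) <- vapply(cats, `[[`, character(1), "id")
  expect_identical(got$heart, "mir-1")
  expect_identical(got$brain, "mir-124")  # 0.7 itself is retained
  expect_length(build_tissue_sets(tsi, grouping, threshold = 1.0), 0L)
  expect_error(build_tissue_sets(data.frame(mirna = "miR-1", tsi = 1.2),
                                 grouping),
               class = "mirsea_validation_error")
})

test_that("tissue membership equals a naive filter for random tables", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 40
    tsi <- data.frame(mirna = sprintf("mir-s%d", 1:n),
                      tsi = round(stats::runif(n), 2))
    grouping <- data.frame(mirna = tsi$mirna,
                           tissue = sample(c("heart", "brain", "liver"), n,
                                           replace = TRUE))
    for (thr in c(0, 0.5, 0.7, 1)) {
      cats <- build_tissue_sets(tsi, grouping, threshold = thr)
      got <- as.character(unlist(lapply(cats, `[[`, "members")))
      naive <- as.character(grouping$mirna[tsi$tsi >= thr])
      expect_setequal(got, naive)
    }
  }
})

test_that("annotation sets union rows per set name and record provenance", {
  fx <- ami_fixture()
  records <- data.frame(set_name = "Muscle development",
                        class_label = "function",
                        member = fx$muscle_members)
  cats <- build_annotation_sets(records, source_tag = "curated review")
  expect_length(cats, 1L)
  expect_length(cats[[1]]$members, 11L)
  expect_match(cats[[1]]$display_name, "curated review")

  # duplicated rows count once; shuffled rows give the same catalog
  dup <- rbind(records, records[1, ])
  expect_length(build_annotation_sets(dup)[[1]]$members, 11L)
  set.seed(1)
  shuffled <- records[sample(nrow(records)), ]
  expect_true(catalogs_equal(catalog(build_annotation_sets(records)),
                             catalog(build_annotation_sets(shuffled))))
  expect_error(build_annotation_sets(
    data.frame(set_name = "x", class_label = "function", member = "")),
    class = "mirsea_format_error")
  expect_error(build_annotation_sets(
    data.frame(set_name = "x", class_label = "pathway", member = "miR-1")),
    class = "mirsea_format_error")
})

test_that("merging catalogs sums categories, unions the universe, and resolves id collisions", {
  fam <- catalog(list(category("setX", "family", c("mir-1", "mir-2"),
                               normalize = FALSE)))
  clu <- catalog(list(category("setX", "cluster", c("mir-2", "mir-3"),
                               normalize = FALSE),
                      category("setY", "cluster", c("mir-4", "mir-5"),
                               normalize = FALSE)))
  merged <- merge_catalogs(list(fam, clu))
  expect_identical(length(merged), 3L)
  expect_length(merged$universe, 5L)  # mir-2 counted once
  ids <- vapply(merged$categories, `[[`, character(1), "id")
  expect_setequal(ids, c("setX.family", "setX.cluster", "setY"))

  # five generated class catalogs keep their per-class counts
  parts <- lapply(1:5, function(s) {
    make_random_catalog(fixture_spec(seed = s, n_per_class = 3))
  })
  big <- merge_catalogs(parts)
  counts <- table(vapply(big$categories, `[[`, character(1), "class_label"))
  expect_true(all(counts == 15L))
})
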