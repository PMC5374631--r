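make_test_genome <- function(len = 4000L, seed = 61L) {
  withr::with_seed(seed, {
    genome_source(c(
      chrA = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
      chrB = paste(sample(c("A", "C", "G", "T"), len / 2, TRUE),
                   collapse = "")))
  })
}

test_that("random negative sampling respects length, exclusions and seeds", {
  genome <- make_test_genome()
  exclude <- region_table(rbp = "X", chrom = "chrA",
                          start = c(100, 500), end = c(200, 600),
                          affinity = 1, strand = "+")
  negs <- sample_negatives_random(genome, n = 50, length = 25,
                                  exclude = exclude, seed = 7)
  expect_length(negs, 50L)
  expect_true(all(nchar(record_sequences(negs)) == 25))
  expect_true(all(record_labels(negs) == "negative"))
  for (r in negs) {
    o <- r$origin
    if (o$chrom == "chrA") {
      expect_false(any(o$start < exclude$end & o$end > exclude$start))
    }
  }
  again <- sample_negatives_random(genome, n = 50, length = 25,
                                   exclude = exclude, seed = 7)
  expect_identical(record_sequences(again), record_sequences(negs))
  other <- sample_negatives_random(genome, n = 50, length = 25,
                                   exclude = exclude, seed = 8)
  expect_false(identical(record_sequences(other), record_sequences(negs)))
})

test_that("random negative sampling fails cleanly when the genome is exhausted", {
  tiny <- genome_source(c(chr = "ACGTACGTAC"))
  blockall <- region_table(rbp = "X", chrom = "chr", start = 0, end = 10,
                           affinity = 1, strand = "+")
  expect_error(sample_negatives_random(tiny, n = 3, length = 5,
                                       exclude = blockall, seed = 1),
               "admissible")
  expect_error(sample_negatives_random(tiny, n = 1, length = 50, seed = 1),
               "too short")
})

test_that("upstream negatives sit exactly at the requested distance", {
  genome <- make_test_genome()
  pos <- region_table(rbp = "QKI", chrom = "chrA", start = 100, end = 125,
                      affinity = 0.95, strand = "+")
  neg <- sample_negatives_upstream(pos, genome, distance = 1)
  expect_length(neg, 1L)
  expect_equal(neg[[1]]$origin$start, 74)
  expect_equal(neg[[1]]$origin$end, 99)
  expect_equal(neg[[1]]$rbp, "QKI")

  # never overlaps the positive region for any admissible distance >= 1
  for (d in c(1, 10, 60)) {
    n <- sample_negatives_upstream(pos, genome, distance = d)[[1]]$origin
    expect_true(n$end < 100)
  }

  # minus strand: upstream lies at larger coordinates
  posm <- region_table(rbp = "QKI", chrom = "chrA", start = 100, end = 125,
                       affinity = 0.95, strand = "-")
  nm <- sample_negatives_upstream(posm, genome, distance = 1)[[1]]$origin
  expect_equal(nm$start, 126)
  expect_equal(nm$end, 151)

  # falling off the chromosome start is skipped with a warning
  edge <- region_table(rbp = "QKI", chrom = "chrA", start = 10, end = 35,
                       affinity = 0.95, strand = "+")
  expect_warning(none <- sample_negatives_upstream(edge, genome, 1),
                 "skipping")
  expect_length(none, 0L)
})

test_that("redundancy filtering drops near-duplicates and keeps distinct sequences", {
  base <- "ACUGUCUGGUUCGUUUUACAUAAUA"
  m4 <- "ACUGUCUGAUUCGUUUUGCAUUAUG"    # 4 mismatches, identity 0.84
  m10 <- "CCAAGCUUGACCGUCUUACAUACUG"   # 10 mismatches, identity < 0.8
  recs <- list(seq_record("base", base), seq_record("dup", base),
               seq_record("near", m4), seq_record("far", m10))
  surv <- redundancy_filter(recs, threshold = 0.8)
  expect_equal(vapply(surv, function(r) r$id, character(1)),
               c("base", "far"))

  # idempotence
  expect_identical(record_sequences(redundancy_filter(surv, 0.8)),
                   record_sequences(surv))

  # two-set mode: drops members similar to the reference set
  surv2 <- redundancy_filter(list(seq_record("near", m4),
                                  seq_record("far", m10)),
                             threshold = 0.8,
                             reference = list(seq_record("ref", base)))
  expect_equal(vapply(surv2, function(r) r$id, character(1)), "far")
})

test_that("ratio datasets nest their negatives and match their descriptors", {
  set.seed(62)
  pos <- lapply(1:10, function(i)
    seq_record(paste0("p", i), rand_rna(25), label = "positive"))
  pool <- lapply(1:60, function(i)
    seq_record(paste0("n", i), rand_rna(25), label = "negative"))
  sets <- make_ratio_datasets(pos, pool, ratios = c(1, 2, 4), seed = 3)
  expect_named(sets, c("1:1", "1:2", "1:4"))
  for (r in c(1, 2, 4)) {
    s <- sets[[paste0("1:", r)]]
    expect_equal(s$n_positive, 10L)
    expect_equal(s$n_negative, 10L * r)
  }
  ids <- function(s) sort(vapply(
    s$records[record_labels(s$records) == "negative"],
    function(r) r$id, character(1)))
  expect_true(all(ids(sets[["1:1"]]) %in% ids(sets[["1:2"]])))
  expect_true(all(ids(sets[["1:2"]]) %in% ids(sets[["1:4"]])))

  expect_error(make_ratio_datasets(pos, pool, ratios = c(1, 10), seed = 3),
               "pool")
})

test_that("train/test splits are stratified, disjoint and reproducible", {
  set <- synth_generate(n_pos = 100, n_neg = 100, n_groups = 4, seed = 63)
  sp <- split_train_test(set, fraction = 0.7, seed = 64)
  train_ids <- vapply(sp$train$records, function(r) r$id, character(1))
  test_ids <- vapply(sp$test$records, function(r) r$id, character(1))
  expect_length(intersect(train_ids, test_ids), 0L)
  expect_setequal(c(train_ids, test_ids),
                  vapply(set$records, function(r) r$id, character(1)))
  expect_equal(sp$train$n_positive, 70L)
  expect_equal(sp$train$n_negative, 70L)

  sp2 <- split_train_test(set, fraction = 0.7, seed = 64)
  expect_identical(sort(vapply(sp2$train$records, function(r) r$id,
                               character(1))), sort(train_ids))

  lone <- labeled_set(c(set$records[1:20],
                        list(seq_record("solo", rand_rna(25),
                                        label = "negative", rbp = "Z"))))
  expect_warning(sp3 <- split_train_test(lone, 0.7, seed = 65), "wholly")
  expect_true("solo" %in% vapply(sp3$train$records, function(r) r$id,
                                 character(1)))
})

test_that("synthetic generation is reproducible with valid sequences and group tags", {
  set <- synth_generate(n_pos = 30, n_neg = 40, n_groups = 5, seed = 66)
  seqs <- record_sequences(set$records)
  expect_true(all(nchar(seqs) == 25))
  expect_true(all(grepl("^[ACGU]+$", seqs)))
  expect_equal(set$n_positive, 30L)
  expect_equal(set$n_negative, 40L)
  expect_equal(sort(unique(record_rbps(set$records))),
               sprintf("RBP%02d", 1:5))
  expect_identical(record_sequences(
    synth_generate(n_pos = 30, n_neg = 40, n_groups = 5, seed = 66)$records),
    seqs)
  expect_false(identical(record_sequences(
    synth_generate(n_pos = 30, n_neg = 40, n_groups = 5, seed = 67)$records),
    seqs))
})

test_that("an uninformative motif model yields chance-level classification", {
  null_set <- synth_generate(motif_model_null(), n_pos = 250, n_neg = 250,
                             n_groups = 4, seed = 68)
  res <- kfold_cv(null_set, k = 5, seed = 69)
  expect_lt(abs(res$metrics$mcc), 0.1)
  expect_lt(abs(res$roc$auc - 0.5), 0.08)
})

test_that("labeled sets round-trip through FASTA plus sidecar", {
  set <- synth_generate(n_pos = 10, n_neg = 10, n_groups = 2, seed = 70)
  fasta <- tempfile(fileext = ".fasta")
  write_labeled_set(set, fasta)
  back <- read_labeled_set(fasta)
  expect_identical(record_sequences(back$records),
                   record_sequences(set$records))
  expect_identical(record_labels(back$records),
                   record_labels(set$records))
  expect_identical(record_rbps(back$records), record_rbps(set$records))
})
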