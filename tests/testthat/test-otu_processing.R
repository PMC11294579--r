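test_that("extraction replicates are summed into PCR replicates and totals conserved", {
  # two extraction columns per PCR replicate for one sample
  meta <- data.frame(
    replicate_id = c("S1.e1.p1", "S1.e2.p1", "S1.e1.p2", "S1.e2.p2",
                     "S1.e1.p3", "S1.e2.p3"),
    sample_id = "S1", method = "bulk", replicate_kind = "extraction",
    replicate_index = rep(1:3, each = 2), is_control = FALSE,
    stringsAsFactors = FALSE)
  counts <- matrix(c(40, 60, 5, 0, 1, 2), nrow = 1,
                   dimnames = list("OTU1", meta$replicate_id))
  m <- read_matrix(counts, meta)
  merged <- merge_extraction_replicates(m)
  expect_equal(ncol(merged$counts), 3L)
  expect_equal(unname(merged$counts[1, "S1.pcr1"]), 100)
  expect_true(all(merged$meta$replicate_kind[!merged$meta$is_control] == "pcr"))

  # single extraction replicate per cell: identity
  single <- toy_matrix(matrix(1:6, 2), "S1")
  expect_identical(merge_extraction_replicates(single)$counts, single$counts)

  # conservation oracle over random matrices
  set.seed(42)
  for (i in 1:100) {
    n_otu <- sample(2:10, 1)
    n_ext <- sample(1:3, 1)
    meta <- expand.grid(ext = seq_len(n_ext), pcr = 1:3)
    meta <- data.frame(
      replicate_id = sprintf("S1.e%d.p%d", meta$ext, meta$pcr),
      sample_id = "S1", method = "bulk", replicate_kind = "extraction",
      replicate_index = meta$pcr, is_control = FALSE)
    cnt <- matrix(rpois(n_otu * nrow(meta), 5), n_otu,
                  dimnames = list(sprintf("OTU%d", 1:n_otu), meta$replicate_id))
    m <- read_matrix(cnt, meta)
    expect_equal(sum(merge_extraction_replicates(m)$counts), sum(cnt))
  }
})

test_that("merging rejects mixed methods and non-integer counts", {
  meta <- data.frame(
    replicate_id = c("a", "b"), sample_id = "S1",
    method = c("bulk", "edna"), replicate_kind = "extraction",
    replicate_index = 1L, is_control = FALSE)
  cnt <- matrix(1, 1, 2, dimnames = list("OTU1", meta$replicate_id))
  expect_error(read_matrix(cnt, meta), "mixed methods")
  m <- toy_matrix(matrix(1:3, 1), "S1")
  m$counts[1, 1] <- 1.5
  expect_error(merge_extraction_replicates(m), "integer")
})

test_that("replicate-consistency filter applies the retention rule per sample", {
  bulk <- consistency_policy("bulk")
  edna <- consistency_policy("edna")
  m <- toy_matrix(matrix(c(10, 0, 5), 1), "S1")
  expect_true(all(filter_replicate_consistency(m, bulk)$counts == 0))
  m2 <- toy_matrix(matrix(c(3, 2, 8), 1), "S1")
  expect_identical(filter_replicate_consistency(m2, edna)$counts, m2$counts)

  # exhaustive 8-pattern oracle for both policies
  patterns <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (pol in list(bulk = bulk, edna = edna)) {
    for (i in seq_len(nrow(patterns))) {
      pat <- patterns[i, ] * 7L     # presence encoded as 7 reads
      m <- toy_matrix(matrix(pat, 1), "S1")
      kept <- any(filter_replicate_consistency(m, pol)$counts > 0)
      expect_identical(kept, sum(patterns[i, ]) >= pol$min_replicates_present)
    }
  }

  # decisions are per sample, not global
  m3 <- toy_matrix(matrix(c(5, 5, 5, 9, 0, 0), 1), c("S1", "S2"))
  f <- filter_replicate_consistency(m3, bulk)
  expect_true(all(f$counts[1, 1:3] == c(5, 5, 5)))
  expect_true(all(f$counts[1, 4:6] == 0))

  # wrong replicate count errors naming the sample
  meta <- data.frame(replicate_id = c("S9.p1", "S9.p2"), sample_id = "S9",
                     method = "bulk", replicate_kind = "pcr",
                     replicate_index = 1:2, is_control = FALSE)
  cnt <- matrix(1, 1, 2, dimnames = list("OTU1", meta$replicate_id))
  expect_error(filter_replicate_consistency(read_matrix(cnt, meta), bulk), "S9")
})

test_that("taxon-level consistency pools presence across OTUs of one taxon", {
  # two OTUs of the same species, each alone in <2 replicates, jointly in 2
  m <- toy_matrix(matrix(c(4, 0, 0,
                           0, 5, 0), 2, byrow = TRUE), "S1")
  tax <- toy_taxonomy(rownames(m$counts),
                      species = c("Baetella una", "Baetella una"))
  edna <- consistency_policy("edna")
  expect_true(all(filter_replicate_consistency(m, edna)$counts == 0))
  kept <- filter_replicate_consistency(m, edna, level = "taxon", taxonomy = tax)
  expect_identical(kept$counts, m$counts)
})

test_that("negative-control subtraction floors at zero and drops controls", {
  m <- toy_matrix(matrix(c(100, 100, 100,
                           20, 20, 20,
                           9, 9, 9), 3, byrow = TRUE), "S1",
                  control_counts = matrix(c(30, 10,
                                            30, 5,
                                            0, 0), 3, byrow = TRUE))
  sub_max <- subtract_negative_controls(m, "max")
  expect_equal(unname(sub_max$counts[1, ]), rep(70, 3))
  expect_equal(unname(sub_max$counts[2, ]), rep(0, 3))   # floored
  expect_equal(unname(sub_max$counts[3, ]), rep(9, 3))   # absent from controls
  expect_equal(sum(sub_max$meta$is_control), 0L)
  sub_sum <- subtract_negative_controls(m, "sum")
  expect_equal(unname(sub_sum$counts[1, ]), rep(60, 3))

  no_ctrl <- toy_matrix(matrix(1:3, 1), "S1")
  expect_warning(out <- subtract_negative_controls(no_ctrl), "no control")
  expect_identical(out$counts, no_ctrl$counts)
})

test_that("presence/absence condenses OTUs by best-rank taxon", {
  m <- toy_matrix(matrix(c(5, 5, 5,
                           9, 9, 9,
                           0, 0, 0), 3, byrow = TRUE), "S1")
  tax <- toy_taxonomy(rownames(m$counts),
                      species = c("Baetella x", "Baetella x", "Baetella y"))
  lists <- to_presence_absence(m, tax)
  expect_equal(nrow(lists$S1), 1L)
  expect_equal(lists$S1$taxon, "Baetella x")
  expect_equal(lists$S1$otu_ids, "OTU001,OTU002")

  # all-zero sample gives an empty list
  zero <- toy_matrix(matrix(0, 2, 3), "S1")
  expect_equal(nrow(to_presence_absence(zero, toy_taxonomy(rownames(zero$counts)))$S1), 0L)

  # OTU without taxonomy errors listing the id
  expect_error(to_presence_absence(m, tax[-2, ]), "OTU002")
})

test_that("condensation is idempotent through a 0/1 round trip", {
  set.seed(7)
  for (i in 1:20) {
    m <- random_matrix(n_otu = 15)
    tax <- toy_taxonomy(rownames(m$counts))
    once <- to_presence_absence(m, tax)
    m01 <- m
    m01$counts <- (m$counts > 0) + 0
    twice <- to_presence_absence(m01, tax)
    expect_identical(lapply(once, as.data.frame), lapply(twice, as.data.frame))
  }
})

test_that("filters never increase counts and are idempotent", {
  set.seed(9)
  for (i in 1:20) {
    m <- random_matrix(n_otu = 25, n_controls = 2)
    pol <- consistency_policy(sample(1:3, 1), 3L)
    f1 <- filter_replicate_consistency(m, pol)
    expect_true(all(f1$counts <= m$counts))
    expect_identical(filter_replicate_consistency(f1, pol)$counts, f1$counts)
    s1 <- subtract_negative_controls(m)
    expect_true(all(s1$counts >= 0))
    expect_true(all(s1$counts <= m$counts[, colnames(s1$counts)]))
    expect_identical(suppressWarnings(subtract_negative_controls(s1))$counts,
                     s1$counts)
  }
})

test_that("pipeline applies merge, consistency and subtraction in the documented order", {
  # counts (1,1,5) with a blank reading 1: consistency-first keeps the OTU
  # (present 3/3, then subtraction leaves (0,0,4)); subtraction-first
  # removes it (post-subtraction presence 1/3)
  m <- toy_matrix(matrix(c(1, 1, 5), 1), "S1",
                  control_counts = matrix(1, 1, 1))
  tax <- toy_taxonomy("OTU001")
  default_order <- filter_pipeline(m, "bulk", tax)
  expect_equal(default_order$taxa_lists$S1$taxon, "Baetella a")
  swapped <- filter_pipeline(m, "bulk", tax, subtract_first = TRUE)
  expect_equal(nrow(swapped$taxa_lists$S1), 0L)

  # an OTU fully wiped by subtraction never reaches the presence/absence list
  m2 <- toy_matrix(matrix(c(2, 2, 2), 1), "S1",
                   control_counts = matrix(5, 1, 1))
  expect_equal(nrow(filter_pipeline(m2, "bulk", tax)$taxa_lists$S1), 0L)
})
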