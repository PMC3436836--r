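# RFC matrix, rule mining, identity baseline

two_class_alignment <- function(rows_p, rows_m) {
  labeled_alignment(sprintf("s%02d", seq_len(length(rows_p) + length(rows_m))),
                    c(rows_p, rows_m),
                    c(rep(1L, length(rows_p)), rep(0L, length(rows_m))))
}

test_that("compute_rfc reproduces the count formula and its symmetries", {
  # 10+10 rows, column 5 always K in + and always E in -, rest identical
  base <- "AAAA%sAAAAA"
  aln <- two_class_alignment(rep(sprintf(base, "K"), 10),
                             rep(sprintf(base, "E"), 10))
  rfc <- compute_rfc(aln, pseudocount = 1)
  expect_equal(unname(rfc$M["K", 5]), log(11), tolerance = 1e-12)   # ln((11/31)/(1/31))
  expect_equal(unname(rfc$M["E", 5]), -log(11), tolerance = 1e-12)
  expect_equal(unname(rfc$M["A", 1]), 0)
  # per-class column distributions normalize over residues + gap
  expect_equal(colSums(rfc$P_plus), rep(1, aln$L), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(colSums(rfc$P_minus), rep(1, aln$L), tolerance = 1e-9,
               ignore_attr = TRUE)

  # identical class contents give the zero matrix
  same <- two_class_alignment(c("AKLM", "GGGG"), c("AKLM", "GGGG"))
  expect_true(all(compute_rfc(same)$M == 0))

  # label swap negates M elementwise
  aln_sw <- aln
  aln_sw$labels <- 1L - aln$labels
  expect_equal(compute_rfc(aln_sw)$M, -rfc$M, tolerance = 1e-12)

  # one empty class is an error
  one <- labeled_alignment(c("a", "b"), c("AAAA", "AAAA"), c(1, 1))
  expect_error(compute_rfc(one), "both classes")
})

test_that("rfc_score sums evidence over non-gap positions", {
  aln <- two_class_alignment(rep("AKAA", 5), rep("AEAA", 5))
  rfc <- compute_rfc(aln)
  # zero matrix -> zero score
  rfc0 <- rfc
  rfc0$M[] <- 0
  expect_equal(rfc_score(rfc0, "KKKK"), 0)
  # additivity over a column partition
  s <- "KEAA"
  total <- rfc_score(rfc, s)
  r1 <- list(start = 1, length = 2)
  r2 <- list(start = 3, length = 2)
  parts <- subseq_features(list(r1, r2), rfc, s)
  expect_equal(sum(parts), total, tolerance = 1e-12)
  # gaps contribute nothing
  expect_equal(rfc_score(rfc, "-E--"), unname(rfc$M["E", 2]))
  expect_error(rfc_score(rfc, "AAAAA"), "length")
})

test_that("mine_subseq_rules returns 25 deterministic rules of length 3-6", {
  aln <- planted_motif_alignment(seed = 3)
  rules <- mine_subseq_rules(aln, seed = 42)
  expect_length(rules, 25)
  expect_true(all(vapply(rules, `[[`, numeric(1), "length") %in% 3:6))
  expect_true(all(vapply(rules, function(r) r$start + r$length - 1,
                         numeric(1)) <= aln$L))
  # ranked by decreasing mean potential score
  rs <- vapply(rules, `[[`, numeric(1), "rank_score")
  expect_true(all(diff(rs) <= 1e-12))

  # bit-reproducible under the same seed, and RNG state is restored
  set.seed(123)
  before <- .Random.seed
  again <- mine_subseq_rules(aln, seed = 42)
  expect_identical(rules, again)
  expect_identical(.Random.seed, before)

  # the top rule localizes the planted motif (10 quick seeded runs)
  motif <- attr(aln, "motif")
  motif_cols <- motif$start:(motif$start + motif$length - 1)
  hits <- vapply(1:10, function(s) {
    top <- mine_subseq_rules(aln, seed = s)[[1]]
    any(top$start:(top$start + top$length - 1) %in% motif_cols)
  }, logical(1))
  expect_true(all(hits))

  expect_error(mine_subseq_rules(aln, lengths = (aln$L + 1):(aln$L + 2)),
               "degenerate")
  expect_error(mine_subseq_rules(aln, n_rules = 10000), "candidate")
})

test_that("rule features equal windowed rfc_score and respect gaps", {
  aln <- planted_motif_alignment(seed = 9)
  rfc <- compute_rfc(aln)
  rules <- mine_subseq_rules(aln, n_rules = 5, seed = 9)
  s <- aln$rows[1]
  fv <- subseq_features(rules, rfc, s)
  expect_length(fv, 5)
  for (j in seq_along(rules)) {
    r <- rules[[j]]
    chars <- strsplit(s, "")[[1]]
    masked <- chars
    masked[setdiff(seq_len(aln$L), r$start:(r$start + r$length - 1))] <- "-"
    expect_equal(unname(fv[j]), rfc_score(rfc, paste(masked, collapse = "")),
                 tolerance = 1e-12)
  }
  # all-gap window scores 0
  gap_seq <- paste(rep("-", aln$L), collapse = "")
  expect_equal(unname(subseq_features(rules, rfc, gap_seq)),
               rep(0, 5))
  bad <- list(list(start = aln$L, length = 6))
  expect_error(subseq_features(bad, rfc, s), "coordinates|window")
})

test_that("rfc_score separates classes on planted alignments (AUC >= 0.9)", {
  aln <- planted_motif_alignment(seed = 21, strength = 0.8)
  rfc <- compute_rfc(aln)
  s <- vapply(aln$rows, function(r) rfc_score(rfc, r), numeric(1))
  expect_gte(roc_auc(aln$labels, s), 0.9)
})

test_that("pairwise_identity implements global-alignment identity", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AATA"), 0.75)
  expect_equal(pairwise_identity("KLMNP", "QRSTV"), 0)
  expect_equal(pairwise_identity("AKLM", "MLKA"),
               pairwise_identity("MLKA", "AKLM"))
  expect_error(pairwise_identity("", "AAAA"), "empty")
})

test_that("redundancy_reduce is greedy-deterministic and verified by oracle", {
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAT", "TTTTTTTTTT", "AAAAAAAAAA")
  kept <- redundancy_reduce(seqs, cutoff = 0.70)
  expect_equal(kept, c(1, 3))
  # all below cutoff -> all kept
  lo <- c("AAAAKKKK", "TTTTRRRR", "GGGGDDDD")
  expect_equal(redundancy_reduce(lo, 0.7), 1:3)
  # oracle: kept set is mutually below cutoff and every dropped sequence
  # matches an earlier kept one
  set.seed(5)
  pool <- replicate(8, paste(sample(c("A", "K", "L"), 12, TRUE), collapse = ""))
  kept <- redundancy_reduce(pool, 0.7)
  for (i in seq_along(kept))
    for (j in seq_len(i - 1))
      expect_lt(pairwise_identity(pool[kept[i]], pool[kept[j]]), 0.7)
  for (dr in setdiff(seq_along(pool), kept)) {
    earlier <- kept[kept < dr]
    expect_true(any(vapply(earlier, function(j)
      pairwise_identity(pool[dr], pool[j]) >= 0.7, logical(1))))
  }
})

test_that("nn_baseline majority-votes the closest training sequences", {
  train <- c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "TTTTTTTT", "TTTTTTTT")
  labels <- c(1, 1, 1, 0, 0)
  expect_equal(nn_baseline(train, labels, "AAAAAAAA", k = 3), 1L)
  expect_equal(nn_baseline(train, labels, "TTTTTTTT", k = 1), 0L)
  # hand fixture: query closest to {2 (pos), 4, 5 (neg)} -> majority negative
  train2 <- c("AAAAAAAA", "AAAATTTT", "TTTTTTTT", "TTTTTTTA", "TTTTATTT")
  labels2 <- c(1, 1, 0, 0, 0)
  # identities to "TTTTTTTT": 0, .5, 1, .875, .875 -> top3 = {3, 4, 5}
  expect_equal(nn_baseline(train2, labels2, "TTTTTTTT", k = 3), 0L)
  # even split predicts positive (documented tie rule)
  expect_equal(nn_baseline(c("AAAAAAAA", "TTTTTTTT"), c(1, 0),
                           "AAAATTTT", k = 2), 1L)
})

test_that("alignment and label files round-trip", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a desc", "AK-LM", ">b", "AKQL-"), fa)
  got <- read_fasta_alignment(fa)
  expect_equal(got$names, c("a", "b"))
  expect_equal(got$rows, c("AK-LM", "AKQL-"), ignore_attr = TRUE)

  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "a AK-", "b AKQ", "", "a LM", "b L-",
               "//"), sto)
  gs <- read_stockholm(sto)
  expect_equal(gs$names, c("a", "b"))
  expect_equal(gs$rows, c("AK-LM", "AKQL-"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\t1", "b\t0"), tsv)
  expect_equal(read_labels_tsv(tsv), c(a = 1L, b = 0L))
})
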