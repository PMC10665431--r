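test_that("mismatch allowance and percent identity are two views of one cutoff", {
  # distance <= 1 over 250 bp iff identity >= 249/250
  expect_equal(mismatch_identity_pct(250, 1), 100 * 249 / 250)
  expect_equal(mismatch_identity_pct(250, 0), 100)
  for (mm in 0:3) {
    expect_identical(mismatch_identity_pct(250, mm) >= 99.6, mm <= 1)
  }
  expect_error(mismatch_identity_pct(250, 300), class = "aux_invalid_input")
})

test_that("ASV matching is sliding-window Hamming with deterministic ties", {
  set.seed(101)
  refs <- c(gB = random_seq(800), gA = random_seq(800))
  window <- substr(refs[["gA"]], 201, 450)

  exact <- match_asvs(c(v1 = window), refs)
  expect_identical(exact$genome_id, "gA")
  expect_identical(exact$mismatches, 0L)
  expect_false(exact$ambiguous)

  one_sub <- match_asvs(c(v2 = substitute_at(window, 37)), refs)
  expect_identical(one_sub$genome_id, "gA")
  expect_identical(one_sub$mismatches, 1L)

  two_sub <- match_asvs(c(v3 = substitute_at(window, c(37, 180))), refs)
  expect_identical(nrow(two_sub), 0L)
  expect_identical(attr(two_sub, "unmatched"), "v3")
  # but allowed when the mismatch budget is raised
  expect_identical(
    match_asvs(c(v3 = substitute_at(window, c(37, 180))), refs,
               max_mismatch = 2)$mismatches, 2L)

  # duplicate references: lexicographically smallest genome, flagged
  dup <- match_asvs(c(v4 = window),
                    c(gZ = refs[["gA"]], gC = refs[["gA"]], gB = refs[["gB"]]))
  expect_identical(dup$genome_id, "gC")
  expect_true(dup$ambiguous)
})

test_that("IUPAC codes in references cover ASV bases; bad input errors", {
  set.seed(77)
  ref <- random_seq(120)
  asv <- substr(ref, 11, 70)
  stopifnot(substr(ref, 20, 20) == "A")  # fixture expects A at position 20
  ref_n <- ref
  substr(ref_n, 20, 20) <- "N"   # N covers any base
  expect_identical(match_asvs(c(a = asv), c(g1 = ref_n))$mismatches, 0L)
  ref_r <- ref
  substr(ref_r, 20, 20) <- "R"   # purine code: covers the A at position 20
  expect_identical(match_asvs(c(a = asv), c(g1 = ref_r))$mismatches, 0L)
  ref_y <- ref
  substr(ref_y, 20, 20) <- "Y"   # pyrimidine: does not cover A -> 1 mismatch
  expect_identical(match_asvs(c(a = asv), c(g1 = ref_y))$mismatches, 1L)

  expect_error(match_asvs(c(a = gsub("A", "N", asv)), c(g1 = ref)),
               class = "aux_invalid_sequence")
  expect_error(match_asvs(c(a = substr(asv, 1, 30)), c(g1 = ref)),
               class = "aux_invalid_input")
  expect_error(match_asvs(setNames(asv, NULL), c(g1 = ref)))
})

test_that("read-depth and occupancy filters use strict and inclusive bounds", {
  counts <- matrix(0L, nrow = 20, ncol = 4,
                   dimnames = list(sprintf("s%02d", 1:20),
                                   c("keep", "few_reads", "rare", "both_ok")))
  counts[1:2, "keep"] <- c(6L, 5L)          # 11 reads, 2/20 = 10% occupancy
  counts[1:10, "few_reads"] <- 1L           # 10 reads (not > 10), 50% occ
  counts[1, "rare"] <- 1000L                # 1 of 20 samples = 5%
  counts[1:20, "both_ok"] <- 5L
  seqs <- setNames(replicate(4, random_seq(250)), colnames(counts))
  tab <- asv_table("h", counts, seqs)
  out <- filter_asvs(tab)
  expect_setequal(out$kept, c("keep", "both_ok"))
  expect_identical(
    out$stats$reason[match(c("few_reads", "rare"), out$stats$asv_id)],
    c("low_reads", "low_occupancy"))
  expect_identical(colnames(out$table$counts), out$kept)
})

test_that("filtering equals a brute-force scan on random tables", {
  set.seed(55)
  for (i in 1:20) {
    n_s <- sample(3:25, 1)
    n_a <- sample(2:15, 1)
    counts <- matrix(rbinom(n_s * n_a, 8, 0.25), nrow = n_s,
                     dimnames = list(sprintf("s%d", 1:n_s),
                                     sprintf("a%d", 1:n_a)))
    seqs <- setNames(replicate(n_a, random_seq(250)),
                     colnames(counts))
    tab <- asv_table("h", counts, seqs)
    got <- filter_asvs(tab)$kept
    want <- colnames(counts)[vapply(seq_len(n_a), function(j) {
      sum(counts[, j]) > 10 && mean(counts[, j] > 0) >= 0.10
    }, logical(1))]
    expect_identical(got, want)
  }
})

test_that("habitat summaries deduplicate taxa and report Table-1 style metrics", {
  counts <- matrix(10L, nrow = 4, ncol = 4,
                   dimnames = list(sprintf("s%d", 1:4),
                                   sprintf("asv%d", 1:4)))
  seqs <- setNames(replicate(4, random_seq(250)), colnames(counts))
  tab <- asv_table("pond", counts, seqs)
  matches <- data.frame(asv_id = paste0("asv", 1:4),
                        genome_id = paste0("g", 1:4))
  prof <- data.frame(genome_id = paste0("g", 1:4),
                     n_auxotrophies = c(0L, 0L, 1L, 3L))
  s <- summarize_habitat(tab, matches, prof)
  expect_equal(s$pct_prototrophs, 50)
  expect_equal(s$mean_n_auxotrophies, 1.0)
  expect_equal(s$pct_single_auxotrophy, 50)
  expect_equal(s$pct_asvs_with_genomes, 100)
  expect_equal(s$weighted_auxotroph_abundance, 50)

  # two ASVs matching one genome count that taxon once
  matches2 <- data.frame(asv_id = paste0("asv", 1:4),
                         genome_id = c("g1", "g1", "g3", "g4"))
  s2 <- summarize_habitat(tab, matches2, prof)
  expect_equal(s2$n_genomes, 3L)
  expect_equal(s2$pct_prototrophs, 100 * 1 / 3)
  expect_equal(s2$mean_n_auxotrophies, mean(c(0, 1, 3)))

  # all matched genomes prototrophic: share of single auxotrophs undefined
  all_proto <- data.frame(genome_id = paste0("g", 1:4),
                          n_auxotrophies = 0L)
  s3 <- summarize_habitat(tab, matches, all_proto)
  expect_equal(s3$pct_prototrophs, 100)
  expect_true(is.na(s3$pct_single_auxotrophy))

  # nothing matched: zero coverage, trait metrics undefined
  s4 <- summarize_habitat(tab, matches[0, ], prof)
  expect_equal(s4$pct_asvs_with_genomes, 0)
  expect_equal(s4$abundance_covered, 0)
  expect_true(is.na(s4$pct_prototrophs))

  expect_error(summarize_habitat(tab, matches, prof[1:2, ]),
               class = "aux_missing_pairs")
})

test_that("habitat metrics are invariant to splitting reads across ASVs of one taxon", {
  set.seed(9)
  counts <- matrix(rbinom(5 * 3, 40, 0.5), nrow = 5,
                   dimnames = list(sprintf("s%d", 1:5), c("a1", "a2", "a3")))
  seqs <- setNames(replicate(3, random_seq(250)), colnames(counts))
  prof <- data.frame(genome_id = c("g1", "g2", "g3"),
                     n_auxotrophies = c(0L, 2L, 1L))
  base <- summarize_habitat(
    asv_table("h", counts, seqs),
    data.frame(asv_id = c("a1", "a2", "a3"),
               genome_id = c("g1", "g2", "g3")), prof)
  # split a1's reads into two ASVs both matching g1
  split_counts <- cbind(counts,
                        a1b = as.integer(floor(counts[, "a1"] / 2)))
  split_counts[, "a1"] <- counts[, "a1"] -
    as.integer(floor(counts[, "a1"] / 2))
  seqs2 <- c(seqs, a1b = seqs[["a1"]])
  split <- summarize_habitat(
    asv_table("h", split_counts, seqs2),
    data.frame(asv_id = c("a1", "a2", "a3", "a1b"),
               genome_id = c("g1", "g2", "g3", "g1")), prof)
  for (col in c("n_genomes", "pct_prototrophs", "mean_n_auxotrophies",
                "pct_single_auxotrophy", "abundance_covered",
                "weighted_auxotroph_abundance")) {
    expect_equal(split[[col]], base[[col]], info = col)
  }
})

test_that("pairwise habitat tests use exact small-sample Mann-Whitney p-values", {
  # two fully separated tie-free groups of 4: two-sided exact p = 2/70,
  # the minimal attainable value for this design
  sep <- compare_habitats(c(1, 2, 3, 4, 5, 6, 7, 8),
                          rep(c("low", "high"), each = 4))
  expect_equal(sep$table$p_raw, 2 / 70, tolerance = 1e-12)
  expect_identical(sep$n_pairs, 1L)
  # with ties the test falls back to the corrected normal approximation,
  # which stays below the 0.05 level for full separation
  tied <- compare_habitats(c(0, 0, 0, 0, 5, 6, 7, 8),
                           rep(c("low", "high"), each = 4))
  expect_lt(tied$table$p_raw, 0.05)
  # identical distributions: adjusted p capped at 1
  same <- compare_habitats(rep(1:4, 2), rep(c("x", "y"), each = 4))
  expect_equal(same$table$p_adjusted, 1)
  expect_identical(unname(same$letters["x"]), unname(same$letters["y"]))

  set.seed(3)
  vals <- c(rnorm(6), rnorm(6), rnorm(6) + 30)
  habs <- rep(c("a", "b", "c"), each = 6)
  three <- compare_habitats(vals, habs)
  expect_identical(nrow(three$table), 3L)
  expect_equal(three$table$p_adjusted,
               pmin(1, three$table$p_raw * 3))
  expect_true(all(three$table$p_adjusted >= three$table$p_raw))
  # a and b share a letter, c does not
  expect_identical(unname(three$letters["a"]), unname(three$letters["b"]))
  expect_false(three$letters["c"] %in% three$letters[c("a", "b")])

  expect_warning(
    compare_habitats(c(1, 2, 3, 4, 9), c("p", "p", "q", "q", "tiny")),
    "fewer than 2")
  expect_error(compare_habitats(1:3, c("a", "a", "a")),
               class = "aux_invalid_input")
})
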