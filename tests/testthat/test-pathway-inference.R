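test_that("candidate rules honour both confidence branches and bit-score contrast", {
  # branch 1 boundary: at least 40% identity and 70% coverage
  expect_true(evaluate_candidate(40, 70, 100))
  # branch 2: at least 30% identity and 80% coverage, winning bit score
  expect_true(evaluate_candidate(30, 80, 100, bits_other = 90))
  # fails both identity/coverage branches
  expect_false(evaluate_candidate(35, 60, 100))
  # bit score must be strictly higher than the other-function alignment
  expect_false(evaluate_candidate(45, 90, 50, bits_other = 50))
  expect_false(evaluate_candidate(30, 80, 89, bits_other = 90))
  # absent competing alignment means the branch alone decides
  expect_true(evaluate_candidate(30, 80, 5))
  expect_false(evaluate_candidate(29.9, 80, 100))
  expect_false(evaluate_candidate(39.9, 79.9, 100))
  # vectorised over rows
  expect_identical(
    evaluate_candidate(c(40, 35, 30), c(70, 60, 80), c(1, 1, 100),
                       c(NA, NA, 90)),
    c(TRUE, FALSE, TRUE))
  expect_error(evaluate_candidate(120, 70, 10), class = "aux_invalid_evidence")
  expect_error(evaluate_candidate(40, 70, -1), class = "aux_invalid_evidence")
})

test_that("a step is present iff some candidate passes", {
  empty <- passing_evidence("g", character(0))
  expect_false(call_step("s1", empty))
  mixed <- rbind(failing_evidence("g", "s1"), passing_evidence("g", "s1"))
  expect_true(call_step("s1", mixed))
  expect_false(call_step("s1", failing_evidence("g", rep("s1", 3))))
  # evidence for other steps is ignored
  expect_false(call_step("s2", passing_evidence("g", "s1")))
})

test_that("missing fraction minimises over routes with exact tie-breaking", {
  single <- pathway_definition("lysine", list(paste0("s", 1:5)))
  calls <- c(s1 = TRUE, s2 = TRUE, s3 = TRUE, s4 = FALSE, s5 = FALSE)
  expect_identical(pathway_missing_fraction(single, calls),
                   c(missing = 2L, total = 5L))
  expect_identical(
    pathway_missing_fraction(single, setNames(rep(TRUE, 5), paste0("s", 1:5))),
    c(missing = 0L, total = 5L))
  # 1/4 beats 1/3
  two <- pathway_definition("lysine",
                            list(c("a1", "a2", "a3"),
                                 c("b1", "b2", "b3", "b4")))
  calls2 <- c(a1 = TRUE, a2 = TRUE, a3 = FALSE,
              b1 = TRUE, b2 = TRUE, b3 = TRUE, b4 = FALSE)
  expect_identical(pathway_missing_fraction(two, calls2),
                   c(missing = 1L, total = 4L))
  # equal fractions 1/3 = 2/6: smaller total wins
  tie <- pathway_definition("lysine",
                            list(paste0("x", 1:6), paste0("y", 1:3)))
  calls3 <- c(setNames(c(rep(TRUE, 4), FALSE, FALSE), paste0("x", 1:6)),
              setNames(c(TRUE, TRUE, FALSE), paste0("y", 1:3)))
  expect_identical(pathway_missing_fraction(tie, calls3),
                   c(missing = 1L, total = 3L))
  # exact tie in fraction and total: first-listed route
  expect_identical(
    pathway_missing_fraction(
      pathway_definition("lysine", list(c("p1", "p2"), c("q1", "q2"))),
      c(p1 = TRUE, p2 = FALSE, q1 = FALSE, q2 = TRUE)),
    c(missing = 1L, total = 2L))
  # uncalled steps are absent
  expect_identical(pathway_missing_fraction(single, c(s1 = TRUE)),
                   c(missing = 4L, total = 5L))
})

test_that("route minimisation agrees with exhaustive enumeration", {
  set.seed(42)
  for (i in 1:200) {
    p <- random_pathway("lysine")
    steps <- unlist(p$routes)
    calls <- setNames(sample(c(TRUE, FALSE), length(steps), replace = TRUE),
                      steps)
    expect_identical(unname(pathway_missing_fraction(p, calls)),
                     oracle_missing_fraction(p$routes, calls))
  }
})

test_that("auxotrophy threshold is inclusive and exact in integer arithmetic", {
  expect_true(call_compound_auxotrophy(2, 5, 40))   # exactly 40% missing
  expect_false(call_compound_auxotrophy(1, 5, 40))
  expect_true(call_compound_auxotrophy(5, 5, 100))
  expect_true(call_compound_auxotrophy(3, 10, 30))
  expect_false(call_compound_auxotrophy(0, 3, 1))
  expect_true(call_compound_auxotrophy(0, 3, 0))
  expect_error(call_compound_auxotrophy(1, 0), class = "aux_invalid_fraction")
  expect_error(call_compound_auxotrophy(3, 2), class = "aux_invalid_fraction")
  expect_error(call_compound_auxotrophy(2, 5, 140),
               class = "aux_invalid_threshold")
})

test_that("genome profiles cover all 18 compounds with consistent counts", {
  db <- tiny_db()
  full <- passing_evidence("gA", all_steps(db))
  prof <- profile_genome("gA", full, db)
  expect_equal(nrow(prof$calls), 18L)
  expect_setequal(prof$calls$compound, aux_compounds())
  expect_identical(prof$genomes$n_auxotrophies, 0L)

  none <- profile_genome("gB", full, db)  # no evidence rows for gB
  expect_identical(none$genomes$n_auxotrophies, 18L)
  expect_true(all(none$calls$missing == none$calls$total))

  # planted knockout of all tryptophan steps only
  trp_steps <- db[["tryptophan"]]$routes[[1]]
  partial <- passing_evidence("gC", setdiff(all_steps(db), trp_steps))
  prof_c <- profile_genome("gC", partial, db)
  expect_identical(prof_c$genomes$n_auxotrophies, 1L)
  expect_true(prof_c$calls$auxotrophic[prof_c$calls$compound == "tryptophan"])
  expect_false(any(prof_c$calls$auxotrophic[
    prof_c$calls$compound != "tryptophan"]))

  incomplete <- db[1:17]
  expect_error(profile_genomes(full, incomplete),
               class = "aux_invalid_pathway")
})

test_that("raising the threshold never enlarges a genome's auxotrophy set", {
  db <- tiny_db(steps_per = 5)
  set.seed(7)
  steps <- all_steps(db)
  ev <- do.call(rbind, lapply(sprintf("g%02d", 1:20), function(g) {
    passing_evidence(g, sample(steps, sample(20:90, 1)))
  }))
  prev <- NULL
  for (th in c(20, 40, 60, 80)) {
    prof <- profile_genomes(ev, db, threshold_percent = th)
    set_th <- prof$calls[prof$calls$auxotrophic,
                         c("genome_id", "compound")]
    key <- paste(set_th$genome_id, set_th$compound)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("adding passing evidence can only turn steps present", {
  db <- tiny_db()
  ev <- failing_evidence("g", all_steps(db))
  before <- profile_genome("g", ev, db)
  expect_identical(before$genomes$n_auxotrophies, 18L)
  more <- rbind(ev, passing_evidence("g", all_steps(db)))
  after <- profile_genome("g", more, db)
  expect_identical(after$genomes$n_auxotrophies, 0L)
})

test_that("genome classification supports the strict two-auxotrophy class", {
  summ <- data.frame(genome_id = c("a", "b", "c"),
                     n_auxotrophies = c(0L, 1L, 3L))
  lax <- classify_genomes(summ, min_auxotrophies = 1)
  expect_identical(as.character(lax$class),
                   c("prototroph", "auxotroph", "auxotroph"))
  strict <- classify_genomes(summ, min_auxotrophies = 2)
  expect_identical(as.character(strict$class),
                   c("prototroph", NA, "auxotroph"))
  expect_error(classify_genomes(summ, 0), class = "aux_invalid_threshold")
})

test_that("genome filters apply completeness, chimerism and 16S rules in order", {
  records <- data.frame(
    genome_id = c("r1", "r2", "r3", "r4", "r5"),
    origin = c("isolate", "isolate", "MAG", "MAG", "SAG"),
    completeness = c(95.0, 99, 99, 99, 96),
    chimeric = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    has_16S = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  out <- filter_genomes(records)
  # 95.0 exactly fails the strict > 95 rule; isolates without 16S are kept
  expect_setequal(out$kept$genome_id, c("r2", "r5"))
  expect_identical(out$counts,
                   c(low_completeness = 1L, chimeric = 1L,
                     assembled_without_16S = 1L))
  expect_identical(
    out$rejected$reason[match(c("r1", "r3", "r4"),
                              out$rejected$genome_id)],
    c("low_completeness", "chimeric", "assembled_without_16S"))
  expect_error(filter_genomes(records[, -3]), class = "aux_missing_field")
})
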