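test_that("parameter constructor enforces mode inequalities and ranges", {
  expect_s3_class(md23_params(), "model_params")
  expect_error(model_params("MD", 2000, 6000, 800, c(31, 50), c(21, 30)), "MD requires")
  expect_error(model_params("MI", 120, 10, 200, c(31, 50), c(11, 20)), "MI requires")
  expect_error(model_params("MD", 6000, 2000, 0, c(31, 50), c(21, 30)), "positive")
  expect_error(model_params("MD", 6000, 2000, 800, c(50, 31), c(21, 30)), "range")
})

test_that("stage planning interpolates, clamps and budgets per branch", {
  tr <- test_tree()
  plan <- plan_stages(tr, md23_params())
  len <- plan$node_length
  expect_equal(unname(len["AS_1"]), 6000)
  expect_equal(unname(len["AS_12"]), 2000)
  bb <- len[paste0("AS_", 1:12)]
  expect_true(all(diff(bb) <= 0))              # MD: non-increasing
  expect_true(all(bb >= 2000 & bb <= 6000))
  expect_true(plan$feasible)
  expect_equal(plan$budgets$mutation_target,
               as.integer(floor(800 * plan$budgets$branch_length + 0.5)))

  pmi <- model_params("MI", 10, 120, 200, c(31, 50), c(11, 20))
  plan_mi <- plan_stages(tr, pmi)
  bb <- plan_mi$node_length[paste0("AS_", 1:12)]
  expect_true(all(diff(bb) >= 0))              # MI: non-decreasing
  expect_true(all(bb >= 10 & bb <= 120))
  expect_true(plan_mi$feasible)
})

test_that("MI planning keeps the shortest intron's ancestor strictly below it", {
  tr <- test_tree()
  pmi <- model_params("MI", 40, 140, 200, c(31, 50), c(11, 20))
  plan <- plan_stages(tr, pmi)
  expect_true(plan$feasible)
  # Rt112 hangs off AS_9; interpolation alone would put AS_9 above 112
  expect_lt(unname(plan$node_length["AS_9"]), 112)
  expect_true(all(diff(plan$node_length[paste0("AS_", 1:12)]) >= 0))
})

test_that("validity reporting names the violated ancestor/leaf pairs", {
  tr <- test_tree()
  expect_true(validate_params(tr, md23_params())$valid)
  expect_true(validate_params(
    tr, model_params("MI", 10, 140, 200, c(31, 50), c(11, 20)))$valid)

  bad <- validate_params(tr, model_params("MD", 6000, 1900, 800, c(31, 50), c(21, 30)))
  expect_false(bad$valid)
  expect_equal(nrow(bad$violations), 1)
  expect_equal(bad$violations$leaf, "Am1975")
  expect_equal(bad$violations$ancestor, "AS_12")
})

test_that("branch evolution hits the exact target length and mutation budget", {
  p <- md23_params()
  set.seed(21)
  parent <- random_sequence(6000)
  for (s in 1:5) {
    set.seed(s)
    res <- evolve_branch(parent, 376, 150, p)
    expect_equal(nchar(res$seq), 376)
    expect_equal(res$ledger$n_transitions + res$ledger$n_transversions, 150L)
    expect_equal(substr(res$seq, 1, 2), "GT")
    expect_equal(substr(res$seq, 375, 376), "AG")
  }
  # no-op branch
  res <- evolve_branch(parent, 6000, 0, p)
  expect_identical(res$seq, parent)
  # precondition: MD cannot grow
  expect_error(evolve_branch(random_sequence(100), 200, 10, p), "parent length")
})

test_that("MI branches grow tiny ancestors to target despite few mutable sites", {
  pmi <- model_params("MI", 10, 120, 800, c(31, 50), c(11, 20))
  set.seed(2)
  res <- evolve_branch(random_sequence(10), 120, 300, pmi)
  expect_equal(nchar(res$seq), 120)
  expect_equal(res$ledger$n_transitions + res$ledger$n_transversions, 300L)
})

test_that("full runs give exact leaf lengths, conserved budgets, determinism", {
  tr <- test_tree()
  run <- run_simulation(tr, md23_params(), seed = 42)
  expect_length(run$leaves, 14)
  expect_length(run$ancestors, 12)
  expect_identical(nchar(run$leaves), tr$leaf_specs[names(run$leaves)])
  # per-edge ledger totals equal the planned budgets
  led <- tidy(run)
  expect_identical(led$n_substitutions, led$mutation_target)

  run2 <- run_simulation(tr, md23_params(), seed = 42)
  expect_identical(run2$leaves, run$leaves)
  expect_identical(run2$ancestors, run$ancestors)
  run3 <- run_simulation(tr, md23_params(), seed = 43)
  expect_false(identical(run3$leaves, run$leaves))
})

test_that("realized ancestor lengths are monotone along every backbone path", {
  tr <- test_tree()
  run_md <- run_simulation(tr, md23_params(), seed = 5)
  lens_md <- nchar(run_md$ancestors[paste0("AS_", 1:12)])
  expect_true(all(diff(lens_md) <= 0))

  pmi <- model_params("MI", 10, 120, 200, c(31, 50), c(31, 40))
  run_mi <- run_simulation(tr, pmi, seed = 5)
  lens_mi <- nchar(run_mi$ancestors[paste0("AS_", 1:12)])
  expect_true(all(diff(lens_mi) >= 0))
  expect_true(all(lens_mi <= 120))
  expect_identical(nchar(run_mi$leaves), tr$leaf_specs[names(run_mi$leaves)])
})

test_that("pooled run ledger recovers the configured ts/tv ratio", {
  tr <- test_tree()
  p <- model_params("MD", 6000, 2000, 800, c(31, 50), c(21, 30))
  ts <- tv <- 0
  for (s in 1:6) {
    run <- run_simulation(tr, p, seed = s)
    ts <- ts + sum(run$ledgers$n_transitions)
    tv <- tv + sum(run$ledgers$n_transversions)
  }
  expect_gt(ts + tv, 30000)
  ratio <- ts / tv
  # 1.5 within 3 binomial SDs of the pooled event count
  p_ts <- 0.6
  se <- 3 * sqrt(p_ts * (1 - p_ts) / (ts + tv))
  expect_gt(ts / (ts + tv), p_ts - se)
  expect_lt(ts / (ts + tv), p_ts + se)
  expect_gt(ratio, 1.4); expect_lt(ratio, 1.6)
})

test_that("runs serialize to FASTA plus manifest and reload identically", {
  tr <- fixture_tree(seed = 3, n_leaves = 6)
  p <- model_params("MD", 4000, 2000, 400, c(31, 50), c(11, 20))
  run <- run_simulation(tr, p, seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_run(run, dir, stem = "t")
  seqs <- read_fasta(paths[["fasta"]])
  expect_length(seqs, 6 + 4)
  expect_identical(seqs[names(run$leaves)], run$leaves)
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$seed, 9)
  expect_equal(man$params$mode, "MD")
})
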