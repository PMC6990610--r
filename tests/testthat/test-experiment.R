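test_that("the L16 array is balanced singly and pairwise", {
  d <- l16_design()
  expect_equal(nrow(d), 16)
  expect_equal(ncol(d), 5)
  for (col in names(d)) {
    expect_equal(unname(table(d[[col]])), rep(4L, 4), ignore_attr = TRUE)
  }
  for (i in 1:4) {
    for (j in (i + 1):5) {
      pairs <- paste(d[[i]], d[[j]])
      expect_equal(sort(unique(pairs)),
                   sort(paste(rep(1:4, each = 4), rep(1:4, 4))))
      expect_equal(unname(table(pairs)), rep(1L, 16), ignore_attr = TRUE)
    }
  }
})

test_that("factor levels reproduce the published level table verbatim", {
  md <- factor_levels("MD")
  val <- function(tbl, f, l) tbl$value[tbl$factor == f & tbl$level == l][[1]]
  expect_equal(val(md, "L_AS1", 1), 4000L)
  expect_equal(val(md, "L_AS12", 1), 2000L)
  expect_equal(val(md, "M_1", 1), 200L)
  expect_equal(val(md, "L_ID", 1), c(31L, 50L))
  expect_equal(val(md, "M_ID", 1), c(11L, 20L))
  expect_equal(val(md, "L_AS1", 4), 7000L)
  expect_equal(val(md, "L_AS12", 4), 2750L)

  mi <- factor_levels("MI")
  expect_equal(val(mi, "L_AS1", 1), 10L)
  expect_equal(val(mi, "L_AS12", 4), 140L)
  expect_equal(val(mi, "M_1", 4), 800L)
  expect_equal(val(mi, "L_ID", 4), c(151L, 170L))
  expect_equal(val(mi, "M_ID", 3), c(31L, 40L))
})

test_that("level combinations materialize to full parameter sets", {
  custom <- tibble::tibble(L_AS1 = 3L, L_AS12 = 1L, M_1 = 3L, L_ID = 1L, M_ID = 2L)
  t1 <- materialize_tests("MD", design = custom)
  expect_equal(t1$L_AS1, 6000L)
  expect_equal(t1$L_AS12, 2000L)
  expect_equal(t1$M_1, 600L)
  expect_equal(t1$L_ID, "31-50")
  expect_equal(t1$M_ID, "21-30")
  p <- t1$params[[1]]
  expect_equal(p$mode, "MD")
  expect_equal(p$r_ratio, 1.5)
  expect_equal(p$l_id, c(31L, 50L))

  full <- materialize_tests("MI")
  expect_equal(nrow(full), 16)
  expect_equal(full$test_id[1], "MI_01")
})

test_that("every materialized test is valid on the default fixture tree", {
  tr <- test_tree()
  for (mode in c("MD", "MI")) {
    tests <- materialize_tests(mode)
    for (i in seq_len(nrow(tests))) {
      expect_true(validate_params(tr, tests$params[[i]])$valid,
                  label = tests$test_id[i])
    }
  }
})

test_that("the named optimization runs carry the printed parameter values", {
  md <- named_tests("MD")
  expect_equal(nrow(md), 8)
  row <- function(tbl, id) tbl[tbl$test_id == id, ]
  r <- row(md, "MD_17")
  expect_equal(unlist(r[c("L_AS1", "L_AS12", "M_1")]),
               c(L_AS1 = 6000, L_AS12 = 2000, M_1 = 600))
  expect_equal(r$L_ID, "31-50"); expect_equal(r$M_ID, "21-30")
  r <- row(md, "MD_23")
  expect_equal(unlist(r[c("L_AS1", "L_AS12", "M_1")]),
               c(L_AS1 = 6000, L_AS12 = 2000, M_1 = 800))
  r <- row(md, "MD_24")
  expect_equal(unlist(r[c("L_AS1", "L_AS12", "M_1")]),
               c(L_AS1 = 6000, L_AS12 = 2500, M_1 = 800))
  expect_equal(r$M_ID, "11-20")

  mi <- named_tests("MI")
  expect_equal(nrow(mi), 8)
  r <- row(mi, "MI_17")
  expect_equal(unlist(r[c("L_AS1", "L_AS12", "M_1")]),
               c(L_AS1 = 10, L_AS12 = 120, M_1 = 200))
  expect_equal(r$M_ID, "31-40")
  r <- row(mi, "MI_24")
  expect_equal(unlist(r[c("L_AS1", "L_AS12", "M_1")]),
               c(L_AS1 = 10, L_AS12 = 120, M_1 = 800))
  expect_equal(r$L_ID, "151-170")
})

test_that("replicated test batches are reproducible and fully recorded", {
  tr <- fixture_tree(seed = 4, n_leaves = 6)
  tests <- named_tests("MD")[c(1, 7), ]
  res <- run_tests(tests, tr, reps = 2, master_seed = 99, bootstrap_reps = 40)
  expect_equal(nrow(res), 4)
  expect_true(all(res$status == "ok"))
  expect_true(all(res$seed > 0 & res$seed < 2^31))
  expect_equal(anyDuplicated(res$seed), 0)
  res2 <- run_tests(tests, tr, reps = 2, master_seed = 99, bootstrap_reps = 40)
  expect_identical(res, res2)
  expect_false(identical(
    res, run_tests(tests, tr, reps = 2, master_seed = 100, bootstrap_reps = 40)))
})

test_that("1-base perturbation changes each sequence at exactly one site", {
  tr <- fixture_tree(seed = 4, n_leaves = 6)
  ref <- synthetic_reference_set(tr, seed = 11)
  expect_identical(nchar(ref), tr$leaf_specs[names(ref)])

  set.seed(12)
  for (r in 1:3) {
    pert <- vapply(ref, function(s) mutate_bases(s, 1)$seq, "")
    for (id in names(ref)) {
      expect_equal(nchar(pert[[id]]), nchar(ref[[id]]))
      expect_equal(sum(strsplit(pert[[id]], "")[[1]] != strsplit(ref[[id]], "")[[1]]), 1)
    }
  }

  dist <- perturb_reference(ref, tr, reps = 3, seed = 13, bootstrap_reps = 40)
  expect_equal(nrow(dist$replicates), 3)
  expect_equal(dist$summary$attribute,
               c("L_MSA", "R_K2I", "Dbar", "SEDbar", "TS_ML"))
  expect_true(all(dist$summary$sd >= 0))
})

test_that("an unperturbed control scored on its own tree is exact and constant", {
  tr <- fixture_tree(seed = 4, n_leaves = 6)
  ref <- synthetic_reference_set(tr, seed = 11)
  own <- infer_tree(ref)
  ctrl <- perturb_reference(ref, own, reps = 2, seed = 14,
                            bootstrap_reps = 40, n_mutations = 0)
  expect_true(all(ctrl$replicates$TS_ML == 12))
  sds <- ctrl$summary$sd[ctrl$summary$attribute != "SEDbar"]
  expect_true(all(sds == 0))
})

test_that("comparison against an identical reference draws no stars", {
  tr <- fixture_tree(seed = 4, n_leaves = 6)
  tests <- named_tests("MD")[3, ]
  res <- run_tests(tests, tr, reps = 3, master_seed = 7, bootstrap_reps = 40)
  ref <- structure(list(replicates = res, reps = 3), class = "reference_distribution")
  cmp <- compare_to_reference(res, ref)
  expect_equal(nrow(cmp), 5)
  expect_true(all(cmp$stars == ""))
  expect_true(all(cmp$p == 1))
})
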