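test_that("builtin aligner handles toy pairs exactly and never edits bases", {
  m <- align_sequences(c(a = "GTACGTACGTAG", b = "GTACGTACGTAG"))
  expect_equal(m$n_cols, 12)
  expect_false(any(grepl("-", m$rows)))

  m2 <- align_sequences(c(long = "GTAAAG", short = "GTAG"))
  expect_equal(m2$n_cols, 6)
  expect_equal(sum(strsplit(m2$rows[["short"]], "")[[1]] == "-"), 2)
  expect_equal(gsub("-", "", m2$rows[["short"]]), "GTAG")
  expect_equal(m2$rows[["long"]], "GTAAAG")

  set.seed(30)
  seqs <- setNames(vapply(c(200, 150, 180, 120, 90), random_sequence, ""),
                   paste0("s", 1:5))
  msa <- align_sequences(seqs)
  expect_gte(msa$n_cols, 200)  # gaps only add columns
  for (id in names(seqs)) {
    expect_identical(gsub("-", "", msa$rows[[id]]), unname(seqs[[id]]))
  }
})

test_that("K2P pair statistics match the closed-form hand evaluation", {
  # 100 comparable sites: 10 transitions, 5 transversions -> P=0.1, Q=0.05
  a <- paste0(strrep("A", 100))
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  ps <- pair_stats(a, b)
  expect_equal(ps$P, 0.1)
  expect_equal(ps$Q, 0.05)
  d_oracle <- -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1))
  r_oracle <- (-0.5 * log(0.75) + 0.25 * log(0.9)) / (-0.5 * log(0.9))
  expect_equal(ps$d, d_oracle, tolerance = 1e-9)
  expect_equal(ps$R_pair, r_oracle, tolerance = 1e-9)
  expect_equal(round(d_oracle, 5), 0.17018)
  expect_equal(round(r_oracle, 4), 2.2305)

  same <- pair_stats(a, a)
  expect_equal(same$P, 0); expect_equal(same$Q, 0); expect_equal(same$d, 0)

  # saturation: P+Q too large -> undefined, flagged not thrown
  sat <- pair_stats(strrep("A", 10), strrep("C", 10))
  expect_false(sat$defined)
  expect_true(is.na(sat$d))

  # gapped sites are excluded from the comparison
  g <- pair_stats("GTA-ACG", "GTAAACG")
  expect_equal(g$n_sites, 6L)
})

test_that("pairwise distances agree with an independent K80 implementation", {
  set.seed(31)
  seqs <- setNames(vapply(rep(400, 5), random_sequence, ""), paste0("t", 1:5))
  # evolve related copies so distances are defined
  for (i in 2:5) seqs[i] <- mutate_bases(seqs[[1]], 60)$seq
  msa <- align_sequences(seqs)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(unname(msa$rows)), "")))
  rownames(bin) <- names(msa$rows)
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  ours <- overall_stats(msa)$pairs
  for (r in seq_len(nrow(ours))) {
    expect_equal(ours$d[r], ref[ours$id_a[r], ours$id_b[r]], tolerance = 1e-9)
  }
})

test_that("overall mean distance equals brute-force all-pairs averaging", {
  set.seed(32)
  base <- random_sequence(300)
  rows <- c(a = base,
            b = mutate_bases(base, 30)$seq,
            c = mutate_bases(base, 50)$seq,
            d = mutate_bases(base, 70)$seq)
  msa <- align_sequences(rows)
  ov <- overall_stats(msa)
  expect_equal(ov$Dbar, brute_force_dbar(msa$rows), tolerance = 1e-12)
  expect_equal(ov$n_excluded, 0)

  same <- align_sequences(setNames(rep(base, 3), c("x", "y", "z")))
  expect_equal(overall_stats(same)$Dbar, 0)
})

test_that("bootstrap SE is zero on identical rows, seeded, and ~1/sqrt(n) scaled", {
  base <- random_sequence(200)
  same <- align_sequences(setNames(rep(base, 3), c("x", "y", "z")))
  expect_equal(sed_bootstrap(same, reps = 50, seed = 1), 0)

  set.seed(33)
  rows <- c(a = base, b = mutate_bases(base, 25)$seq, c = mutate_bases(base, 40)$seq)
  msa <- align_sequences(rows)
  expect_identical(sed_bootstrap(msa, reps = 100, seed = 4),
                   sed_bootstrap(msa, reps = 100, seed = 4))

  # duplicating every column doubles n_cols and shrinks the SE by ~1/sqrt(2)
  dbl <- align_sequences(setNames(paste0(rows, rows), names(rows)))
  ratios <- vapply(1:20, function(s) {
    sed_bootstrap(dbl, reps = 120, seed = s) / sed_bootstrap(msa, reps = 120, seed = s)
  }, numeric(1))
  expect_gt(mean(ratios), 1 / sqrt(2) - 0.12)
  expect_lt(mean(ratios), 1 / sqrt(2) + 0.12)
})

test_that("neighbor-joining recovers additive topologies and ignores input order", {
  # hand-built additive tree: ((A,B),(C,D),(E,F)) with distinct branch lengths
  nwk <- "((A:0.10,B:0.20):0.15,(C:0.05,D:0.25):0.30,(E:0.12,F:0.18):0.22);"
  truth <- ape::read.tree(text = nwk)
  D <- ape::cophenetic.phylo(truth)
  inferred <- nj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(inferred$phylo),
                                         ape::unroot(truth))), 0)
  # permuted label order gives the identical ladderized layout
  perm <- sample(rownames(D))
  inferred2 <- nj_tree(D[perm, perm])
  expect_identical(ladder_layout(inferred2), ladder_layout(inferred))

  expect_error(nj_tree(D[1:3, 1:3]), "")
})

test_that("topology self-score is 2N and degrades sensibly on rearranged trees", {
  for (n in c(4, 6, 9, 14, 20)) {
    tr <- fixture_tree(seed = n, n_leaves = n)
    expect_equal(as.integer(topology_score(tr, tr)), 2L * n)
  }
  # hand-scored 4-leaf case: moving the cherry from (C,D) to (A,B)
  ref <- parse_newick("(A1:1,B2:1,(C3:1,D4:1)AS_2:1)AS_1;")
  tst <- parse_newick("(C3:1,D4:1,(A1:1,B2:1)AS_2:1)AS_1;")
  # ref: forms A=STRAIGHT,B=L,C=INV_L,D=L; above C=TOP,D=C,A=D,B=A
  # tst: forms A=INV_L,B=L,C=STRAIGHT,D=L; above A=TOP,B=A,C=B,D=C
  # agreement: forms B,D (+2); locations B,D (+2)
  expect_equal(as.integer(topology_score(tst, ref)), 4L)

  # score is bounded on arbitrary same-label trees
  a <- fixture_tree(seed = 1); b <- fixture_tree(seed = 1)
  sc <- as.integer(topology_score(a, b))
  expect_gte(sc, 0); expect_lte(sc, 28)
  expect_error(topology_score(ref, fixture_tree(seed = 1)), "label sets differ")
})

test_that("explicit matchings map locations through the bijection", {
  ref <- parse_newick("(A1:1,B2:1,(C3:1,D4:1)AS_2:1)AS_1;")
  tst <- parse_newick("(W1:1,X2:1,(Y3:1,Z4:1)AS_2:1)AS_1;")
  match <- c(W1 = "A1", X2 = "B2", Y3 = "C3", Z4 = "D4")
  expect_equal(as.integer(topology_score(tst, ref, match)), 8L)
  expect_error(topology_score(tst, ref, c(W1 = "A1")), "bijection")
})

test_that("the composed attribute pipeline is reproducible and label-safe", {
  tr <- fixture_tree(seed = 4, n_leaves = 6)
  p <- model_params("MD", 4000, 2000, 400, c(31, 50), c(11, 20))
  run <- run_simulation(tr, p, seed = 17)
  a1 <- intron_attributes(run$leaves, tr, bootstrap_reps = 60, seed = 3)
  a2 <- intron_attributes(run$leaves, tr, bootstrap_reps = 60, seed = 3)
  expect_identical(a1, a2)
  expect_s3_class(a1, "tbl_df")
  expect_true(a1$L_MSA >= max(nchar(run$leaves)))
  expect_true(a1$TS_ML >= 0 && a1$TS_ML <= 12)

  bad <- run$leaves
  names(bad)[1] <- "nope"
  expect_error(intron_attributes(bad, tr), "do not match")

  # degenerate set: identical sequences
  const <- setNames(rep(run$leaves[[1]], 6), names(run$leaves))
  at <- intron_attributes(const, tr, bootstrap_reps = 30)
  expect_equal(at$Dbar, 0)
  expect_equal(at$SEDbar, 0)
  expect_equal(at$L_MSA, nchar(run$leaves[[1]]))
})
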