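FACTOR_NAMES <- c("L_AS1", "L_AS12", "M_1", "L_ID", "M_ID")

gf4_mul <- matrix(c(
  0, 0, 0, 0,
  0, 1, 2, 3,
  0, 2, 3, 1,
  0, 3, 1, 2
), 4, 4, byrow = TRUE)

#' The L16(4^5) orthogonal array
#'
#' Constructs the standard 16-run orthogonal array for five 4-level factors
#' over GF(4): rows are indexed by two base factors and the remaining three
#' columns are their GF(4) linear combinations, which guarantees that every
#' level appears exactly 4 times in each column and every ordered level pair
#' exactly once in each column pair.
#'
#' @return A 16-row tibble with columns `L_AS1`, `L_AS12`, `M_1`, `L_ID`,
#'   `M_ID`, levels in 1..4.
#' @export
l16_design <- function() {
  grid <- expand.grid(a = 0:3, b = 0:3)
  a <- grid$a; b <- grid$b
  xor4 <- function(x, y) bitwXor(x, y)
  cols <- cbind(
    a,
    b,
    xor4(a, b),
    xor4(a, gf4_mul[3, b + 1]),
    xor4(a, gf4_mul[4, b + 1])
  ) + 1L
  out <- tibble::as_tibble(as.data.frame(cols))
  names(out) <- FACTOR_NAMES
  out
}

#' Factor level values for the orthogonal screen
#'
#' The published level table for the two models: scalar levels for the
#' ancestor lengths and the per-branch mutation budget, inclusive ranges for
#' the per-event indel and mutation sizes.
#'
#' @param mode `"MD"` or `"MI"`.
#' @return Tibble with columns `factor`, `level`, `value` (list-column).
#' @export
factor_levels <- function(mode = c("MD", "MI")) {
  mode <- match.arg(mode)
  ranges_lid <- list(c(31L, 50L), c(71L, 90L), c(111L, 130L), c(151L, 170L))
  ranges_mid <- list(c(11L, 20L), c(21L, 30L), c(31L, 40L), c(41L, 50L))
  scalars <- if (mode == "MD") {
    list(L_AS1 = c(4000L, 5000L, 6000L, 7000L),
         L_AS12 = c(2000L, 2250L, 2500L, 2750L),
         M_1 = c(200L, 400L, 600L, 800L))
  } else {
    list(L_AS1 = c(10L, 20L, 30L, 40L),
         L_AS12 = c(110L, 120L, 130L, 140L),
         M_1 = c(200L, 400L, 600L, 800L))
  }
  tibble::tibble(
    factor = rep(FACTOR_NAMES, each = 4L),
    level = rep(1:4, times = 5L),
    value = c(as.list(scalars$L_AS1), as.list(scalars$L_AS12),
              as.list(scalars$M_1), ranges_lid, ranges_mid)
  )
}

params_from_values <- function(mode, l_as1, l_as12, m1, l_id, m_id, seed = NULL) {
  model_params(mode, l_as1, l_as12, m1, l_id, m_id, r_ratio = 1.5, seed = seed)
}

range_label <- function(r) paste0(r[1], "-", r[2])

#' Materialize the 16 orthogonal tests as parameter sets
#'
#' Maps the level matrix of [l16_design()] through the level value table of
#' [factor_levels()] for one mode, giving 16 fully specified parameter sets
#' at R = 1.5.
#'
#' @param mode `"MD"` or `"MI"`.
#' @param design Level matrix (defaults to [l16_design()]).
#' @return Tibble: `test_id`, scalar/range value columns, and a `params`
#'   list-column of [model_params()] objects.
#' @export
materialize_tests <- function(mode = c("MD", "MI"), design = l16_design()) {
  mode <- match.arg(mode)
  fl <- factor_levels(mode)
  val <- function(f, lev) fl$value[fl$factor == f & fl$level == lev][[1]]
  rows <- lapply(seq_len(nrow(design)), function(i) {
    v <- lapply(FACTOR_NAMES, function(f) val(f, design[[f]][i]))
    names(v) <- FACTOR_NAMES
    tibble::tibble(
      test_id = sprintf("%s_%02d", mode, i),
      L_AS1 = v$L_AS1, L_AS12 = v$L_AS12, M_1 = v$M_1,
      L_ID = range_label(v$L_ID), M_ID = range_label(v$M_ID),
      params = list(params_from_values(mode, v$L_AS1, v$L_AS12, v$M_1,
                                       v$L_ID, v$M_ID))
    )
  })
  dplyr::bind_rows(rows)
}

NAMED_TESTS <- list(
  MD_17 = list("MD", 6000, 2000, 600, c(31, 50), c(21, 30)),
  MD_18 = list("MD", 6000, 2500, 800, c(31, 50), c(21, 30)),
  MD_19 = list("MD", 6000, 2000, 800, c(31, 50), c(41, 50)),
  MD_20 = list("MD", 5000, 2500, 800, c(31, 50), c(21, 30)),
  MD_21 = list("MD", 6000, 2250, 800, c(31, 50), c(11, 20)),
  MD_22 = list("MD", 6000, 2250, 800, c(31, 50), c(41, 50)),
  MD_23 = list("MD", 6000, 2000, 800, c(31, 50), c(21, 30)),
  MD_24 = list("MD", 6000, 2500, 800, c(31, 50), c(11, 20)),
  MI_17 = list("MI", 10, 120, 200, c(31, 50), c(31, 40)),
  MI_18 = list("MI", 10, 120, 200, c(31, 50), c(11, 20)),
  MI_19 = list("MI", 10, 120, 800, c(31, 50), c(11, 20)),
  MI_20 = list("MI", 20, 120, 200, c(31, 50), c(11, 20)),
  MI_21 = list("MI", 10, 110, 800, c(31, 50), c(11, 20)),
  MI_22 = list("MI", 40, 110, 200, c(31, 50), c(11, 20)),
  MI_23 = list("MI", 20, 120, 200, c(151, 170), c(11, 20)),
  MI_24 = list("MI", 10, 120, 800, c(151, 170), c(11, 20))
)

#' The named optimization parameter sets
#'
#' The eight hand-tuned MD runs (`MD_17` to `MD_24`) and eight MI runs
#' (`MI_17` to `MI_24`) used in the parameter-optimization stage.
#'
#' @param mode `"MD"` or `"MI"`.
#' @return Tibble in the same shape as [materialize_tests()].
#' @export
#' @examples
#' named_tests("MD")
named_tests <- function(mode = c("MD", "MI")) {
  mode <- match.arg(mode)
  ids <- grep(paste0("^", mode), names(NAMED_TESTS), value = TRUE)
  rows <- lapply(ids, function(id) {
    v <- NAMED_TESTS[[id]]
    tibble::tibble(
      test_id = id, L_AS1 = v[[2]], L_AS12 = v[[3]], M_1 = v[[4]],
      L_ID = range_label(v[[5]]), M_ID = range_label(v[[6]]),
      params = list(params_from_values(v[[1]], v[[2]], v[[3]], v[[4]], v[[5]], v[[6]]))
    )
  })
  dplyr::bind_rows(rows)
}

derive_seed <- function(master_seed, test_index, replicate) {
  as.integer((as.numeric(master_seed) * 48271 +
              as.numeric(test_index) * 1299709 +
              as.numeric(replicate) * 7919) %% 2147483647)
}

#' Run a table of tests with replication and attribute evaluation
#'
#' For every test and replicate: derive a per-run seed from the master seed,
#' run the simulator, and evaluate the five attributes against the guide
#' tree.  Per-run failures are recorded in the `status` column rather than
#' aborting the batch; output is a pure function of
#' `(tests, tree, reps, master_seed)`.
#'
#' @param tests Tibble with `test_id` and a `params` list-column
#'   ([materialize_tests()] or [named_tests()]).
#' @param tree Guide tree.
#' @param reps Replicates per test (default 10).
#' @param master_seed Master seed for the seed derivation.
#' @param bootstrap_reps,aligner Passed to [intron_attributes()].
#' @return Tibble: test columns, `rep`, `seed`, the five attributes,
#'   `n_undefined_pairs`, `status`.
#' @export
run_tests <- function(tests, tree, reps = 10L, master_seed = 1L,
                      bootstrap_reps = 500L, aligner = "builtin") {
  rows <- list()
  for (i in seq_len(nrow(tests))) {
    for (r in seq_len(reps)) {
      seed <- derive_seed(master_seed, i, r)
      meta <- dplyr::select(tests[i, ], -"params")
      row <- tryCatch({
        run <- run_simulation(tree, tests$params[[i]], seed = seed)
        at <- intron_attributes(run$leaves, tree, bootstrap_reps = bootstrap_reps,
                                aligner = aligner)
        dplyr::bind_cols(meta, tibble::tibble(rep = r, seed = seed), at,
                         tibble::tibble(status = "ok"))
      }, error = function(e) {
        dplyr::bind_cols(meta, tibble::tibble(
          rep = r, seed = seed, L_MSA = NA_integer_, R_K2I = NA_real_,
          Dbar = NA_real_, SEDbar = NA_real_, TS_ML = NA_integer_,
          n_undefined_pairs = NA_integer_, status = conditionMessage(e)))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full L16 orthogonal screen for one mode
#'
#' @param mode `"MD"` or `"MI"`.
#' @inheritParams run_tests
#' @return The [run_tests()] result table (16 x `reps` rows).
#' @export
run_orthogonal <- function(mode = c("MD", "MI"), tree, reps = 10L,
                           master_seed = 1L, bootstrap_reps = 500L,
                           aligner = "builtin") {
  mode <- match.arg(mode)
  run_tests(materialize_tests(mode), tree, reps = reps,
            master_seed = master_seed, bootstrap_reps = bootstrap_reps,
            aligner = aligner)
}

#' Synthetic reference intron set
#'
#' Stands in for the real chordate intron sequences (which are not
#' redistributable here): one MD run with the `MD_23` parameter set over the
#' guide tree, whose 14 leaf sequences carry exactly the per-leaf target
#' lengths.  Clearly synthetic: its attribute values emulate the shape of a
#' real reference set, not its published numbers.
#'
#' @param tree Guide tree (default [fixture_tree()]).
#' @param seed Seed for the generating run.
#' @return Named character vector of leaf sequences.
#' @export
synthetic_reference_set <- function(tree = fixture_tree(), seed = 2020L) {
  run <- run_simulation(tree, NAMED_TESTS_params("MD_23"), seed = seed)
  run$leaves
}

NAMED_TESTS_params <- function(id) {
  v <- NAMED_TESTS[[id]]
  if (is.null(v)) stop("unknown test id: ", id, call. = FALSE)
  params_from_values(v[[1]], v[[2]], v[[3]], v[[4]], v[[5]], v[[6]])
}

#' Reference attribute distribution by 1-base perturbation
#'
#' Each replicate gives every reference sequence exactly one substitution at
#' a uniformly chosen internal position (lengths unchanged), then recomputes
#' the five attributes with a full realignment.  Attributes are summarized
#' as mean and standard deviation across replicates -- the "reference
#' distribution" that model runs are t-tested against.
#'
#' @param ref_seqs Named character vector matching `ref_tree` leaves.
#' @param ref_tree Reference guide tree.
#' @param reps Perturbation replicates (default 10).
#' @param seed Seed.
#' @param r_ratio Transition/transversion ratio for the perturbing
#'   substitutions.
#' @param n_mutations Substitutions per sequence per replicate (default 1;
#'   0 gives an unperturbed control).
#' @param bootstrap_reps,aligner Passed to [intron_attributes()].
#' @return A `reference_distribution`: list with `replicates` (tibble, one
#'   row per replicate) and `summary` (tibble `attribute`, `mean`, `sd`).
#' @export
perturb_reference <- function(ref_seqs, ref_tree, reps = 10L, seed = NULL,
                              r_ratio = 1.5, n_mutations = 1L,
                              bootstrap_reps = 500L, aligner = "builtin") {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(reps), function(r) {
    pert <- vapply(ref_seqs,
                   function(s) mutate_bases(s, n_mutations, r_ratio = r_ratio)$seq,
                   character(1))
    at <- intron_attributes(pert, ref_tree, bootstrap_reps = bootstrap_reps,
                            aligner = aligner)
    dplyr::bind_cols(tibble::tibble(rep = r), at)
  })
  replicates <- dplyr::bind_rows(rows)
  attrs <- c("L_MSA", "R_K2I", "Dbar", "SEDbar", "TS_ML")
  summary <- tibble::tibble(
    attribute = attrs,
    mean = vapply(attrs, function(a) mean(replicates[[a]]), numeric(1)),
    sd = vapply(attrs, function(a) stats::sd(replicates[[a]]), numeric(1))
  )
  structure(list(replicates = replicates, summary = summary, reps = reps),
            class = "reference_distribution")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat("<reference_distribution> ", x$reps, " perturbation replicates\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Compare model runs against the reference distribution
#'
#' For every test in a [run_tests()] result table and every attribute, runs
#' an independent two-sample t test of the replicate values against the
#' reference replicates and attaches significance stars
#' (`*` P < .1, `**` P < .05, `***` P < .01).
#'
#' @param results A [run_tests()] result tibble.
#' @param reference A [perturb_reference()] result.
#' @param pooled Use the pooled-variance t test (default) or Welch.
#' @return Tibble: `test_id`, `attribute`, group means/sds, `t`, `df`, `p`,
#'   `stars`.
#' @export
compare_to_reference <- function(results, reference, pooled = TRUE) {
  attrs <- c("L_MSA", "R_K2I", "Dbar", "SEDbar", "TS_ML")
  ok <- results[results$status == "ok", , drop = FALSE]
  out <- list()
  for (id in unique(ok$test_id)) {
    sub <- ok[ok$test_id == id, ]
    for (a in attrs) {
      x <- sub[[a]]; y <- reference$replicates[[a]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      tt <- t_compare(x, y, pooled = pooled)
      out[[length(out) + 1L]] <- tibble::tibble(
        test_id = id, attribute = a,
        mean_model = mean(x), sd_model = stats::sd(x),
        mean_reference = mean(y), sd_reference = stats::sd(y),
        t = tt$t, df = tt$df, p = tt$p, stars = tt$stars
      )
    }
  }
  dplyr::bind_rows(out)
}
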