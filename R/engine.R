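#' Model parameter sets for the MD and MI simulators
#'
#' The five adjustable parameters of both models: the length of the first
#' ancestral sequence (`l_as1`), the length of the last backbone ancestor
#' (`l_as12`), the number of bases mutated per unit branch length (`m1`),
#' and the per-event size ranges for indels (`l_id`) and mutations (`m_id`).
#' In MD mode a long ancestor shrinks by block deletion
#' (`l_as1 >= l_as12`); in MI mode a short ancestor grows by block
#' insertion (`l_as1 <= l_as12`).
#'
#' @param mode `"MD"` (mutation-and-deletion) or `"MI"`
#'   (mutation-and-insertion).
#' @param l_as1,l_as12 Lengths in bases of the first and last backbone
#'   ancestral sequences.
#' @param m1 Substitutions per unit branch length (> 0).
#' @param l_id,m_id Inclusive integer ranges `c(lo, hi)`: bases
#'   inserted/deleted per indel event, and bases mutated per mutation event.
#' @param r_ratio Transition/transversion ratio (default 1.5).
#' @param seed Optional integer seed recorded with the run.
#' @return A `model_params` object.
#' @export
#' @examples
#' model_params("MD", 6000, 2000, 800, c(31, 50), c(21, 30))
model_params <- function(mode, l_as1, l_as12, m1, l_id, m_id,
                         r_ratio = 1.5, seed = NULL) {
  mode <- match.arg(mode, c("MD", "MI"))
  stopifnot(length(l_id) == 2L, length(m_id) == 2L)
  if (l_id[1] > l_id[2] || m_id[1] > m_id[2]) stop("empty event-size range", call. = FALSE)
  if (m1 <= 0) stop("m1 must be positive", call. = FALSE)
  if (mode == "MD" && l_as1 < l_as12) stop("MD requires l_as1 >= l_as12", call. = FALSE)
  if (mode == "MI" && l_as1 > l_as12) stop("MI requires l_as1 <= l_as12", call. = FALSE)
  structure(
    list(mode = mode, l_as1 = as.integer(l_as1), l_as12 = as.integer(l_as12),
         m1 = as.numeric(m1), l_id = as.integer(l_id), m_id = as.integer(m_id),
         r_ratio = r_ratio, seed = seed),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %s: L_AS1=%d L_AS12=%d M_1=%g L_I/D=%d-%d M_I/D=%d-%d R=%g\n",
              x$mode, x$l_as1, x$l_as12, x$m1, x$l_id[1], x$l_id[2],
              x$m_id[1], x$m_id[2], x$r_ratio))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

# backbone depth (1-based index along AS_1..AS_k) for every internal node;
# off-backbone internal nodes inherit the depth of their nearest backbone
# ancestor
backbone_depths <- function(ph, backbone) {
  nt <- ape::Ntip(ph)
  labs <- vapply(seq_len(ph$Nnode), function(i) node_label(ph, nt + i), character(1))
  depth <- setNames(rep(NA_real_, ph$Nnode), labs)
  idx <- match(backbone, labs)
  depth[idx] <- seq_along(backbone)
  # inherit down the tree for unlabeled / off-backbone internal nodes
  kids <- phylo_children(ph)
  walk <- function(node, d) {
    if (node <= nt) return(invisible(NULL))
    i <- node - nt
    if (is.na(depth[i])) depth[i] <<- d else d <- depth[i]
    for (k in kids[[node]]) walk(k, d)
  }
  walk(phylo_root(ph), 1)
  depth
}

#' Plan per-node target lengths and per-branch mutation budgets
#'
#' Assigns `l_as1` to the root and `l_as12` to the last backbone ancestor,
#' linearly interpolates the interior backbone lengths between them, then
#' runs a monotonicity repair pass clamping each interior node so that along
#' every root-to-leaf path lengths are non-increasing (MD) or non-decreasing
#' (MI) and every ancestor is strictly longer (MD) / shorter (MI) than each
#' of its leaf children.  The endpoint nodes stay fixed at their parameter
#' values; an infeasible endpoint (e.g. MD with `l_as12` at or below a leaf
#' child's target) makes the plan invalid.  Per-edge mutation budgets are
#' `round(m1 * branch_length)` (half-up).
#'
#' @param tree A `guide_tree`.
#' @param params A [model_params()] object.
#' @return A `stage_plan`: list with `node_length` (named numeric),
#'   `budgets` (tibble `parent`, `child`, `branch_length`,
#'   `mutation_target`), `feasible`, and a `violations` tibble of
#'   (ancestor, leaf) pairs breaking the validity constraint.
#' @export
plan_stages <- function(tree, params) {
  ph <- tree$phylo
  nt <- ape::Ntip(ph)
  backbone <- tree$backbone
  if (is.null(backbone)) stop("tree has no AS_* backbone labels", call. = FALSE)
  k <- length(backbone)
  md <- params$mode == "MD"

  depth <- backbone_depths(ph, backbone)
  interp <- params$l_as1 + (depth - 1) / max(k - 1, 1) * (params$l_as12 - params$l_as1)
  interp <- round_half_up(interp)

  kids <- phylo_children(ph)
  labs_int <- names(depth)
  last_bb <- backbone[k]
  fixed <- setNames(rep(NA_real_, ph$Nnode), labs_int)
  fixed[backbone[1]] <- params$l_as1
  fixed[last_bb] <- params$l_as12

  # tightest bound each internal node must respect from below (MD: lower
  # bound = leaf child target + 1 and bounds of internal children; MI mirrored)
  bound <- setNames(rep(if (md) -Inf else Inf, ph$Nnode), labs_int)
  comb <- if (md) max else min
  post <- function(node) {
    if (node <= nt) return(invisible(NULL))
    lab <- node_label(ph, node)
    b <- if (md) -Inf else Inf
    for (ch in kids[[node]]) {
      post(ch)
      if (ch <= nt) {
        tgt <- tree$leaf_specs[ph$tip.label[ch]]
        b <- comb(b, if (md) tgt + 1 else tgt - 1)
      } else {
        clab <- node_label(ph, ch)
        b <- comb(b, if (!is.na(fixed[clab])) fixed[clab] else bound[clab])
      }
    }
    bound[lab] <<- b
    invisible(NULL)
  }
  post(phylo_root(ph))

  len <- setNames(rep(NA_real_, ph$Nnode), labs_int)
  pre <- function(node, parent_len) {
    if (node <= nt) return(invisible(NULL))
    lab <- node_label(ph, node)
    v <- if (!is.na(fixed[lab])) {
      fixed[lab]
    } else {
      v0 <- if (md) max(interp[lab], bound[lab]) else min(interp[lab], bound[lab])
      if (!is.na(parent_len)) v0 <- if (md) min(v0, parent_len) else max(v0, parent_len)
      v0
    }
    len[lab] <<- v
    for (ch in kids[[node]]) pre(ch, v)
  }
  pre(phylo_root(ph), NA_real_)

  # validity scan: every internal node vs each of its leaf children
  viol <- list()
  for (node in (nt + 1L):(nt + ph$Nnode)) {
    lab <- node_label(ph, node)
    for (ch in kids[[node]]) {
      if (ch <= nt) {
        leaf <- ph$tip.label[ch]
        tgt <- tree$leaf_specs[leaf]
        bad <- if (md) len[lab] <= tgt else len[lab] >= tgt
        if (bad) viol[[length(viol) + 1L]] <- tibble::tibble(
          ancestor = lab, leaf = leaf,
          ancestor_length = unname(len[lab]), leaf_length = unname(tgt))
      }
    }
  }
  # monotone breaks against fixed endpoints
  mono_ok <- TRUE
  for (i in seq_len(nrow(ph$edge))) {
    p <- ph$edge[i, 1]; c_ <- ph$edge[i, 2]
    if (c_ > nt) {
      lp <- len[node_label(ph, p)]; lc <- len[node_label(ph, c_)]
      if ((md && lc > lp) || (!md && lc < lp)) mono_ok <- FALSE
    }
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(ancestor = character(), leaf = character(),
                   ancestor_length = numeric(), leaf_length = numeric())

  edges <- tibble::tibble(
    parent = vapply(ph$edge[, 1], function(n) node_label(ph, n), character(1)),
    child = vapply(ph$edge[, 2], function(n) node_label(ph, n), character(1)),
    branch_length = ph$edge.length,
    mutation_target = as.integer(round_half_up(params$m1 * ph$edge.length))
  )
  structure(
    list(node_length = len, budgets = edges,
         feasible = mono_ok && nrow(violations) == 0L,
         violations = violations, params = params),
    class = "stage_plan"
  )
}

#' Check MD/MI validity of a parameter set on a guide tree
#'
#' Plans the stage lengths and reports every (ancestor, leaf-child) pair
#' whose planned ancestral length fails to be strictly longer (MD) or
#' strictly shorter (MI) than the leaf's target length.
#'
#' @inheritParams plan_stages
#' @return A list with `valid` (logical) and `violations` (tibble).
#' @export
#' @examples
#' tr <- fixture_tree(seed = 1)
#' validate_params(tr, model_params("MD", 6000, 2000, 800, c(31, 50), c(21, 30)))
validate_params <- function(tree, params) {
  plan <- plan_stages(tree, params)
  list(valid = plan$feasible, violations = plan$violations)
}

#' Evolve one branch: alternate mutation and indel until both targets are met
#'
#' Starting from the parent sequence, repeatedly applies a mutation event of
#' `min(draw(m_id), remaining_mutations)` bases followed by an indel event of
#' `min(draw(l_id), remaining_length_change)` bases (deletion in MD,
#' insertion in MI), until the mutation budget is spent and the sequence has
#' exactly `child_target_len` bases.  Final partial draws are capped, never
#' redrawn, so terminal lengths are exact for every seed.
#'
#' @param parent_seq Nucleotide string.
#' @param child_target_len Exact target length in bases.
#' @param mutation_target Total substitutions to apply on this branch.
#' @param params A [model_params()].
#' @return List with `seq` and a `ledger` of transition/transversion counts.
#' @export
evolve_branch <- function(parent_seq, child_target_len, mutation_target, params) {
  len <- nchar(parent_seq)
  md <- params$mode == "MD"
  child_target_len <- as.integer(child_target_len)
  if (md && len < child_target_len) {
    stop("MD branch needs parent length >= child target (", len, " < ",
         child_target_len, ")", call. = FALSE)
  }
  if (!md && len > child_target_len) {
    stop("MI branch needs parent length <= child target (", len, " > ",
         child_target_len, ")", call. = FALSE)
  }
  seq <- parent_seq
  rem_mut <- as.integer(mutation_target)
  rem_len <- abs(child_target_len - len)
  ledger <- empty_ledger()
  repeat {
    did <- FALSE
    if (rem_mut > 0L) {
      mutable <- max(nchar(seq) - 4L, 0L)
      m <- min(draw_from_range(params$m_id[1], params$m_id[2]), rem_mut, mutable)
      if (m > 0L) {
        res <- mutate_bases(seq, m, r_ratio = params$r_ratio)
        seq <- res$seq
        ledger <- merge_ledgers(ledger, res$ledger)
        rem_mut <- rem_mut - m
        did <- TRUE
      }
    }
    if (rem_len > 0L) {
      l <- min(draw_from_range(params$l_id[1], params$l_id[2]), rem_len)
      seq <- if (md) delete_block(seq, l) else insert_block(seq, l)
      rem_len <- rem_len - l
      did <- TRUE
    }
    if (rem_mut == 0L && rem_len == 0L) break
    if (!did) stop("branch evolution stalled: no mutable sites and no length change left", call. = FALSE)
  }
  list(seq = seq, ledger = ledger)
}

#' Run a full MD or MI simulation over a guide tree
#'
#' Generates the root ancestral sequence at `l_as1` bases, then evolves every
#' branch in pre-order with [evolve_branch()], producing one sequence per
#' ancestral node and one per leaf (exactly at its target length).
#'
#' @inheritParams plan_stages
#' @param seed Integer seed; overrides `params$seed` when given.
#' @return An `intron_run`: list with `ancestors` and `leaves` (named
#'   character vectors), `ledgers` (per-edge tibble), `plan`, `params`,
#'   `seed`.
#' @export
#' @examples
#' tr <- fixture_tree(seed = 1)
#' run <- run_simulation(tr, named_tests("MD")$params[[7]], seed = 42)
#' nchar(run$leaves[["Cm376"]])
run_simulation <- function(tree, params, seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  plan <- plan_stages(tree, params)
  if (!plan$feasible) {
    stop("invalid parameter set for this tree; violations at: ",
         paste(unique(plan$violations$ancestor), collapse = ", "), call. = FALSE)
  }
  ph <- tree$phylo
  nt <- ape::Ntip(ph)
  kids <- phylo_children(ph)
  seqs <- setNames(vector("list", nt + ph$Nnode), NULL)
  root <- phylo_root(ph)
  seqs[[root]] <- random_sequence(params$l_as1)
  ledgers <- list()

  visit <- function(node) {
    for (ch in kids[[node]]) {
      tgt <- if (ch <= nt) tree$leaf_specs[ph$tip.label[ch]]
             else plan$node_length[node_label(ph, ch)]
      edge_i <- which(ph$edge[, 1] == node & ph$edge[, 2] == ch)
      mt <- plan$budgets$mutation_target[edge_i]
      res <- evolve_branch(seqs[[node]], tgt, mt, params)
      seqs[[ch]] <<- res$seq
      ledgers[[length(ledgers) + 1L]] <<- tibble::tibble(
        parent = node_label(ph, node), child = node_label(ph, ch),
        mutation_target = mt,
        n_transitions = res$ledger$n_transitions,
        n_transversions = res$ledger$n_transversions
      )
      if (ch > nt) visit(ch)
    }
  }
  visit(root)

  anc_idx <- (nt + 1L):(nt + ph$Nnode)
  ancestors <- setNames(unlist(seqs[anc_idx]),
                        vapply(anc_idx, function(n) node_label(ph, n), character(1)))
  leaves <- setNames(unlist(seqs[seq_len(nt)]), ph$tip.label)
  structure(
    list(ancestors = ancestors, leaves = leaves,
         ledgers = dplyr::bind_rows(ledgers), plan = plan, params = params,
         seed = seed, tree = tree),
    class = "intron_run"
  )
}

#' @export
print.intron_run <- function(x, ...) {
  cat("<intron_run> ", x$params$mode, " model: ", length(x$ancestors),
      " ancestors + ", length(x$leaves), " leaves\n", sep = "")
  cat("  leaf lengths: ", paste(range(nchar(x$leaves)), collapse = "-"), " bases\n", sep = "")
  invisible(x)
}

#' @export
tidy.intron_run <- function(x, ...) {
  dplyr::mutate(x$ledgers,
                n_substitutions = .data$n_transitions + .data$n_transversions)
}

#' @export
glance.intron_run <- function(x, ...) {
  tibble::tibble(
    mode = x$params$mode,
    n_leaves = length(x$leaves),
    n_ancestors = length(x$ancestors),
    total_transitions = sum(x$ledgers$n_transitions),
    total_transversions = sum(x$ledgers$n_transversions),
    min_leaf_length = min(nchar(x$leaves)),
    max_leaf_length = max(nchar(x$leaves)),
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' Write an intron run to FASTA plus a JSON manifest
#'
#' The FASTA holds the ancestor records (`AS_*`) followed by the leaf
#' records; the manifest records parameters, seed, package version and the
#' per-edge ledger totals.
#'
#' @param run An `intron_run`.
#' @param dir Output directory (created if needed).
#' @param stem File stem (default `"run"`).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir, stem = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(stem, ".fasta"))
  manifest <- file.path(dir, paste0(stem, "_manifest.json"))
  write_fasta(c(run$ancestors, run$leaves), fasta)
  jsonlite::write_json(
    list(
      package = "intronsim",
      version = as.character(utils::packageVersion("intronsim")),
      seed = run$seed,
      params = run$params[c("mode", "l_as1", "l_as12", "m1", "l_id", "m_id", "r_ratio")],
      ledger = run$ledgers
    ),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(fasta = fasta, manifest = manifest))
}
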