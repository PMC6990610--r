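#' Guide trees
#'
#' A guide tree is the rooted display of an unrooted binary tree with N
#' leaves and N-2 internal "ancestral sequence" nodes (`AS_1` ... `AS_k`):
#' the root `AS_1` has three children, every other internal node two.  Leaf
#' labels are species abbreviations followed by the target intron length in
#' bases (e.g. `"Cm376"`), so the tree itself carries the per-leaf length
#' table used by the simulators.
#'
#' @name guide_tree
NULL

new_guide_tree <- function(phylo, backbone = NULL) {
  specs <- leaf_lengths_from_labels(phylo$tip.label)
  structure(
    list(phylo = phylo, leaf_specs = specs, backbone = backbone),
    class = "guide_tree"
  )
}

leaf_lengths_from_labels <- function(labels) {
  len <- suppressWarnings(as.integer(sub("^.*?(\\d+)$", "\\1", labels)))
  setNames(len, labels)
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("<guide_tree> ", length(x$phylo$tip.label), " leaves, ",
      x$phylo$Nnode, " internal nodes\n", sep = "")
  if (all(!is.na(x$leaf_specs))) {
    cat("  leaf target lengths: ", min(x$leaf_specs), "-", max(x$leaf_specs),
        " bases\n", sep = "")
  }
  invisible(x)
}

#' Parse and write Newick guide trees
#'
#' `parse_newick()` accepts a Newick string (or path to a file containing
#' one) with branch lengths; internal node labels are retained.
#' `write_newick()` serializes a guide tree back to Newick.
#'
#' @param text Newick string, or a file path when `file = TRUE`.
#' @param file Read `text` as a file path.
#' @param tree A `guide_tree`.
#' @return `parse_newick()` returns a `guide_tree`; `write_newick()` a
#'   Newick string (invisibly the path when `path` is given).
#' @export
parse_newick <- function(text, file = FALSE) {
  ph <- tryCatch(
    suppressWarnings(if (file) ape::read.tree(text) else ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(ph)) stop("malformed Newick input", call. = FALSE)
  backbone <- grep("^AS_\\d+$", ph$node.label, value = TRUE)
  backbone <- backbone[order(as.integer(sub("AS_", "", backbone)))]
  new_guide_tree(ph, backbone = if (length(backbone)) backbone else NULL)
}

#' @rdname parse_newick
#' @param path Optional output file path.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree$phylo)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(path))
  }
  txt
}

# species abbreviations used for the default 14-leaf fixture, ordered by
# position on the backbone ladder (root first)
FIXTURE_SPECIES <- c("Bf", "Bb", "Cm", "Ch", "Xl", "Xt", "Cp", "Cy", "Gg",
                     "Rt", "Ac", "Mm", "Hs", "Am")

#' Generate a reference-style guide tree fixture
#'
#' Builds a ladder-like rooted display with `n_leaves` leaves and
#' `n_leaves - 2` internal nodes `AS_1 ... AS_k`: the root `AS_1` carries two
#' leaves and the backbone child `AS_2`; each interior backbone node carries
#' one leaf; the final backbone node carries two leaves.  For the default
#' `n_leaves = 14` the leaf length table anchors the three chordate lengths
#' 112 (`Rt112`, on `AS_9`), 376 (`Cm376`, on `AS_2`) and 1975 (`Am1975`, on
#' `AS_12`); the remaining lengths are drawn uniformly on `length_range`.
#' Branch lengths are uniform draws on `branch_range`
#' (substitution-distance-like units).
#'
#' @param seed Integer seed; the same seed yields an identical tree.
#' @param n_leaves Number of leaves (>= 4).
#' @param branch_range Range for uniform branch-length draws.
#' @param length_range Range for the free leaf target lengths.
#' @return A `guide_tree`.
#' @export
#' @examples
#' fixture_tree(seed = 1)
fixture_tree <- function(seed = 1L, n_leaves = 14L,
                         branch_range = c(0.05, 0.60),
                         length_range = c(150L, 1800L)) {
  n_leaves <- as.integer(n_leaves)
  if (n_leaves < 4L) stop("n_leaves must be >= 4", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  k <- n_leaves - 2L  # internal nodes
  if (n_leaves == 14L) {
    abbr <- FIXTURE_SPECIES
    lens <- setNames(rep(NA_integer_, 14L), abbr)
    lens[c("Rt", "Cm", "Am")] <- c(112L, 376L, 1975L)
    free <- is.na(lens)
    lens[free] <- draw_from_range(length_range[1], length_range[2], sum(free))
  } else {
    # letter-only abbreviations so the trailing digits are the target length
    abbr <- paste0(rep(LETTERS, each = 26), letters)[seq_len(n_leaves)]
    lens <- setNames(draw_from_range(length_range[1], length_range[2], n_leaves), abbr)
  }
  labels <- paste0(abbr, lens)

  # leaf assignment along the ladder: AS_1 gets leaves 1-2, AS_2..AS_{k-1}
  # one leaf each, AS_k the last two
  bl <- function() round(stats::runif(1, branch_range[1], branch_range[2]), 4)
  leaf <- function(i) paste0(labels[i], ":", bl())
  nwk <- paste0("(", leaf(n_leaves - 1L), ",", leaf(n_leaves), ")AS_", k, ":", bl())
  if (k > 2L) {
    for (j in rev(seq(2L, k - 1L))) {
      nwk <- paste0("(", leaf(j + 1L), ",", nwk, ")AS_", j, ":", bl())
    }
  }
  nwk <- paste0("(", leaf(1L), ",", leaf(2L), ",", nwk, ")AS_1;")
  parse_newick(nwk)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# --- tree anatomy helpers (on ape phylo) -------------------------------------

phylo_children <- function(ph) {
  n_nodes <- ape::Ntip(ph) + ph$Nnode
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(ph$edge))) {
    p <- ph$edge[i, 1]
    kids[[p]] <- c(kids[[p]], ph$edge[i, 2])
  }
  kids
}

phylo_root <- function(ph) ape::Ntip(ph) + 1L

node_label <- function(ph, node) {
  nt <- ape::Ntip(ph)
  if (node <= nt) ph$tip.label[node]
  else if (!is.null(ph$node.label) && nzchar(ph$node.label[node - nt])) ph$node.label[node - nt]
  else paste0("node", node)
}

#' Ladderized layout of a guide tree
#'
#' Produces the deterministic drawing used by the topology score: at every
#' internal node children are ordered by descendant-leaf count (larger clade
#' on top), ties broken by the lexicographically smallest descendant leaf
#' label; leaves then occupy rows `0 .. N-1` top to bottom and each internal
#' node sits at the mean row of its children.  For each leaf the layout
#' records its *branch form* -- `"INV_L_SHAPE"` if the leaf sits strictly
#' above its parent node (by more than half a row), `"L_SHAPE"` if strictly
#' below, `"STRAIGHT"` otherwise -- and its *relative location*: the label of
#' the leaf in the row immediately above (`"TOP"` for the topmost leaf).
#'
#' @param tree A `guide_tree` (or object with a `$phylo`).
#' @return A tibble with columns `leaf`, `row`, `parent_row`, `form`,
#'   `above`, of class `ladder_layout`.
#' @export
ladder_layout <- function(tree) {
  ph <- if (inherits(tree, "phylo")) tree else tree$phylo
  nt <- ape::Ntip(ph)
  kids <- phylo_children(ph)
  n_nodes <- nt + ph$Nnode

  n_desc <- integer(n_nodes)
  min_leaf <- character(n_nodes)
  fill <- function(node) {
    if (node <= nt) {
      n_desc[node] <<- 1L
      min_leaf[node] <<- ph$tip.label[node]
    } else {
      for (k in kids[[node]]) fill(k)
      n_desc[node] <<- sum(n_desc[kids[[node]]])
      min_leaf[node] <<- min(min_leaf[kids[[node]]])
    }
  }
  root <- phylo_root(ph)
  fill(root)

  row <- numeric(n_nodes)
  parent_row_of_leaf <- numeric(nt)
  next_row <- 0L
  place <- function(node) {
    if (node <= nt) {
      row[node] <<- next_row
      next_row <<- next_row + 1L
      return(invisible(NULL))
    }
    ks <- kids[[node]]
    ord <- order(-n_desc[ks], min_leaf[ks])
    for (k in ks[ord]) place(k)
    row[node] <<- mean(row[ks])
    invisible(NULL)
  }
  place(root)
  for (i in seq_len(nrow(ph$edge))) {
    child <- ph$edge[i, 2]
    if (child <= nt) parent_row_of_leaf[child] <- row[ph$edge[i, 1]]
  }

  ord <- order(row[seq_len(nt)])
  leaves <- ph$tip.label[ord]
  leaf_rows <- row[seq_len(nt)][ord]
  prow <- parent_row_of_leaf[ord]
  diff <- prow - leaf_rows
  form <- ifelse(abs(diff) < 0.5, "STRAIGHT",
                 ifelse(diff > 0, "INV_L_SHAPE", "L_SHAPE"))
  above <- c("TOP", leaves[-length(leaves)])
  out <- tibble::tibble(
    leaf = leaves, row = as.integer(leaf_rows), parent_row = prow,
    form = form, above = above
  )
  class(out) <- c("ladder_layout", class(out))
  out
}

lookup_layout <- function(layout, leaf) {
  i <- match(leaf, layout$leaf)
  if (is.na(i)) stop("unknown leaf: ", leaf, call. = FALSE)
  i
}

#' Branch form and relative location of a leaf
#'
#' Accessors into a [ladder_layout()].
#'
#' @param layout A `ladder_layout`.
#' @param leaf Leaf label.
#' @return `branch_form()` one of `"L_SHAPE"`, `"INV_L_SHAPE"`,
#'   `"STRAIGHT"`; `relative_location()` the label of the leaf directly
#'   above, or `"TOP"`.
#' @export
branch_form <- function(layout, leaf) layout$form[lookup_layout(layout, leaf)]

#' @rdname branch_form
#' @export
relative_location <- function(layout, leaf) layout$above[lookup_layout(layout, leaf)]
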