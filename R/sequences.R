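#' @useDynLib intronsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats sd setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# transition partners; everything else is one of two transversions
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

as_base_vector <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) strsplit(seq, "", fixed = TRUE)[[1]] else as.character(seq)
}

as_base_string <- function(v) paste0(v, collapse = "")

check_bases <- function(v) {
  bad <- setdiff(unique(v), DNA_BASES)
  if (length(bad)) {
    stop("sequence contains characters outside {A,C,G,T}: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(v)
}

#' Replace sequence termini with the canonical intron dinucleotides
#'
#' Overwrites the first two bases with `GT` and the last two with `AG`, the
#' splice-site signature of a spliceosomal intron.  All interior bases are
#' untouched and the length is unchanged.
#'
#' @param seq A nucleotide string over `{A,C,G,T}`.
#' @return The capped sequence string.
#' @export
#' @examples
#' cap_termini("AAAAAA")
cap_termini <- function(seq) {
  v <- as_base_vector(seq)
  n <- length(v)
  if (n < 4L) stop("sequence must be at least 4 bases long to carry GT...AG termini", call. = FALSE)
  check_bases(v)
  v[1:2] <- c("G", "T")
  v[(n - 1L):n] <- c("A", "G")
  as_base_string(v)
}

#' Generate a random intron-like sequence
#'
#' Bases are drawn i.i.d. uniformly over `{A,G,T,C}` and the termini are then
#' capped with `GT`/`AG` (see [cap_termini()]).  Randomness comes from R's
#' global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param length Number of bases (at least 4).
#' @return A nucleotide string of exactly `length` bases.
#' @export
random_sequence <- function(length) {
  length <- as.integer(length)
  if (is.na(length) || length < 4L) stop("length must be an integer >= 4", call. = FALSE)
  cap_termini(sample(DNA_BASES, length, replace = TRUE))
}

#' Substitute bases at a fixed transition/transversion ratio
#'
#' Each input base is replaced by a different base: its transition partner
#' (A<->G, C<->T) with probability `r_ratio / (r_ratio + 1)`, otherwise one of
#' its two transversion partners with equal probability.  With `r_ratio = 0`
#' transitions never occur.
#'
#' @param bases Character vector of single bases in `{A,C,G,T}`.
#' @param r_ratio Transition/transversion ratio (default 1.5).
#' @return Character vector of substituted bases, same length as `bases`.
#' @export
#' @examples
#' set.seed(1)
#' table(substitute_bases(rep("A", 1000), r_ratio = 1.5))
substitute_bases <- function(bases, r_ratio = 1.5) {
  check_bases(bases)
  if (r_ratio < 0) stop("r_ratio must be non-negative", call. = FALSE)
  n <- length(bases)
  if (n == 0L) return(character(0))
  is_ts <- stats::runif(n) < r_ratio / (r_ratio + 1)
  out <- character(n)
  out[is_ts] <- TRANSITION_OF[bases[is_ts]]
  if (any(!is_ts)) {
    tv <- which(!is_ts)
    # the two transversion partners of any base are the two bases of the
    # other chemical class; pick each with probability 1/2
    pur <- c("A", "G")
    pyr <- c("C", "T")
    pick <- stats::runif(length(tv)) < 0.5
    from_pur <- bases[tv] %in% pur
    out[tv] <- ifelse(from_pur, ifelse(pick, "C", "T"), ifelse(pick, "A", "G"))
  }
  unname(out)
}

#' Count transitions between two equal-length base vectors
#' @noRd
count_transitions <- function(old, new) {
  changed <- old != new
  sum(changed & new == TRANSITION_OF[old])
}

empty_ledger <- function() {
  list(n_transitions = 0L, n_transversions = 0L, positions = integer(0))
}

merge_ledgers <- function(a, b) {
  list(
    n_transitions = a$n_transitions + b$n_transitions,
    n_transversions = a$n_transversions + b$n_transversions,
    positions = c(a$positions, b$positions)
  )
}

#' Mutate a sequence at n distinct positions
#'
#' Samples `n` positions uniformly without replacement (within this call) and
#' applies a substitution at each, drawn at the configured
#' transition/transversion ratio.  Sequence length is unchanged.  When
#' `protect_termini` is `TRUE` (default) the terminal `GT`/`AG` dinucleotides
#' are never touched.
#'
#' @param seq Nucleotide string.
#' @param n Number of positions to substitute.
#' @param r_ratio Transition/transversion ratio.
#' @param protect_termini Protect the first and last two bases.
#' @return A list with elements `seq` (mutated string) and `ledger`
#'   (`n_transitions`, `n_transversions`, `positions`, 1-based).
#' @export
mutate_bases <- function(seq, n, r_ratio = 1.5, protect_termini = TRUE) {
  v <- as_base_vector(seq)
  check_bases(v)
  n <- as.integer(n)
  len <- length(v)
  sites <- if (protect_termini) seq.int(3L, len - 2L) else seq_len(len)
  if (protect_termini && len < 5L) sites <- integer(0)
  if (n > length(sites)) {
    stop("cannot mutate ", n, " positions: only ", length(sites), " mutable sites", call. = FALSE)
  }
  if (n == 0L) return(list(seq = as_base_string(v), ledger = empty_ledger()))
  pos <- sites[sample.int(length(sites), n)]
  old <- v[pos]
  new <- substitute_bases(old, r_ratio)
  v[pos] <- new
  n_ts <- count_transitions(old, new)
  list(
    seq = as_base_string(v),
    ledger = list(
      n_transitions = as.integer(n_ts),
      n_transversions = as.integer(n - n_ts),
      positions = as.integer(pos)
    )
  )
}

#' Delete a contiguous internal block of bases
#'
#' Removes one block of `block_len` bases at a uniformly chosen internal
#' position, never touching the terminal `GT`/`AG`, so the result still
#' starts `GT` and ends `AG`.
#'
#' @param seq Nucleotide string.
#' @param block_len Bases to delete (`0 <= block_len <= nchar(seq) - 4`).
#' @return The shortened sequence string.
#' @export
delete_block <- function(seq, block_len) {
  v <- as_base_vector(seq)
  len <- length(v)
  block_len <- as.integer(block_len)
  if (block_len == 0L) return(as_base_string(v))
  if (block_len < 0L || block_len > len - 4L) {
    stop("block_len must be between 0 and length - 4 (= ", len - 4L, ")", call. = FALSE)
  }
  # block must stay within the internal region [3, len - 2]
  starts <- 3L:(len - 1L - block_len)
  s <- starts[sample.int(length(starts), 1L)]
  as_base_string(v[-(s:(s + block_len - 1L))])
}

#' Insert a random block of bases at an internal junction
#'
#' Inserts `block_len` i.i.d. uniform bases after a uniformly chosen internal
#' position (strictly inside the terminal dinucleotides).
#'
#' @inheritParams delete_block
#' @param block_len Bases to insert (non-negative).
#' @return The lengthened sequence string.
#' @export
insert_block <- function(seq, block_len) {
  v <- as_base_vector(seq)
  len <- length(v)
  block_len <- as.integer(block_len)
  if (block_len < 0L) stop("block_len must be non-negative", call. = FALSE)
  if (block_len == 0L) return(as_base_string(v))
  if (len < 4L) stop("sequence must be at least 4 bases long", call. = FALSE)
  # junction after position j keeps GT prefix and AG suffix intact
  j <- sample(2L:(len - 2L), 1L)
  ins <- sample(DNA_BASES, block_len, replace = TRUE)
  as_base_string(c(v[1:j], ins, v[(j + 1L):len]))
}

#' Draw a uniform integer from an inclusive range
#'
#' Event sizes (bases mutated or inserted/deleted per event) are modelled as
#' uniform draws from an inclusive integer range rather than fixed numbers.
#'
#' @param lo,hi Inclusive integer bounds, `lo <= hi`.
#' @param n Number of draws.
#' @return Integer vector of length `n`.
#' @export
draw_from_range <- function(lo, hi, n = 1L) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo > hi) stop("invalid range: lo > hi", call. = FALSE)
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers around Biostrings I/O operating on named character vectors.
#' Lines are wrapped at 70 columns on write.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
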