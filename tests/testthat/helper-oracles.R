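# Independent oracles used across test files.  These deliberately share no
# code with the package implementation.

# Mean pairwise K2P distance by direct looping over all unordered row pairs.
brute_force_dbar <- function(rows) {
  ids <- names(rows)
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  ds <- c()
  for (i in seq_len(nrow(mat) - 1)) {
    for (j in (i + 1):nrow(mat)) {
      a <- mat[i, ]; b <- mat[j, ]
      ok <- a != "-" & b != "-"
      n <- sum(ok)
      if (n == 0) next
      ts_pairs <- c("AG", "GA", "CT", "TC")
      diffs <- ok & a != b
      ts <- sum(paste0(a, b)[diffs] %in% ts_pairs)
      tv <- sum(diffs) - ts
      P <- ts / n; Q <- tv / n
      if (1 - 2 * P - Q > 0 && 1 - 2 * Q > 0) {
        ds <- c(ds, -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)))
      }
    }
  }
  mean(ds)
}

# Duncan homogeneous subsets by exhaustive interval enumeration: every
# consecutive interval of ranked means whose range is under its least
# significant range is homogeneous; report the maximal ones.
brute_force_duncan <- function(values, groups, alpha = 0.05) {
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  k <- length(means)
  fit <- anova(lm(values ~ factor(groups)))
  mse <- fit$`Mean Sq`[2]
  dfe <- fit$Df[2]
  ns <- table(groups)
  n_h <- k / sum(1 / as.numeric(ns))
  se <- sqrt(mse / n_h)
  intervals <- list()
  for (i in 1:k) {
    for (j in i:k) {
      p <- j - i + 1
      ok <- if (p == 1) TRUE else {
        lsr <- qtukey((1 - alpha)^(p - 1), p, dfe) * se
        (means[i] - means[j]) < lsr + 1e-12
      }
      if (ok) intervals[[length(intervals) + 1]] <- c(i, j)
    }
  }
  maximal <- Filter(function(iv) {
    !any(vapply(intervals, function(o) {
      (o[1] <= iv[1] && o[2] >= iv[2]) && !(o[1] == iv[1] && o[2] == iv[2])
    }, logical(1)))
  }, intervals)
  lapply(maximal, function(iv) names(means)[iv[1]:iv[2]])
}

# A fixed 14-leaf tree shared across tests (cheap to rebuild; deterministic).
test_tree <- function() fixture_tree(seed = 1)

md23_params <- function() model_params("MD", 6000, 2000, 800, c(31, 50), c(21, 30))
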