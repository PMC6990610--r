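#' Significance stars at the 0.1 / 0.05 / 0.01 levels
#'
#' `***` for p < 0.01, `**` for p < 0.05, `*` for p < 0.1 (strict
#' inequalities), otherwise the empty string.
#'
#' @param p P value(s) in `[0, 1]`.
#' @return Character vector of star strings.
#' @export
star_level <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

#' Independent two-sample t test with star reporting
#'
#' Pooled-variance (default) or Welch two-sample t test, two-sided.  When
#' both samples are constant with equal means the statistic is defined as 0
#' with p = 1.
#'
#' @param x,y Numeric samples of size >= 2.
#' @param pooled Pooled-variance test (`TRUE`, default) or Welch.
#' @return An `intron_t` object (list with `t`, `df`, `p`, `stars`, group
#'   means and sds); see [generics::tidy()].
#' @export
#' @examples
#' t_compare(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
t_compare <- function(x, y, pooled = TRUE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  res <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      list(statistic = 0, parameter = length(x) + length(y) - 2, p.value = 1)
    } else {
      list(statistic = sign(mean(x) - mean(y)) * Inf,
           parameter = length(x) + length(y) - 2, p.value = 0)
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = pooled)
    list(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
         p.value = tt$p.value)
  }
  structure(
    list(t = res$statistic, df = res$parameter, p = res$p.value,
         stars = star_level(res$p.value),
         mean_x = mean(x), mean_y = mean(y),
         sd_x = stats::sd(x), sd_y = stats::sd(y),
         n_x = length(x), n_y = length(y), pooled = pooled),
    class = "intron_t"
  )
}

#' @export
print.intron_t <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.4g, p = %.4g %s\n", x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' @export
tidy.intron_t <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_x - x$mean_y, mean_x = x$mean_x, mean_y = x$mean_y,
    statistic = x$t, df = x$df, p.value = x$p, stars = x$stars,
    method = if (x$pooled) "pooled t" else "Welch t"
  )
}

#' Main-effects ANOVA over the orthogonal screen
#'
#' Fits a fixed-effects linear model of one attribute on the five design
#' factors as categorical main effects, with no interaction terms; the error
#' term is the residual of the all-main-effects model.  Reports per-factor F
#' statistics, degrees of freedom, p values and significance stars, plus the
#' observed per-level means used for optimal-level plots.
#'
#' @param results A [run_tests()] result tibble (the factor value columns
#'   `L_AS1`, `L_AS12`, `M_1`, `L_ID`, `M_ID` are treated as factors).
#' @param attribute Attribute column name (e.g. `"Dbar"`).
#' @return A `main_effects` object: list with `anova` (per-factor tibble),
#'   `level_means` (tibble `factor`, `level`, `mean`), `attribute`, `fit`.
#' @export
main_effects_anova <- function(results, attribute) {
  stopifnot(attribute %in% names(results))
  dat <- results[results$status == "ok" & !is.na(results[[attribute]]), , drop = FALSE]
  facs <- FACTOR_NAMES[vapply(FACTOR_NAMES, function(f) length(unique(dat[[f]])) > 1L, logical(1))]
  if (!length(facs)) stop("no factor varies in this result table", call. = FALSE)
  for (f in facs) dat[[f]] <- factor(dat[[f]])
  fml <- stats::as.formula(paste(attribute, "~", paste(facs, collapse = " + ")))
  fit <- stats::aov(fml, data = dat)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  resid_row <- terms == "Residuals"
  tab <- tibble::tibble(
    factor = terms[!resid_row],
    df = sm$Df[!resid_row],
    df_error = sm$Df[resid_row],
    statistic = sm$`F value`[!resid_row],
    p.value = sm$`Pr(>F)`[!resid_row]
  )
  if (stats::sd(dat[[attribute]]) == 0) {
    # a constant response carries no effect; avoid 0/0 floating noise
    tab$statistic <- 0
    tab$p.value <- 1
  }
  tab$stars <- ""
  ok_p <- !is.na(tab$p.value)
  tab$stars[ok_p] <- star_level(tab$p.value[ok_p])
  lm_rows <- lapply(facs, function(f) {
    agg <- stats::aggregate(dat[[attribute]], list(level = dat[[f]]), mean)
    tibble::tibble(factor = f, level = as.character(agg$level), mean = agg$x)
  })
  structure(
    list(anova = tab, level_means = dplyr::bind_rows(lm_rows),
         attribute = attribute, fit = fit,
         mse = sm$`Mean Sq`[resid_row], df_error = sm$Df[resid_row]),
    class = "main_effects"
  )
}

#' @export
print.main_effects <- function(x, ...) {
  cat("<main_effects> attribute:", x$attribute, "\n")
  print(x$anova)
  invisible(x)
}

#' @export
tidy.main_effects <- function(x, ...) x$anova

#' @export
glance.main_effects <- function(x, ...) {
  tibble::tibble(
    attribute = x$attribute,
    df_error = x$df_error,
    mse = x$mse,
    n = length(stats::residuals(x$fit))
  )
}

#' Duncan's multiple range test
#'
#' Ranks group means and performs the stepwise range comparisons of Duncan's
#' procedure: a set of `p` consecutively ranked means is homogeneous when
#' its range is below the least significant range
#' `R_p = q(alpha_p, p, df) * sqrt(MSE / n)` built from the studentized
#' range distribution at the protection level `alpha_p = 1 - (1-alpha)^(p-1)`.
#' Unbalanced group sizes are handled with the harmonic mean n (with a
#' warning).  The error mean square and df default to the one-way ANOVA of
#' the supplied groups but can be supplied from a wider model (e.g. the
#' main-effects ANOVA).
#'
#' @param values Numeric responses.
#' @param groups Group labels (same length as `values`).
#' @param alpha Significance level (default 0.05).
#' @param mse,df_error Optional error mean square and degrees of freedom.
#' @return A `duncan_mrt` object: list with `means` (tibble `group`, `n`,
#'   `mean`, `subsets`), `subsets` (list of character vectors, ordered by
#'   descending mean), `ranges` (tibble of least significant ranges).
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05, mse = NULL, df_error = NULL) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tabn <- table(groups)
  k <- length(tabn)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tabn < 2L) && is.null(mse)) stop("each group needs >= 2 samples", call. = FALSE)
  if (is.null(mse) || is.null(df_error)) {
    fit <- stats::aov(values ~ factor(groups))
    sm <- summary(fit)[[1]]
    mse <- sm$`Mean Sq`[2]
    df_error <- sm$Df[2]
  }
  if (length(unique(tabn)) > 1L) {
    warning("unbalanced groups: using harmonic mean group size")
  }
  n_h <- k / sum(1 / as.numeric(tabn))
  se <- sqrt(mse / n_h)
  means <- sort(vapply(split(values, groups), mean, numeric(1)), decreasing = TRUE)
  spans <- 2:k
  lsr <- if (se == 0) rep(0, length(spans)) else
    vapply(spans, function(p) stats::qtukey((1 - alpha)^(p - 1), p, df_error) * se,
           numeric(1))
  ranges <- tibble::tibble(span = spans, least_significant_range = lsr)

  # maximal runs of consecutively ranked means whose range is below the LSR
  homog <- function(i, j) {
    if (i == j) return(TRUE)
    (means[i] - means[j]) < lsr[match(j - i + 1L, spans)] + 1e-12
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && homog(i, j + 1L)) j <- j + 1L
    runs[[i]] <- c(i, j)
  }
  # drop runs contained in an earlier (longer) one
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (h in seq_len(k)) {
      if (h != i && runs[[h]][1] <= runs[[i]][1] && runs[[h]][2] >= runs[[i]][2] &&
          !(runs[[h]][1] == runs[[i]][1] && runs[[h]][2] == runs[[i]][2])) {
        keep[i] <- FALSE
      }
    }
  }
  subsets <- lapply(which(keep), function(i) names(means)[runs[[i]][1]:runs[[i]][2]])
  subsets <- unique(subsets)
  member <- vapply(names(means), function(g) {
    paste(which(vapply(subsets, function(s) g %in% s, logical(1))), collapse = ",")
  }, character(1))
  structure(
    list(
      means = tibble::tibble(group = names(means),
                             n = as.integer(tabn[names(means)]),
                             mean = unname(means), subsets = unname(member)),
      subsets = subsets, ranges = ranges, alpha = alpha,
      mse = mse, df_error = df_error
    ),
    class = "duncan_mrt"
  )
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat("<duncan_mrt> alpha =", x$alpha, "\n")
  print(x$means)
  invisible(x)
}

#' @export
tidy.duncan_mrt <- function(x, ...) x$means

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
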