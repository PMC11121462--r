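#' Descriptive summary of a measurement
#'
#' The eleven-column descriptive surface used throughout the reporting
#' tables: n, mean, sample SD (n − 1), two-sided t confidence interval for
#' the mean, variance, min, max and the 25/50/75 % quantiles (linear
#' interpolation between order statistics, quantile type 7).
#'
#' @param values numeric vector, n >= 1.
#' @param level confidence level (default 0.95).
#' @return A one-row tibble. For n = 1 the CI is `NA` (flagged via
#'   `ci_defined = FALSE`).
#' @export
describe <- function(values, level = 0.95) {
  if (!length(values)) stop("cannot describe an empty sequence")
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2) stats::sd(values) else NA_real_
  ci <- if (n >= 2) ci_mean(m, s, n, level) else c(NA_real_, NA_real_)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    n = n, mean = m, sd = s,
    ci_low = ci[1], ci_high = ci[2], ci_defined = n >= 2,
    var = s^2, min = min(values), max = max(values),
    q25 = q[1], median = q[2], q75 = q[3]
  )
}

#' Closed-form t confidence interval for a mean
#'
#' `mean` ± `qt(1 - (1 - level)/2, n - 1) * sd / sqrt(n)`. Used to audit
#' every published confidence-interval column from its printed (mean, SD,
#' n) triple.
#'
#' @param mean,sd,n summary statistics (`n >= 2`, `sd >= 0`).
#' @param level confidence level.
#' @return `c(low, high)`.
#' @examples
#' round(ci_mean(30.17, 8.07, 29), 2)  # 27.10 33.24
#' @export
ci_mean <- function(mean, sd, n, level = 0.95) {
  if (n < 2) stop("CI requires n >= 2")
  if (sd < 0) stop("sd must be non-negative")
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  c(mean - half, mean + half)
}

#' One-way ANOVA
#'
#' Classical fixed-effects decomposition with df (k − 1, N − k), computed by
#' `stats::aov`. A fully degenerate input (every value identical) returns
#' F = 0, p = 1 rather than NaN.
#'
#' @param groups list of numeric vectors (>= 2 groups, at least one with
#'   >= 2 values).
#' @return A list: `statistic`, `df`, `p_value`, `method`.
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 1L)) stop("every group needs at least one value")
  if (all(lengths(groups) < 2L)) stop("at least one group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  if (stats::var(y) == 0) {
    return(list(statistic = 0, df = c(df1, df2), p_value = 1,
                method = "one-way ANOVA"))
  }
  tab <- summary(stats::aov(y ~ g))[[1L]]
  f <- tab[["F value"]][1L]
  if (!is.finite(f)) f <- 0
  list(statistic = f, df = c(df1, df2),
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       method = "one-way ANOVA")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference on k − 1 df, via
#' `stats::kruskal.test`. A fully tied input (H undefined, 0/0) is an
#' error.
#'
#' @param groups list of numeric vectors (>= 2 groups, total N >= 3).
#' @return A list: `statistic` (H), `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  y <- unlist(groups, use.names = FALSE)
  if (length(y) < 3L) stop("need at least three values in total")
  if (length(unique(y)) == 1L) stop("all values tied: H is undefined")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(y, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, method = "Kruskal-Wallis")
}

#' Tukey HSD with compact letter display
#'
#' Pairwise comparisons after one-way ANOVA using the studentized-range
#' distribution (the Tukey-Kramer variant under unequal group sizes, via
#' `stats::TukeyHSD`), summarized as a compact letter display by the
#' standard insert-and-absorb algorithm: two groups share a letter iff
#' their adjusted p-value is >= `alpha`. Groups are processed in input
#' order, so letter assignment is deterministic.
#'
#' @param groups named (or unnamed) list of numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return A list: `letters` (named character vector, one letter string per
#'   group), `p_adjusted` (symmetric matrix of Tukey-adjusted p-values).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (any(lengths(groups) < 2L) && stats::var(y) == 0) {
    stop("cannot compare: singleton group with zero pooled variance")
  }
  fit <- stats::aov(y ~ g)
  hsd <- stats::TukeyHSD(fit)$g
  pmat <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (r in rownames(hsd)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1L]]
    pmat[pair[1L], pair[2L]] <- pmat[pair[2L], pair[1L]] <- hsd[r, "p adj"]
  }
  list(letters = compact_letters(pmat, alpha), p_adjusted = pmat)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb: start with one letter covering all groups; for each
#' significantly different pair covered by a common letter, split that
#' letter into two (each excluding one member of the pair), then absorb
#' letters whose group set is contained in another's. Letters are relabeled
#' a, b, c, ... in order of their first (input-order) member.
#'
#' @param pmat symmetric matrix of pairwise p-values with group dimnames.
#' @param alpha significance level.
#' @return Named character vector of letter strings; groups sharing any
#'   letter are statistically indistinguishable at `alpha`.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  gn <- rownames(pmat)
  k <- length(gn)
  sets <- list(seq_len(k))           # letter = set of member group indices
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (pmat[i, j] < alpha) {
        new_sets <- list()
        for (s in sets) {
          if (all(c(i, j) %in% s)) {
            new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        # absorb: drop any set contained in another
        keep <- rep(TRUE, length(new_sets))
        for (a in seq_along(new_sets)) {
          for (b in seq_along(new_sets)) {
            if (a != b && keep[b] &&
                all(new_sets[[a]] %in% new_sets[[b]]) &&
                (length(new_sets[[a]]) < length(new_sets[[b]]) ||
                   (length(new_sets[[a]]) == length(new_sets[[b]]) && a > b))) {
              keep[a] <- FALSE
              break
            }
          }
        }
        sets <- new_sets[keep]
      }
    }
  }
  ord <- order(vapply(sets, min, integer(1)))
  sets <- sets[ord]
  out <- character(k)
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  if (any(out == "")) stop("internal error: group left without a letter")
  stats::setNames(out, gn)
}

#' Pearson correlation matrix with significance stars
#'
#' Pairwise Pearson r between the nine physicochemical parameters, with
#' two-sided p-values from t = r sqrt((n - 2) / (1 - r^2)) and stars at
#' p < 0.05 (*), < 0.01 (**), < 0.001 (***). No multiplicity adjustment is
#' applied (the stars describe raw per-pair thresholds). A zero-variance
#' column yields `NA` correlations for its pairs.
#'
#' @param table a sample table (>= 3 rows).
#' @param parameters columns to correlate (default the nine measurements).
#' @return A list: `r` (symmetric matrix), `p` (matrix), `stars` (character
#'   matrix), `n`.
#' @export
pearson_matrix <- function(table, parameters = measurement_cols()) {
  X <- as.matrix(table[, parameters])
  n <- nrow(X)
  if (n < 3L) stop("need at least three complete records")
  zero_var <- apply(X, 2L, stats::var) == 0
  r <- suppressWarnings(stats::cor(X))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r) <- ifelse(zero_var, NA_real_, 1)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  list(r = r, p = p, stars = stars, n = n)
}
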