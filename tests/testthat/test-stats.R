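# brute-force Kruskal-Wallis through the rank-ANOVA identity:
# H = (N - 1) * SSB / SST computed on midranks (tie correction implicit)
kw_brute <- function(groups) {
  y <- unlist(groups)
  r <- rank(y)
  g <- rep(seq_along(groups), lengths(groups))
  rbar <- mean(r)
  ssb <- sum(tapply(r, g, function(x) length(x) * (mean(x) - rbar)^2))
  sst <- sum((r - rbar)^2)
  (length(y) - 1) * ssb / sst
}

test_that("describe matches hand arithmetic and handles degenerate input", {
  d <- describe(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$var, 1)
  expect_equal(d$median, 2)
  expect_equal(d$q25, 1.5) # linear interpolation between order statistics

  d0 <- describe(rep(5, 20))
  expect_equal(d0$sd, 0)
  expect_equal(c(d0$ci_low, d0$ci_high), c(5, 5))
  expect_equal(c(d0$q25, d0$median, d0$q75), c(5, 5, 5))

  d1 <- describe(7)
  expect_false(d1$ci_defined)
  expect_error(describe(numeric(0)), "empty")

  # internal consistency on arbitrary data
  set.seed(1)
  x <- rlnorm(57)
  d2 <- describe(x)
  expect_true(d2$ci_low <= d2$mean && d2$mean <= d2$ci_high)
  expect_true(d2$min <= d2$q25 && d2$q25 <= d2$median &&
                d2$median <= d2$q75 && d2$q75 <= d2$max)
  expect_equal(d2$var, d2$sd^2)
})

test_that("closed-form CI reproduces published summary rows", {
  # spot checks at 2 decimals
  expect_equal(round(ci_mean(30.17, 8.07, 29), 2), c(27.10, 33.24))
  # printed bounds derive from unrounded means, so allow the rounding band
  expect_lt(max(abs(ci_mean(16.19, 1.07, 213) - c(16.04, 16.33))), 0.01)
  expect_equal(ci_mean(12.3, 0, 10), c(12.3, 12.3))
  expect_error(ci_mean(5, 1, 1), "n >= 2")

  # full sweep over the embedded reference rows, +-0.01 rounding band
  ref <- read.csv(system.file("extdata", "ci_reference.csv",
                              package = "honeyaudit"))
  expect_gt(nrow(ref), 150)
  ci <- t(mapply(ci_mean, ref$mean, ref$sd, ref$n))
  err <- pmax(abs(ci[, 1] - ref$ci_low), abs(ci[, 2] - ref$ci_high))
  off <- which(err > 0.01)
  if (length(off)) {
    message("CI rows beyond the rounding band: ",
            paste(ref$parameter[off], ref$group[off], collapse = "; "))
  }
  expect_equal(length(off), 0L)
})

test_that("one-way ANOVA matches the classical decomposition", {
  # SSB = 6, SSW = 6 -> F = (6/2)/(6/6) = 3 on (2, 6) df
  res <- oneway_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$statistic, 3)
  expect_equal(res$df, c(2, 6))

  expect_equal(oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  expect_equal(oneway_anova(list(c(2, 2), c(2, 2)))$statistic, 0)
  expect_equal(oneway_anova(list(c(2, 2), c(2, 2)))$p_value, 1)

  # k = 2: F equals the squared pooled-variance t statistic
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(7 + i)
    b <- rnorm(12, mean = 0.5)
    f <- oneway_anova(list(a, b))$statistic
    t2 <- t.test(a, b, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2))
  }
})

test_that("Kruskal-Wallis equals the brute-force rank oracle exhaustively", {
  # H for {1,2} vs {3,4}: rank sums 3 and 7 -> 0.6 * 29 - 15 = 2.4
  res <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(res$statistic, 2.4)
  expect_equal(res$df, 1)
  expect_equal(kruskal_wallis(list(c(1, 3), c(2, 4)))$statistic,
               kw_brute(list(c(1, 3), c(2, 4))))

  # identical groups of distinct values -> H = 0
  expect_equal(kruskal_wallis(list(c(1, 5, 9), c(1, 5, 9)))$statistic, 0)

  # exhaustive sweep: all 2- and 3-part size compositions of N <= 8, with
  # tied and untied value patterns
  set.seed(11)
  for (N in 3:8) {
    for (k in 2:3) {
      sizes_list <- expand.grid(rep(list(1:(N - k + 1)), k))
      sizes_list <- sizes_list[rowSums(sizes_list) == N, , drop = FALSE]
      for (r in seq_len(nrow(sizes_list))) {
        sizes <- as.integer(sizes_list[r, ])
        for (vals in list(sample(N), sample(1:3, N, replace = TRUE))) {
          if (length(unique(vals)) == 1L) next
          groups <- split(vals, rep(seq_len(k), sizes))
          expect_equal(kruskal_wallis(groups)$statistic, kw_brute(groups),
                       tolerance = 1e-12)
        }
      }
    }
  }

  # rank invariance under strictly monotone transforms
  g <- list(c(0.2, 1.4, 2), c(0.5, 3.3), c(1.1, 7, 0.1))
  h0 <- kruskal_wallis(g)$statistic
  expect_equal(kruskal_wallis(lapply(g, exp))$statistic, h0)
  expect_equal(kruskal_wallis(lapply(g, function(x) x^3 + 5))$statistic, h0)

  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "tied")
})

test_that("Tukey letters separate what the pairwise tests separate", {
  set.seed(21)
  far <- list(a = rnorm(30, 0), b = rnorm(30, 100))
  expect_equal(unname(tukey_hsd(far)$letters), c("a", "b"))

  same <- list(g1 = rnorm(30), g2 = rnorm(30))
  expect_equal(unname(tukey_hsd(same)$letters), c("a", "a"))

  # three groups, middle indistinguishable from both ends
  tr <- list(lo = rnorm(40, 0, 1), mid = rnorm(40, 1.05, 1),
             hi = rnorm(40, 2.1, 1))
  lt <- tukey_hsd(tr)$letters
  expect_true(all(nchar(lt) >= 1))
  # groups sharing a letter iff adjusted p >= alpha
  p <- tukey_hsd(tr)$p_adjusted
  for (i in 1:2) for (j in (i + 1):3) {
    share <- length(intersect(strsplit(lt[[i]], "")[[1]],
                              strsplit(lt[[j]], "")[[1]])) > 0
    expect_equal(share, p[i, j] >= 0.05)
  }
})

test_that("compact letter display follows insert-and-absorb on a known matrix", {
  gn <- c("A", "B", "C", "D")
  p <- matrix(1, 4, 4, dimnames = list(gn, gn))
  p["A", "D"] <- p["D", "A"] <- 0.001
  p["A", "C"] <- p["C", "A"] <- 0.02
  lt <- compact_letters(p, alpha = 0.05)
  # A differs from C and D; B spans both letters
  expect_false(grepl("a", lt[["C"]]) && grepl("a", lt[["A"]]) &&
                 identical(lt[["A"]], lt[["C"]]))
  expect_true(length(intersect(strsplit(lt[["A"]], "")[[1]],
                               strsplit(lt[["D"]], "")[[1]])) == 0)
  expect_true(length(intersect(strsplit(lt[["A"]], "")[[1]],
                               strsplit(lt[["C"]], "")[[1]])) == 0)
  expect_true(length(intersect(strsplit(lt[["A"]], "")[[1]],
                               strsplit(lt[["B"]], "")[[1]])) > 0)
  expect_true(length(intersect(strsplit(lt[["B"]], "")[[1]],
                               strsplit(lt[["C"]], "")[[1]])) > 0)

  # all-indistinguishable: single letter
  p1 <- matrix(1, 3, 3, dimnames = list(gn[1:3], gn[1:3]))
  expect_equal(unname(compact_letters(p1)), c("a", "a", "a"))
  # all-different: distinct letters
  p0 <- matrix(0, 3, 3, dimnames = list(gn[1:3], gn[1:3]))
  diag(p0) <- 1
  expect_equal(unname(compact_letters(p0)), c("a", "b", "c"))
})

test_that("correlation matrix recovers exact linear dependence with stars", {
  tab <- make_samples(20,
                      sample_id = sprintf("P%02d", 1:20),
                      glu = seq(20, 39), fru = seq(20, 39),     # y = x
                      suc = 40 - seq(20, 39) / 2,               # y = -x/2
                      hmf = runif(20, 1, 30), acid = runif(20, 5, 45),
                      dia = runif(20, 9, 18), ins = runif(20, 0, 0.05),
                      mc = runif(20, 14, 19), econd = runif(20, 0.1, 0.7))
  cm <- pearson_matrix(tab)
  expect_equal(cm$r["glu", "fru"], 1)
  expect_equal(cm$stars["glu", "fru"], "***")
  expect_equal(cm$r["glu", "suc"], -1)
  expect_true(isSymmetric(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 9))

  # p-values agree with cor.test
  ct <- cor.test(tab$hmf, tab$acid)
  expect_equal(cm$p["hmf", "acid"], ct$p.value)

  # zero-variance column flagged as NA
  tab$ins <- 0.01
  cm2 <- pearson_matrix(tab)
  expect_true(all(is.na(cm2$r["ins", ])))
  expect_error(pearson_matrix(tab[1:2, ]), "three")
})
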