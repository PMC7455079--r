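mk_scores <- function(vals, modules, samples) {
  matrix(vals, length(modules), length(samples),
         dimnames = list(modules, samples))
}

test_that("normal range is the HC mean and n-1 SD", {
  sc <- mk_scores(c(0.1, 0.3, 0.5, 0.2), "M", paste0("s", 1:4))
  nr <- fit_normal_range(sc, c("s1", "s2"))
  expect_equal(nr$mean, 0.2)
  expect_equal(nr$sd, sqrt(0.02))        # two-point SD 0.1414...
  expect_equal(attr(nr, "n_hc"), 2L)
  expect_error(fit_normal_range(sc, "s1"), "at least 2")
  expect_error(fit_normal_range(sc, c("s1", "zzz")), "zzz")
})

test_that("trichotomization applies strict inequalities at mean +/- SD", {
  sc <- mk_scores(c(0, 0.1, 0.15, 0.1, -0.1, -0.15, 0.05), "M", paste0("p", 1:7))
  nr <- fit_normal_range(mk_scores(c(-0.1, 0.1), "M", c("h1", "h2")),
                         c("h1", "h2"))
  # mean 0, sd sqrt(0.02) ~ 0.1414
  calls <- trichotomize(sc, nr)
  expect_equal(unname(calls["M", ]), c(0L, 0L, 1L, 0L, 0L, -1L, 0L))
  # boundary exactly at mean + SD calls 0
  sc2 <- mk_scores(nr$mean + nr$sd, "M", "pb")
  expect_equal(unname(trichotomize(sc2, nr)["M", 1]), 0L)
})

test_that("identical HC scores give SD 0 and every deviation is called", {
  nr <- fit_normal_range(mk_scores(c(0.2, 0.2, 0.2), "M", paste0("h", 1:3)),
                         paste0("h", 1:3))
  expect_equal(nr$sd, 0)
  calls <- trichotomize(mk_scores(c(0.2, 0.2001, 0.1999), "M", paste0("p", 1:3)), nr)
  expect_equal(unname(calls["M", ]), c(0L, 1L, -1L))
})

test_that("null patients are called non-zero at the Gaussian tail rate", {
  set.seed(5)
  n_hc <- 5000L; n_pat <- 20000L
  hc <- mk_scores(stats::rnorm(n_hc, 0, 0.2), "M", paste0("h", 1:n_hc))
  pat <- mk_scores(stats::rnorm(n_pat, 0, 0.2), "M", paste0("p", 1:n_pat))
  nr <- fit_normal_range(hc, colnames(hc))
  calls <- trichotomize(pat, nr)
  frac <- mean(calls != 0L)
  expect_lt(abs(frac - 2 * (1 - stats::pnorm(1))), 0.02)  # ~ 31.7%
  # and each tail individually ~ 15.9%
  expect_lt(abs(mean(calls == 1L) - (1 - stats::pnorm(1))), 0.015)
})

test_that("group frequencies count and percentage correctly", {
  calls <- matrix(c(1L, 1L, 0L, -1L), 1, 4,
                  dimnames = list("M", paste0("p", 1:4)))
  fr <- group_frequencies(calls, stats::setNames(rep("G1", 4), paste0("p", 1:4)))
  expect_equal(fr$pct_up, 50)
  expect_equal(fr$pct_down, 25)
  # all-zero calls give zero percentages
  fr0 <- group_frequencies(matrix(0L, 2, 3, dimnames = list(c("A", "B"),
                                                            paste0("p", 1:3))),
                           stats::setNames(rep("G", 3), paste0("p", 1:3)))
  expect_true(all(fr0$pct_up == 0) && all(fr0$pct_down == 0))
})

test_that("frequency Fisher tests match hypergeometric enumeration", {
  calls <- matrix(c(rep(1L, 30), rep(0L, 70), rep(1L, 10), rep(0L, 90)), 1, 200,
                  dimnames = list("M", paste0("p", 1:200)))
  grouping <- stats::setNames(rep(c("G1", "G2"), each = 100), paste0("p", 1:200))
  fr <- group_frequencies(calls, grouping)
  ft <- frequency_tests(fr)
  p_up <- ft$p[ft$direction == "up"]
  expect_equal(p_up, enum_fisher_p(matrix(c(30, 70, 10, 90), 2, byrow = TRUE)),
               tolerance = 1e-9)
  # identical frequencies give p = 1
  calls2 <- matrix(rep(c(1L, 0L), 100), 1, 200,
                   dimnames = list("M", paste0("p", 1:200)))
  ft2 <- frequency_tests(group_frequencies(calls2, grouping))
  expect_equal(ft2$p[ft2$direction == "up"], 1)
})

test_that("the exact p for a 5/0 vs 0/5 split is 2/252", {
  calls <- matrix(c(rep(1L, 5), rep(0L, 5)), 1, 10,
                  dimnames = list("M", paste0("p", 1:10)))
  grouping <- stats::setNames(rep(c("A", "B"), each = 5), paste0("p", 1:10))
  ft <- frequency_tests(group_frequencies(calls, grouping))
  expect_equal(ft$p[ft$direction == "up"], 2 / 252, tolerance = 1e-12)
})

test_that("Welch pairwise tests match the textbook formula and Sidak", {
  x <- c(1.1, 2.3, 1.9); y <- c(3.2, 2.8, 4.1)
  sc <- mk_scores(c(x, y), "M", paste0("p", 1:6))
  grouping <- stats::setNames(rep(c("A", "B"), each = 3), paste0("p", 1:6))
  res <- pairwise_group_tests(sc, grouping, adjust = "none")
  se <- sqrt(stats::var(x) / 3 + stats::var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((stats::var(x) / 3)^2 / 2 + (stats::var(y) / 3)^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  # identical groups: t = 0, p = 1
  sc2 <- mk_scores(rep(c(1, 2, 3), 2), "M", paste0("p", 1:6))
  res2 <- pairwise_group_tests(sc2, grouping, adjust = "none")
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
  # Sidak adjustment over the pair family
  sc3 <- mk_scores(stats::rnorm(9), "M", paste0("p", 1:9))
  g3 <- stats::setNames(rep(c("A", "B", "C"), each = 3), paste0("p", 1:9))
  r3n <- pairwise_group_tests(sc3, g3, adjust = "none")
  r3s <- pairwise_group_tests(sc3, g3, adjust = "sidak")
  expect_equal(r3s$p_adj, 1 - (1 - r3n$p)^3)
})

test_that("Welch type-I error is near nominal under the null", {
  set.seed(6)
  reps <- 1000L
  p <- replicate(reps, {
    stats::t.test(stats::rnorm(8), stats::rnorm(8, sd = 2),
                  var.equal = FALSE)$p.value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("calls and frequencies are invariant to module order", {
  set.seed(7)
  sc <- matrix(stats::rnorm(40), 4, 10,
               dimnames = list(paste0("M", 1:4), paste0("p", 1:10)))
  hc <- paste0("p", 1:4)
  nr <- fit_normal_range(sc, hc)
  calls <- trichotomize(sc, nr)
  perm <- c(3, 1, 4, 2)
  calls_p <- trichotomize(sc[perm, ], nr)
  attr(calls_p, "qc") <- NULL               # matrix subsetting drops qc
  expect_equal(calls_p, calls[perm, ])
})
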