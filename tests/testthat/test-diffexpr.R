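null_expr <- function(n_genes, n1, n2, seed = 1L, sd = 0.5) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * (n1 + n2), 8, sd), n_genes, n1 + n2,
              dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n1 + n2))))
  list(expr = m, g1 = colnames(m)[seq_len(n1)],
       g2 = colnames(m)[n1 + seq_len(n2)])
}

test_that("moderated t is calibrated under the null", {
  fx <- null_expr(5000, 6, 6, seed = 2L)
  de <- moderated_t_test(fx$expr, fx$g1, fx$g2)
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.012)
  expect_lt(sum(de$q < 0.05), 5)
})

test_that("a strongly shifted gene attains the smallest q", {
  fx <- null_expr(2000, 20, 20, seed = 3L)
  fx$expr["g00042", fx$g1] <- fx$expr["g00042", fx$g1] + 3 * 0.5
  de <- moderated_t_test(fx$expr, fx$g1, fx$g2)
  expect_equal(de$gene[which.min(de$q)], "g00042")
  expect_gt(de$lfc[de$gene == "g00042"], 1)
})

test_that("d0 = 0 reproduces the ordinary equal-variance t", {
  fx <- null_expr(50, 5, 7, seed = 4L)
  de <- moderated_t_test(fx$expr, fx$g1, fx$g2, d0 = 0)
  ordinary <- vapply(rownames(fx$expr), function(g) {
    stats::t.test(fx$expr[g, fx$g1], fx$expr[g, fx$g2],
                  var.equal = TRUE)$statistic
  }, numeric(1))
  expect_equal(unname(de$t), unname(ordinary), tolerance = 1e-10)
})

test_that("the moderated t interpolates between ordinary t and pooled z", {
  fx <- null_expr(300, 4, 4, seed = 5L)
  t0 <- moderated_t_test(fx$expr, fx$g1, fx$g2, d0 = 0)$t
  t_inf <- moderated_t_test(fx$expr, fx$g1, fx$g2, d0 = Inf)$t
  t_est <- moderated_t_test(fx$expr, fx$g1, fx$g2)$t
  # shrinkage pulls extreme statistics toward the pooled statistic
  expect_true(stats::cor(t0, t_est) > 0.95 && stats::cor(t_inf, t_est) > 0.95)
  expect_lt(stats::sd(t_inf), stats::sd(t0))
})

test_that("the fitted variance prior agrees with the limma empirical Bayes fit", {
  fx <- null_expr(3000, 8, 8, seed = 6L)
  # make variances heterogeneous so the prior df is informative
  scale <- sqrt(stats::rchisq(3000, 5) / 5)
  fx$expr <- fx$expr * scale + 8 * (1 - scale)
  de <- moderated_t_test(fx$expr, fx$g1, fx$g2)
  design <- cbind(1, rep(c(1, 0), each = 8))
  fit <- limma::eBayes(limma::lmFit(fx$expr[, c(fx$g1, fx$g2)], design))
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(de, "s0_2"), fit$s2.prior, tolerance = 0.05)
  expect_equal(unname(de$t), unname(fit$t[, 2]), tolerance = 1e-6)
})

test_that("BH step-up matches the hand computation and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  p <- stats::runif(200)
  perm <- sample(200)
  q <- bh_adjust(p)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_true(all(q >= p))
})

test_that("randomized half-splits of a homogeneous group find nothing", {
  # independent matrix per replicate: discovery events on one matrix are
  # correlated across splits, so reuse would understate the zero rate
  counts <- vapply(1:10, function(s) {
    fx <- null_expr(3000, 40, 0, seed = 100L + s)
    randomization_control(fx$expr, colnames(fx$expr), seed = s)$n_deg
  }, numeric(1))
  expect_gte(sum(counts == 0), 8)
  # deterministic per seed
  fx <- null_expr(3000, 40, 0, seed = 9L)
  expect_identical(randomization_control(fx$expr, colnames(fx$expr), seed = 3L),
                   randomization_control(fx$expr, colnames(fx$expr), seed = 3L))
})

test_that("a secretly two-subtype group lights up under an aligned split", {
  set.seed(10)
  expr <- matrix(stats::rnorm(2000 * 40, 8, 0.4), 2000, 40,
                 dimnames = list(sprintf("g%05d", 1:2000),
                                 sprintf("s%03d", 1:40)))
  expr[1:100, 1:20] <- expr[1:100, 1:20] + 1.5   # planted subtype
  de <- moderated_t_test(expr, colnames(expr)[1:20], colnames(expr)[21:40])
  expect_gt(sum(de$q < 0.05), 80)
})

test_that("gene-list overlap matches the enumeration oracle", {
  universe <- sprintf("u%03d", 1:100)
  a <- universe[1:10]
  b <- c(universe[6:10], universe[90:94])   # overlap 5
  res <- overlap_test(a, b, universe)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p,
               enum_fisher_p(matrix(c(5, 5, 5, 85), 2, byrow = TRUE)),
               tolerance = 1e-9)
  expect_gt(res$odds_ratio, 1)
  # symmetry in the two lists
  expect_equal(overlap_test(b, a, universe)$p, res$p)
})

test_that("identical and disjoint lists sit at the overlap extremes", {
  universe <- sprintf("u%03d", 1:60)
  a <- universe[1:12]
  same <- overlap_test(a, a, universe)
  expect_equal(same$overlap, 12L)
  shifted <- overlap_test(a, c(a[1:11], universe[50]), universe)
  expect_lt(same$p, shifted$p)      # maximal overlap is minimal p
  disj <- overlap_test(universe[1:30], universe[31:60], universe)
  expect_lt(disj$odds_ratio, 1)
  expect_error(overlap_test(a, a, character(0)), "empty")
  expect_error(overlap_test(c(a, "zz"), a, universe), "subset")
})
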