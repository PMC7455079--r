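test_that("autoantibody flags map to the mutually exclusive serology groups", {
  md <- tibble::tibble(
    rnp   = c(TRUE,  TRUE,  FALSE, FALSE, FALSE),
    dsdna = c(TRUE,  FALSE, TRUE,  FALSE, FALSE),
    sm    = c(FALSE, TRUE,  FALSE, TRUE,  FALSE),
    ssa   = c(TRUE,  FALSE, FALSE, FALSE, FALSE),
    ssb   = c(FALSE, FALSE, TRUE,  FALSE, FALSE))
  expect_equal(autoantibody_group(md),
               c("RNP+dsDNA+", "RNP+dsDNA-", "RNP-dsDNA+", "Sm/SSA/SSB",
                 "negative"))
})

test_that("the default predictor matrix has exactly 26 binary columns", {
  md <- generate_metadata(cohort_config(
    n_per_ancestry = c(AA = 30, EA = 30, NAA = 30), n_hc = 5, seed = 2L))
  X <- build_predictor_matrix(md)
  expect_equal(ncol(X), 26L)
  expect_equal(nrow(X), 90L)
  expect_true(all(X %in% c(0L, 1L)))
  # serology group indicators are mutually exclusive
  sero <- X[, c("sero_RNPpos_dsDNApos", "sero_RNPpos_dsDNAneg",
                "sero_RNPneg_dsDNApos", "sero_SmSSASSB")]
  expect_true(all(rowSums(sero) <= 1))
  # ancestry indicators partition the patients
  expect_true(all(rowSums(X[, c("ancestry_AA", "ancestry_EA",
                                "ancestry_NAA")]) == 1))
})

test_that("spearman screen flags correlated pairs and keeps rank invariance", {
  set.seed(3)
  x <- stats::rnorm(200)
  res <- spearman_screen(cbind(a = x, b = exp(x)))   # monotone transform
  expect_equal(res$rho["a", "b"], 1)
  expect_equal(res$drop, "b")
  # engineered binary pair with rho = 0.56 is flagged at threshold 0.5
  x1 <- rep(c(1, 1, 0, 0), c(39, 11, 11, 39))
  x2 <- rep(c(1, 0, 1, 0), c(39, 11, 11, 39))
  res2 <- spearman_screen(cbind(u = x1, v = x2))
  expect_equal(unname(res2$rho["u", "v"]), 0.56, tolerance = 1e-10)
  expect_equal(res2$drop, "v")
  # independent binaries are not flagged
  set.seed(4)
  Xn <- matrix(stats::rbinom(400 * 4, 1, 0.4), 400, 4,
               dimnames = list(NULL, paste0("p", 1:4)))
  expect_length(spearman_screen(Xn)$drop, 0L)
  # constant columns warned and reported missing
  expect_warning(res3 <- spearman_screen(cbind(a = x, k = rep(1, 200))),
                 "constant")
  expect_true(is.na(res3$rho["a", "k"]))
})

test_that("a saturated single-predictor logistic fit equals the 2x2 odds ratio", {
  y <- rep(c(1, 1, 0, 0), c(40, 20, 10, 30))
  x <- rep(c(1, 0, 1, 0), c(40, 20, 10, 30))
  res <- logistic_fit(y, cbind(x = x))
  or <- res$table$or[res$table$term == "x"]
  expect_equal(or, (40 * 30) / (10 * 20), tolerance = 1e-6)  # 6.0
  # intercept-only on balanced outcomes gives intercept 0
  res0 <- logistic_fit(rep(c(0, 1), 25), matrix(numeric(0), 50, 0))
  expect_equal(res0$table$coef, 0, tolerance = 1e-9)
})

test_that("logistic fit detects separation and singular designs", {
  y <- rep(c(0, 1), each = 20)
  x_sep <- as.numeric(y)                      # perfect separation
  expect_error(logistic_fit(y, cbind(bad = x_sep)), "separation")
  set.seed(5)
  x <- stats::rbinom(40, 1, 0.5)
  expect_error(logistic_fit(y, cbind(a = x, b = x)), "singular")
})

test_that("null predictors yield small coefficients and uniform-ish p", {
  set.seed(6)
  n <- 4000L
  y <- stats::rbinom(n, 1, 0.4)
  X <- matrix(stats::rbinom(n * 3, 1, 0.5), n,
              dimnames = list(NULL, paste0("x", 1:3)))
  res <- logistic_fit(y, X)
  expect_true(all(abs(res$table$coef[-1L]) < 0.25))
})

test_that("stepwise recovers a planted predictor with a covering interval", {
  set.seed(7)
  n <- 2000L
  X <- matrix(stats::rbinom(n * 10, 1, 0.5), n,
              dimnames = list(NULL, paste0("x", 1:10)))
  eta <- -1 + 1.5 * X[, "x1"]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  res <- stepwise_select(y, X)
  expect_true("x1" %in% res$selected)
  row <- res$table[res$table$term == "x1", ]
  expect_true(row$ci_lo < exp(1.5) && exp(1.5) < row$ci_hi)
  expect_false(res$discarded)
})

test_that("a duplicated predictor never enters twice", {
  set.seed(8)
  n <- 800L
  x1 <- stats::rbinom(n, 1, 0.5)
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 1.2 * x1))
  X <- cbind(x1 = x1, x1_copy = x1, noise = stats::rbinom(n, 1, 0.5))
  res <- stepwise_select(y, X)
  expect_equal(sum(c("x1", "x1_copy") %in% res$selected), 1L)
})

test_that("stepwise with p_enter = 1 ranks candidates by score-test p first", {
  set.seed(9)
  n <- 600L
  x1 <- stats::rbinom(n, 1, 0.5)
  x2 <- stats::rbinom(n, 1, 0.5)
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 1.5 * x1 + 0.4 * x2))
  res <- stepwise_select(y, cbind(x1 = x1, x2 = x2), p_enter = 1,
                         p_remove = 1)
  expect_equal(res$selected[1L], "x1")    # strongest candidate enters first
})

test_that("Hosmer-Lemeshow rejects grossly mis-calibrated fits and guards df", {
  set.seed(10)
  n <- 600L
  p_true <- stats::runif(n, 0.1, 0.9)
  y <- stats::rbinom(n, 1, p_true)
  hl_bad <- hosmer_lemeshow(y, 1 - p_true)   # inverted probabilities
  expect_lt(hl_bad$p, 1e-6)
  hl_ok <- hosmer_lemeshow(y, p_true)
  expect_gt(hl_ok$p, 1e-4)
  expect_equal(hl_ok$df, 8L)
  expect_error(hosmer_lemeshow(y, p_true, g = 2L), "df")
})

test_that("odds-ratio edges follow the printed interval rule", {
  e1 <- or_to_edge("sero", "IGS", 31.6)
  expect_equal(e1$width_pt, 20L)
  expect_equal(e1$direction, "positive")
  e2 <- or_to_edge("aza", "NK_low", 4.8)
  expect_equal(e2$width_pt, 10L)
  e3 <- or_to_edge("mtx", "plasma_cell", 0.394)
  expect_equal(e3$display_or, 1 / 0.394, tolerance = 1e-12)  # 2.538
  expect_equal(e3$width_pt, 5L)
  expect_equal(e3$direction, "negative")
  expect_error(or_to_edge("a", "b", -2), "> 0")
})

test_that("edge widths are reciprocal-symmetric with flipped direction", {
  set.seed(11)
  for (or in exp(stats::runif(50, log(0.05), log(40)))) {
    e <- or_to_edge("a", "b", or)
    einv <- or_to_edge("a", "b", 1 / or)
    expect_equal(e$width_pt, einv$width_pt)
    if (abs(or - 1) > 1e-12) expect_false(e$direction == einv$direction)
  }
})

test_that("simple linear fits match closed-form least squares", {
  exact <- simple_linear_fit(1:10, 2 * (1:10) + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)
  hand <- simple_linear_fit(c(1, 2, 3), c(1, 3, 2))
  expect_equal(hand$slope, 0.5)
  expect_equal(hand$r_squared, 0.25)
  set.seed(12)
  noise <- simple_linear_fit(stats::rnorm(5000), stats::rnorm(5000))
  expect_lt(noise$r_squared, 0.01)
  expect_error(simple_linear_fit(rep(1, 5), stats::rnorm(5)), "constant")
})
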