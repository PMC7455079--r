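test_that("metadata generation is reproducible and respects configured sizes", {
  cfg <- cohort_config(n_per_ancestry = c(AA = 20, EA = 40, NAA = 15),
                       n_hc = 10, seed = 1L)
  m1 <- generate_metadata(cfg)
  m2 <- generate_metadata(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 20 + 40 + 15 + 10)
  expect_equal(sum(m1$is_control), 10)
  expect_equal(as.integer(table(m1$ancestry[!m1$is_control])[c("AA", "EA", "NAA")]),
               c(20L, 40L, 15L))
})

test_that("controls carry no disease flags and zero SLEDAI", {
  md <- generate_metadata(cohort_config(n_per_ancestry = c(AA = 5, EA = 5, NAA = 5),
                                        n_hc = 8, seed = 3L))
  hc <- md[md$is_control, ]
  flag_cols <- c("dsdna", "rnp", "sm", "ssa", "ssb", "c3_low", "c4_low",
                 "corticosteroids", "antimalarials", "nsaids", "aza", "mtx",
                 "mmf", "cyclophosphamide", "rash", "arthritis",
                 "mucosal_ulcers", "vasculitis", "alopecia", "age_gt50")
  for (cl in flag_cols) expect_false(any(hc[[cl]]), label = cl)
  expect_true(all(hc$sledai == 0L))
})

test_that("default frequencies reproduce the emulated cohort rates", {
  cfg <- cohort_config(n_per_ancestry = c(AA = 10000, EA = 0, NAA = 0),
                       n_hc = 0, seed = 5L)
  md <- generate_metadata(cfg)
  # anti-RNP 62% in AA, within 3 binomial SDs
  tol <- 3 * sqrt(0.62 * 0.38 / 10000)
  expect_lt(abs(mean(md$rnp) - 0.62), tol)
  # joint dsDNA & low complement 23% in AA
  joint <- mean(md$dsdna & (md$c3_low | md$c4_low))
  expect_lt(abs(joint - 0.23), 3 * sqrt(0.23 * 0.77 / 10000))
  # marginals: dsDNA 57.5%, low C 40%
  expect_lt(abs(mean(md$dsdna) - 0.575), 3 * sqrt(0.575 * 0.425 / 10000))
  expect_lt(abs(mean(md$c3_low | md$c4_low) - 0.40), 3 * sqrt(0.4 * 0.6 / 10000))
  # immunosuppressive composite 39% in AA
  is_any <- md$aza | md$mtx | md$mmf | md$cyclophosphamide
  expect_lt(abs(mean(is_any) - 0.39), 3 * sqrt(0.39 * 0.61 / 10000))
})

test_that("NAA patients get the elevated corticosteroid and IS rates", {
  cfg <- cohort_config(n_per_ancestry = c(AA = 0, EA = 0, NAA = 8000),
                       n_hc = 0, seed = 6L)
  md <- generate_metadata(cfg)
  expect_lt(abs(mean(md$corticosteroids) - 0.92), 3 * sqrt(0.92 * 0.08 / 8000))
  is_any <- md$aza | md$mtx | md$mmf | md$cyclophosphamide
  expect_lt(abs(mean(is_any) - 0.58), 3 * sqrt(0.58 * 0.42 / 8000))
})

test_that("degenerate all-zero frequencies give all-false flags", {
  fr <- default_frequencies()
  for (nm in setdiff(names(fr), c("is_split", "lowc_split", "duration"))) {
    fr[[nm]][] <- 0
  }
  md <- generate_metadata(cohort_config(n_per_ancestry = c(AA = 50, EA = 0, NAA = 0),
                                        n_hc = 0, frequencies = fr, seed = 2L))
  for (cl in c("dsdna", "rnp", "sm", "ssa", "ssb", "c3_low", "c4_low",
               "corticosteroids", "aza", "mtx", "mmf", "rash", "age_gt50")) {
    expect_false(any(md[[cl]]), label = cl)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_ancestry = c(AA = -1, EA = 5, NAA = 5)),
               "configuration error")
  fr <- default_frequencies()
  fr$rnp["AA"] <- 1.4
  expect_error(cohort_config(frequencies = fr), "configuration error")
})

test_that("expression generation is seed-deterministic", {
  cfg <- cohort_config(n_per_ancestry = c(AA = 5, EA = 5, NAA = 5),
                       n_hc = 4, seed = 9L)
  md <- generate_metadata(cfg)
  mods <- default_modules(1200, seed = 4L)
  e1 <- generate_expression(md, mods, n_genes = 1200, seed = 21L)
  e2 <- generate_expression(md, mods, n_genes = 1200, seed = 21L)
  expect_identical(e1, e2)
})

test_that("with no planted effects gene distributions match across ancestries", {
  cfg <- cohort_config(n_per_ancestry = c(AA = 150, EA = 150, NAA = 0),
                       n_hc = 0, seed = 13L)
  md <- generate_metadata(cfg)
  mods <- default_modules(1100, seed = 5L)
  expr <- generate_expression(md, mods, effects = effect_table(),
                              n_genes = 1100, seed = 22L)
  aa <- md$sample_id[md$ancestry == "AA"]
  ea <- md$sample_id[md$ancestry == "EA"]
  g <- mods$modules$plasma_cell[1L]
  expect_gt(stats::ks.test(expr[g, aa], expr[g, ea])$p.value, 0.01)
})

test_that("a planted module shift is recovered through the enrichment engine", {
  cfg <- cohort_config(n_per_ancestry = c(AA = 20, EA = 20, NAA = 0),
                       n_hc = 0, seed = 17L)
  md <- generate_metadata(cfg)
  mods <- default_modules(1100, seed = 6L)
  expr <- generate_expression(
    md, mods, effects = effect_table("ancestry:AA", "plasma_cell", 1.0),
    n_genes = 1100, seed = 23L)
  sc <- enrichment_scores(expr, mods)
  aa <- md$sample_id[md$ancestry == "AA"]
  ea <- md$sample_id[md$ancestry == "EA"]
  expect_gt(mean(sc["plasma_cell", aa]), mean(sc["plasma_cell", ea]))
})

test_that("default effect table plants the reported drug and serology directions", {
  eff <- default_effect_table()
  lookup <- function(cov, mod) eff$delta[eff$covariate == cov & eff$module == mod]
  expect_gt(lookup("corticosteroids", "LDG"), 0)
  expect_lt(lookup("mtx", "plasma_cell"), 0)
  expect_lt(lookup("aza", "NK_cell"), 0)
  expect_gt(lookup("serology:RNP+dsDNA+", "IGS"), 0)
})

test_that("effect table referencing an unknown module fails by name", {
  cfg <- cohort_config(n_per_ancestry = c(AA = 3, EA = 3, NAA = 3),
                       n_hc = 2, seed = 1L)
  md <- generate_metadata(cfg)
  mods <- default_modules(1100, seed = 7L)
  expect_error(
    generate_expression(md, mods,
                        effects = effect_table("mtx", "no_such_module", -1),
                        n_genes = 1100, seed = 1L),
    "no_such_module")
})
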