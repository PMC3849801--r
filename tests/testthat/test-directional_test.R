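test_that("fixture deltas reproduce the worked example in order", {
  dv <- replacement_deltas(sage1_replacements(), h_scale(), "from_minus_to")
  expect_equal(dv$values, table1_deltas)
  expect_identical(dv$scale_symbol, "h")
  neg <- replacement_deltas(sage1_replacements(), h_scale(), "to_minus_from")
  expect_equal(neg$values, -table1_deltas)
  empty <- replacement_list(integer(), character(), character(), 10)
  expect_error(replacement_deltas(empty, h_scale()), "empty")
})

test_that("t-test matches the independent oracle on the fixture", {
  dv <- replacement_deltas(sage1_replacements(), h_scale(), "from_minus_to")
  res <- directional_t_test(dv)
  expect_identical(res$n, 15L)
  expect_equal(res$net_change, 27.1)
  expect_identical(res$df, 14L)
  oracle <- stats::t.test(table1_deltas)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_two_tailed, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$net_change, res$n * res$mean)
})

test_that("t and p match stats::t.test over random vectors to 1e-9", {
  for (x in random_delta_vectors(200, seed = 11)) {
    res <- directional_t_test(x)
    oracle <- stats::t.test(x)
    expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(res$p_two_tailed, oracle$p.value, tolerance = 1e-9)
    expect_identical(res$df, length(x) - 1L)
  }
})

test_that("degenerate inputs are flagged, not dropped", {
  sym <- directional_t_test(c(1, -1))
  expect_identical(sym$t, 0)
  expect_identical(sym$p_two_tailed, 1)
  expect_false(sym$degenerate)

  const <- directional_t_test(c(2, 2, 2))
  expect_true(const$degenerate)
  expect_identical(const$p_two_tailed, 0)
  expect_identical(const$t, Inf)

  zeroes <- directional_t_test(c(0, 0))
  expect_true(zeroes$degenerate)
  expect_identical(zeroes$p_two_tailed, 1)

  single <- directional_t_test(5)
  expect_true(single$degenerate)
  expect_true(is.na(single$p_two_tailed))
  expect_true(single$low_n)

  expect_error(directional_t_test(numeric()), "empty")
})

test_that("p is invariant under the sign convention; t and net negate", {
  rl <- sample_null_replacements(12, seed = 3)
  a <- directional_t_test(replacement_deltas(rl, h_scale(), "to_minus_from"))
  b <- directional_t_test(replacement_deltas(rl, h_scale(), "from_minus_to"))
  expect_identical(a$p_two_tailed, b$p_two_tailed)
  expect_equal(a$t, -b$t)
  expect_equal(a$net_change, -b$net_change)
})

test_that("direction labels are consistent with p and the mean", {
  for (seed in 1:25) {
    rl <- sample_null_replacements(10, seed = seed)
    res <- directional_t_test(replacement_deltas(rl, h_scale()), alpha = 0.05)
    if (res$direction == "none") {
      expect_true(is.na(res$p_two_tailed) || res$p_two_tailed >= 0.05 ||
                    res$mean == 0)
    } else {
      expect_lt(res$p_two_tailed, 0.05)
      expect_identical(res$direction,
                       if (res$mean > 0) "increase" else "decrease")
    }
  }
})

test_that("panel runs one test per scale in library order", {
  panel <- run_property_panel(sage1_replacements(),
                              convention = "from_minus_to")
  expect_s3_class(panel, "directional_panel")
  expect_identical(nrow(panel), 25L)
  expect_identical(panel$scale, names(builtin_scales()))
  expect_true(all(panel$n == 15L))
  expect_false(any(panel$low_n))
  expect_equal(panel$net_change[panel$scale == "h"], 27.1)

  expect_identical(nrow(run_property_panel(sage1_replacements(),
                                           prop_library(list()))), 0L)
})

test_that("BH adjustment is additive and low-n sets the advisory flag", {
  rl <- sage1_replacements()
  raw <- run_property_panel(rl, convention = "from_minus_to")
  adj <- run_property_panel(rl, convention = "from_minus_to", adjust = TRUE)
  expect_identical(strip_df(raw), strip_df(adj)[names(strip_df(raw))])
  expect_equal(adj$p_adj, stats::p.adjust(raw$p, "BH"))

  small <- rl_small <- replacement_list(c(2, 5), c("C", "V"), c("R", "A"), 10)
  expect_true(all(run_property_panel(small)$low_n))
})

test_that("a failing scale is reported without aborting the panel", {
  lib <- builtin_scales()[c("h", "p")]
  broken <- unclass(lib)
  broken$p$values <- broken$p$values[1:5]  # corrupt after construction
  lib2 <- structure(broken, class = "prop_library")
  expect_warning(panel <- run_property_panel(sage1_replacements(), lib2),
                 "failed for scale")
  expect_identical(nrow(panel), 2L)
  expect_true(is.na(panel$error[panel$scale == "h"]))
  expect_false(is.na(panel$error[panel$scale == "p"]))
  expect_false(is.na(panel$t[panel$scale == "h"]))
})
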