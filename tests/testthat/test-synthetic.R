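test_that("configuration validation catches bad settings", {
  expect_error(sim_config(latent_dim = 15, n_features = 15), "smaller")
  expect_error(sim_config(missing_fraction = 1.2), "missing_fraction")
  expect_error(sim_config(pos_rate = 0), "pos_rate")
  expect_error(sim_config(quartile_window = c("q3", "q2")), "increasing")
  expect_error(sim_config(quartile_window = "q5"), "labels")
  expect_equal(sim_config(quartile_window = c("min", "max"))$quartile_window,
               c(0, 1))
})

test_that("the complete generator hits the target positive rate, rank and
          determinism", {
  g <- generate_complete(sim_config(n_instances = 10000, seed = 11))
  expect_lt(abs(mean(g$labels) - 0.118), 0.015)
  ## noiseless linear map: feature matrix has rank Q_true
  g0 <- generate_complete(sim_config(n_instances = 100, n_features = 8,
                                     latent_dim = 3, noise_var = 0,
                                     seed = 2))
  expect_equal(qr(g0$data$values)$rank, 3)
  ## determinism
  g2 <- generate_complete(sim_config(n_instances = 10000, seed = 11))
  expect_identical(g$data$values, g2$data$values)
  expect_identical(g$labels, g2$labels)
  ## columns standardized
  expect_equal(colMeans(g$data$values), rep(0, 15), tolerance = 1e-10,
               ignore_attr = TRUE)
  ## nonlinear map runs and keeps full rank
  gn <- generate_complete(sim_config(n_instances = 80, n_features = 6,
                                     latent_dim = 2,
                                     feature_map = "gp-sample", seed = 3))
  expect_gt(qr(gn$data$values)$rank, 2)
})

test_that("the regression-quartile mechanism masks exactly the selected
          instances by the stated rule", {
  g <- generate_complete(sim_config(n_instances = 500, seed = 7))
  Y <- g$data$values
  mm <- induce_missingness(Y, 0.2, c("q2", "q3"), seed = 5)
  sel <- attr(mm, "selected")
  expect_length(sel, 100L)                       # floor(0.2 * 500) exactly
  expect_true(all(rowSums(mm$mask)[-sel] == 0))  # untouched elsewhere
  ## independent re-evaluation of the rule, cell for cell
  for (j in seq_len(ncol(Y))) {
    fitj <- lm(Y[, j] ~ Y[, -j])$fitted.values
    b <- quantile(fitj, c(0.5, 0.75), names = FALSE)
    expected <- fitj[sel] >= b[1] & fitj[sel] <= b[2]
    expect_identical(unname(mm$mask[sel, j]), unname(expected))
  }
  ## per-feature masking rate among selected ~ window mass (25%)
  expect_equal(mean(mm$mask[sel, ]), 0.25, tolerance = 0.06)
  ## vacuous window masks everything in the selected rows
  mm_all <- induce_missingness(Y[1:50, ], 0.4, c("min", "max"), seed = 1)
  sel2 <- attr(mm_all, "selected")
  expect_true(all(mm_all$mask[sel2, ]))
  ## zero fraction: empty mask
  expect_equal(n_missing(induce_missingness(Y, 0, seed = 1)), 0L)
  ## observed-value variant differs but uses the same bounds
  mo <- induce_missingness(Y, 0.2, c("q2", "q3"), seed = 5,
                           rule = "observed")
  expect_identical(attr(mo, "selected"), sel)
  expect_false(identical(mo$mask, mm$mask))
})

test_that("benchmark bundles are consistent, replayable and round-trip
          through files bit-exactly", {
  b <- make_benchmark(sim_config(n_instances = 120, n_features = 8,
                                 seed = 13))
  ## masked values agree with truth on observed cells
  expect_equal(b$data$values[!b$data$mask], b$truth[!b$data$mask])
  ## manifest replay is bit-identical
  b2 <- make_benchmark(b$manifest)
  expect_identical(b$truth, b2$truth)
  expect_identical(b$data$mask, b2$data$mask)
  expect_identical(b$labels, b2$labels)
  ## file round trip
  d <- withr::local_tempdir()
  b3 <- make_benchmark(sim_config(n_instances = 40, n_features = 5,
                                  seed = 3), dir = d)
  expect_error(make_benchmark(sim_config(seed = 3), dir = d), "force")
  rt <- read_masked_csv(file.path(d, "masked.csv"))
  expect_identical(unname(rt$values), unname(b3$data$values))
  expect_identical(unname(rt$mask), unname(b3$data$mask))
  tr <- read_masked_csv(file.path(d, "truth.csv"))
  expect_identical(unname(tr$values), unname(b3$truth))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  b4 <- make_benchmark(man)
  expect_identical(b4$truth, b3$truth)
})
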