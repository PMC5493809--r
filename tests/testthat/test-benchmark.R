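test_that("rank AUC matches hand values and the exhaustive pairwise oracle", {
  expect_equal(auc_roc(c(5, 4, 1, 0.5), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_roc(rep(0.3, 6), c(1, 0, 1, 0, 0, 0)), 0.5)
  expect_equal(auc_roc(c(0.9, 0.8, 0.3), c(1, 0, 0)), 1)
  expect_error(auc_roc(1:3, c(1, 1, 1)), "single class")

  brute <- function(s, l) {
    pos <- s[as.logical(l)]; neg <- s[!as.logical(l)]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(13)
  for (k in 1:200) {
    n <- sample(4:12, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    l <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc_roc(s, l), brute(s, l))
  }
})

test_that("Brier score is the mean squared difference on [0,1] scores", {
  expect_equal(brier_score(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(brier_score(rep(0.5, 4), c(1, 0, 1, 0)), 0.25)
  expect_equal(brier_score(c(1, 0, 0.5), c(1, 0, 0)), 1 / 12)
  expect_error(brier_score(c(1.2, 0), c(1, 0)), "0, 1|\\[0, 1\\]")
})

test_that("scenario construction respects the study design", {
  spec <- scenario_spec("motif-cascade", "exogenous-input",
                        noise_level = 0.025, n_reps = 2, seed = 5)
  sc <- make_scenario(spec, 42)
  expect_length(sc$truth_nodes, 1)
  sc2 <- make_scenario(scenario_spec("motif-fanout", "exogenous-input",
                                     n_affected = 2, n_reps = 1, seed = 5), 42)
  expect_length(sc2$truth_nodes, 2)
  expect_s3_class(sc$data, "bden_data")
  # nominal kinetic parameters untouched when param_error = 0
  expect_equal(sc$nominal$kinetic_params,
               build_model("motif-cascade")$kinetic_params)
  # amplitude calibration: the pulse moves some observable by >= 5 noise sd
  y_true <- attr(sc$data, "truth")
  m <- build_model("motif-cascade")
  y_nom <- observe(m, integrate_model(m, m$default_grid), m$default_grid)
  sd_k <- 0.025 * abs(rowMeans(y_nom))
  expect_gte(max(abs(y_true - y_nom) / sd_k), 4.9)

  # removing the only matching interaction labels its two endpoints
  spec_rm <- scenario_spec("motif-coherent-ffl", "remove-interaction",
                           noise_level = 0.025, n_reps = 1, seed = 5)
  sc_rm <- make_scenario(spec_rm, 42)
  expect_equal(sort(build_model("motif-coherent-ffl")$species_names[sc_rm$truth_pair]),
               c("B", "C"))
  expect_equal(sc_rm$sign, "stim")

  # parameter perturbation bounded by the requested relative error
  spec_pe <- scenario_spec("motif-cascade", "exogenous-input",
                           noise_level = 0.025, param_error = 0.2,
                           n_reps = 1, seed = 5)
  sc_pe <- make_scenario(spec_pe, 43)
  rel <- abs(sc_pe$nominal$kinetic_params /
               build_model("motif-cascade")$kinetic_params - 1)
  expect_true(all(rel <= 0.2 + 1e-12) && any(rel > 0))

  expect_error(make_scenario(scenario_spec("motif-coherent-ffl",
                                           "add-interaction",
                                           n_reps = 1), 1),
               "infeasible")
})

test_that("noise is relative to each series mean", {
  m <- ode_model(function(x, u, t, p) c(0, 0), initial_state = c(4, 40),
                 default_grid = seq(0, 9, by = 1), name = "const")
  devs <- replicate(400, {
    d <- simulate_dataset(m, noise_level = 0.025)
    (d$values - attr(d, "truth"))[, 1]
  })
  expect_equal(sd(devs[1, ]), 0.1, tolerance = 0.1)     # 2.5% of mean 4
  expect_equal(sd(devs[2, ]), 1.0, tolerance = 0.1)     # 2.5% of mean 40
  # fixed seed: identical datasets
  d1 <- simulate_dataset(m, noise_level = 0.025, seed = 7)
  d2 <- simulate_dataset(m, noise_level = 0.025, seed = 7)
  expect_identical(d1$values, d2$values)
})

test_that("benchmark results are deterministic and bookkeeping is exact", {
  ctrl <- bden_control(n_samples = 90, n_burnin = 30, thin = 3, seed = 1)
  spec <- scenario_spec("motif-cascade", "exogenous-input",
                        noise_level = 0.025, n_reps = 2, seed = 77)
  b1 <- run_benchmark(spec, ctrl)
  b2 <- run_benchmark(spec, ctrl)
  expect_identical(b1$aucs, b2$aucs)
  expect_identical(b1$briers, b2$briers)
  expect_equal(b1$n_completed, 2)
  expect_true(all(b1$aucs >= 0 & b1$aucs <= 1))

  spec1 <- scenario_spec("motif-cascade", "exogenous-input",
                         noise_level = 0.025, n_reps = 1, seed = 78)
  b3 <- run_benchmark(spec1, ctrl)
  expect_equal(b3$mad_auc, 0)  # a single repetition has no dispersion
  tab <- benchmark_table(b1, b3)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$reps, c(2, 1))
})
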