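test_that("the model registry exposes the documented test systems", {
  nms <- list_models()
  expect_true(all(c("jak-stat", "gprotein", "uvb", "epor", "alpha-pinene",
                    "dream6") %in% nms))
  js <- build_model("jak-stat")
  expect_equal(js$n_states, 4)
  expect_equal(js$n_obs, 3)
  expect_equal(length(js$default_grid), 16)

  gp <- build_model("gprotein")
  expect_equal(gp$n_states, 6)
  tr <- integrate_model(gp, gp$default_grid)
  expect_equal(unname(observe(gp, tr)), tr$states)  # fully observed

  uv <- build_model("uvb")
  expect_equal(c(uv$n_states, uv$n_obs, length(uv$default_grid)), c(11, 5, 7))
  ep <- build_model("epor")
  expect_equal(c(ep$n_states, length(ep$default_grid)), c(6, 8))
  ap <- build_model("alpha-pinene")
  expect_equal(ap$n_states, 4)
  d6 <- build_model("dream6")
  expect_equal(d6$n_states, 12)
  expect_equal(length(d6$default_grid), 5)

  expect_error(build_model("nonexistent"), "available")
})

test_that("all five motifs integrate to bounded trajectories", {
  motifs <- list_motifs()
  expect_length(motifs, 5)
  for (m in motifs) {
    expect_true(m$n_states %in% c(3L, 4L))
    tr <- integrate_model(m, m$default_grid)
    expect_true(all(is.finite(tr$states)))
    expect_lt(max(abs(tr$states)), 100)
  }
})

test_that("every fixture integrates and rebuilds bit-identically from its spec file", {
  for (nm in list_models()) {
    m1 <- build_model(nm)
    m2 <- build_model(nm)
    t1 <- integrate_model(m1, m1$default_grid)$states
    t2 <- integrate_model(m2, m2$default_grid)$states
    expect_identical(t1, t2)
    expect_true(all(is.finite(t1)))
  }
})

test_that("total STAT5 mass is conserved along the closed cycle", {
  m <- build_model("jak-stat")
  x <- integrate_model(m, m$default_grid)$states
  total <- x[1, ] + x[2, ] + 2 * x[3, ] + 2 * x[4, ]
  expect_lt(max(abs(total - total[1])), 1e-4)
})

test_that("structural variants alter only the stated interaction", {
  m <- build_model("jak-stat")
  v <- model_variants(m)
  expect_true("no-nuclear-export" %in% v$name)
  expect_equal(v$mode[v$name == "no-nuclear-export"], "remove")
  nom <- variant_model(m, "no-nuclear-export")
  # the variant must differ from the base dynamics
  xb <- integrate_model(m, m$default_grid)$states
  xv <- integrate_model(nom, m$default_grid)$states
  expect_gt(max(abs(xb - xv)), 1e-3)
  expect_error(variant_model(m, "no-such-variant"), "unknown variant")
})

test_that("simulated datasets honour the noise design", {
  m <- build_model("motif-fanout")
  d0 <- simulate_dataset(m, noise_level = 1e-12, seed = 1)
  expect_equal(d0$values, attr(d0, "truth"), tolerance = 1e-9)

  set.seed(1)
  sds <- replicate(300, {
    d <- simulate_dataset(m, noise_level = 0.1)
    (d$values - attr(d, "truth"))[2, 5]
  })
  want <- 0.1 * abs(mean(attr(simulate_dataset(m, noise_level = 1e-12,
                                               seed = 1), "truth")[2, ]))
  expect_equal(sd(sds), want, tolerance = 0.15)
})

test_that("a model spec round-trips through the parser", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c(
    "name: rt-toy",
    "species: [S1, S2]",
    "initial: {S1: 1, S2: 0}",
    "parameters: {k: 0.5, d: 0.2}",
    "inputs:",
    "  pulse: \"t*exp(-t)\"",
    "rates:",
    "  S1: \"pulse - k*S1\"",
    "  S2: \"k*S1 - d*S2\"",
    "observables:",
    "  tot: \"S1 + S2\"",
    "time:",
    "  t0: 0",
    "  grid: [0, 1, 2, 3, 4]"), tf)
  m <- read_model_spec(tf)
  expect_equal(m$n_states, 2)
  expect_equal(m$n_obs, 1)
  tr <- integrate_model(m, m$default_grid)
  expect_true(all(is.finite(tr$states)))
  expect_equal(unname(observe(m, tr)[1, ]), colSums(tr$states))
  expect_error(read_model_spec(tempfile()), "not found")
})
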