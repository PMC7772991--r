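test_that("deconvolution solves the worked two-antibody systems", {
  # identity: F' = F
  eye <- xreact_matrix(diag(3), c("a", "b", "c"))
  F <- c(a = 5, b = 0, c = 12)
  expect_equal(deconvolve(eye, F)$F_prime, F)

  mat <- xreact_matrix(matrix(c(1, 0, 0.5, 1), 2, 2), c("a1", "a2"))
  sol <- deconvolve(mat, c(a1 = 10, a2 = 4))
  expect_equal(unname(sol$F_prime), c(8, 4))
  expect_lt(sol$residual, 1e-12)

  mat2 <- xreact_matrix(matrix(c(1, 0, 0.8, 1), 2, 2), c("a1", "a2"))
  sol2 <- deconvolve(mat2, c(a1 = 0.5, a2 = 10))
  expect_equal(unname(sol2$F_prime), c(-7.5, 10))  # negative F' is legitimate

  expect_error(deconvolve(mat, c(1, 2, 3)), "length")
})

test_that("solver matches independent Gaussian elimination on random chips", {
  set.seed(101)
  for (i in 1:200) {
    G <- random_xreact(n = 16, n_links = 28)
    F <- runif(16, 0, 5000)
    mine <- deconvolve(xreact_matrix(G), F)
    oracle <- gaussian_elimination(G, F)
    expect_lt(max(abs(unname(mine$F_prime) - oracle)) /
                max(abs(oracle)), 1e-8)
    expect_lt(mine$residual / sqrt(sum(F^2)), 1e-8)
    expect_false(mine$ill_conditioned)
  }
})

test_that("deconvolution is linear in the observed fluorescence", {
  set.seed(7)
  G <- random_xreact(n = 10, n_links = 15)
  mat <- xreact_matrix(G)
  F <- runif(10, 0, 1000)
  base <- deconvolve(mat, F)$F_prime
  for (a in c(0.1, 2, 37.5)) {
    expect_equal(deconvolve(mat, a * F)$F_prime, a * base,
                 tolerance = 1e-10)
  }
})

test_that("singular matrices fall back to minimum-norm least squares", {
  G <- matrix(c(1, 1, 1, 1), 2, 2)  # rank 1, violates unit-diagonal? no: diag = 1
  mat <- xreact_matrix(G, c("a", "b"))
  expect_warning(sol <- deconvolve(mat, c(a = 2, b = 2)), "ill-conditioned")
  expect_true(sol$ill_conditioned)
  # minimum-norm solution of x1 + x2 = 2 is (1, 1)
  expect_equal(unname(sol$F_prime), c(1, 1))
  expect_lt(sol$residual, 1e-10)
})

test_that("every decision-table combination yields exactly its one code", {
  grid <- decision_table()
  codes <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    codes[i] <- fsmi:::classify_one(grid$f_above[i], grid$fp_above[i],
                                    grid$ab_type[i], grid$consistency_ok[i])
  }
  expect_identical(codes, grid$expected)
  # totality/exclusivity: every combination got exactly one known code
  expect_true(all(codes %in% c("I", "II.a", "II.b", "III")))
  # B-type nodes never receive II.b
  expect_false(any(codes[grid$ab_type == "B"] == "II.b"))
})

test_that("classification reproduces the worked two-antibody examples", {
  mat <- xreact_matrix(matrix(c(1, 0, 0.5, 1), 2, 2), c("a1", "a2"))
  rep1 <- classify(mat, c(a1 = 5, a2 = 10), B = 1)
  expect_equal(unname(rep1$table$F_prime), c(0, 10))
  expect_equal(rep1$table$ab_type, c("B", "A"))
  expect_equal(rep1$table$presence, c("II.a", "III"))
  expect_equal(rep1$table$top_explainer[1], "a2")
  # full contribution breakdown: 0.5 x 10 from a2, 1 x 0 from itself
  expect_equal(explain(rep1, "a1"), c(a2 = 5, a1 = 0))
  # the II.a explaining set holds only the cross-reactor
  expect_equal(rep1$explanations[["a1"]], c(a2 = 5))

  mat2 <- xreact_matrix(matrix(c(1, 0, 0.8, 1), 2, 2), c("a1", "a2"))
  rep2 <- classify(mat2, c(a1 = 0.5, a2 = 10), B = 1)
  expect_equal(rep2$table$presence, c("I", "II.b"))
  expect_equal(rep2$table$ab_type, c("B", "A"))

  # all-zero fluorescence: everything code I
  rep3 <- classify(mat, c(a1 = 0, a2 = 0), B = 1)
  expect_true(all(rep3$table$presence == "I"))
})

test_that("contribution breakdown is ranked and conserves the observed F", {
  mat <- reference_matrix()
  fx <- demo_reactor_sample()
  report <- classify(mat, fx$F, fx$B)
  for (code in sample(mat$antibody_order, 6)) {
    contrib <- explain(report, code)
    expect_true(all(diff(contrib) <= 0))
    expect_equal(sum(contrib), unname(fx$F[code]), tolerance = 1e-8)
  }
  expect_error(explain(report, "nope"), "unknown")
  # identity matrix: a single self contribution
  eye <- xreact_matrix(diag(2), c("x", "y"))
  r <- classify(eye, c(x = 10, y = 0), B = 1)
  expect_equal(explain(r, "x"), c(x = 10))
})

test_that("demo samples reproduce the published presence codes", {
  for (s in c("reactor", "sediment")) {
    fx <- if (s == "reactor") demo_reactor_sample() else demo_sediment_sample()
    report <- run_demo(s)
    expect_identical(report$table$presence, fx$expected$presence)
    expect_identical(report$table$ab_type, fx$expected$ab_type)
    # fixture construction: report recovers the generating F'
    expect_equal(report$table$F_prime, unname(fx$F_prime),
                 tolerance = 1e-8)
  }
})

test_that("reports serialize to TSV and JSON", {
  report <- run_demo("reactor")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_report(report, tp)
  tab <- utils::read.delim(tp)
  expect_equal(nrow(tab), 16)
  expect_true(all(c("antibody", "F", "F_prime", "ab_type", "presence_code",
                    "top_explainer", "residual") %in% names(tab)))
  jp <- withr::local_tempfile(fileext = ".json")
  write_report_json(report, jp)
  payload <- jsonlite::read_json(jp)
  expect_equal(length(payload$table), 16)  # one record per antibody
  expect_named(payload$thresholds,
               c("background", "multiplier", "dec_fraction",
                 "consistency_tolerance", "theta_pos", "theta_dec"),
               ignore.order = TRUE)
})

test_that("noise-free synthetic samples recover presence exactly, off-chip relatives give II.b", {
  uni <- make_reference_universe()
  mat <- reference_matrix()
  quiet <- noise_model(replicate_cv = 0)
  run_sample <- function(conc, seed) {
    spots <- simulate_assay(uni, sample_spec(conc), noise = quiet,
                            seed = seed)
    ctrl <- simulate_assay(uni, sample_spec(), noise = quiet,
                           seed = seed + 100)
    profile <- summarize_replicates(spots)
    B <- profile$background
    net <- subtract_control(profile, summarize_replicates(ctrl),
                            "buffer_only")
    classify(mat, profile_f(net), B)
  }
  S <- c("L2C1", "L6C1", "L9C1")  # includes the densely linked L6C1
  report <- run_sample(
    stats::setNames(rep(1e4 * max(uni$K), length(S)), paste0("AG_", S)), 1)
  called <- report$table$antibody[report$table$presence == "III"]
  expect_setequal(called, S)
  # cross-lit spots are explained away as II.a, never III
  lit_absent <- with(report$table, antibody[presence == "II.a"])
  expect_true(all(c("L6S2", "L3C1", "L5C1") %in% lit_absent))

  # off-chip relative binds L6C1 but not its EPS partner: II.b
  rep_rel <- run_sample(c(REL_L6 = 1e4 * max(uni$K)), 11)
  tab <- rep_rel$table
  expect_equal(tab$presence[tab$antibody == "L6C1"], "II.b")
  expect_true(all(tab$presence[tab$antibody != "L6C1"] == "I"))
})
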