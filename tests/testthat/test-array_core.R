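test_that("replicate summarization takes the median and flags high CV", {
  spots <- toy_spot_table(list(ab1 = c(100, 100, 100),
                               ab2 = c(90, 100, 200),
                               ab3 = c(10, 500, 520)))
  profile <- summarize_replicates(spots)
  f <- profile_f(profile)
  expect_equal(unname(f["ab1"]), 100)
  expect_equal(profile$antibodies$cv[profile$antibodies$antibody == "ab1"], 0)
  # median by direct sort: sort(90, 100, 200)[2] = 100; its CV (~0.47)
  # exceeds the 0.25 limit and is flagged
  expect_equal(unname(f["ab2"]), 100)
  expect_true(profile$antibodies$high_cv[profile$antibodies$antibody == "ab2"])
  expect_true(profile$antibodies$high_cv[profile$antibodies$antibody == "ab3"])
})

test_that("summarization is permutation-invariant and enforces the layout", {
  set.seed(11)
  for (i in 1:20) {
    reps <- runif(3, 0, 1000)
    a <- summarize_replicates(toy_spot_table(list(x = reps)))
    b <- summarize_replicates(toy_spot_table(list(x = sample(reps))))
    expect_equal(profile_f(a), profile_f(b))
  }
  incomplete <- toy_spot_table(list(ab1 = c(100, 110)))
  expect_error(summarize_replicates(incomplete), "ab1")
  expect_error(summarize_replicates(incomplete), "f1")
})

test_that("background is the pooled median over all blank roles", {
  spots <- toy_spot_table(list(ab1 = c(300, 300, 300)),
                          blanks = c(50, 50, 50))
  expect_equal(summarize_replicates(spots)$background, 50)
  # three blank groups with medians 40 / 50 / 60 pool to 50
  extra <- rbind(
    as.data.frame(toy_spot_table(list(ab1 = c(300, 300, 300)),
                                 blanks = c(40, 40, 40))),
    data.frame(field_id = "f1", target = "PPB", role = "blank_buffer",
               replicate = 1:3, intensity = c(50, 50, 50)),
    data.frame(field_id = "f1", target = "PI", role = "preimmune",
               replicate = 1:3, intensity = c(60, 60, 60)))
  profile <- summarize_replicates(spot_table(extra))
  expect_equal(profile$background, 50)
  expect_equal(unname(profile$preimmune["PI"]), 60)
  no_controls <- spot_table(data.frame(
    field_id = "f1", target = "ab1", role = "antibody", replicate = 1:3,
    intensity = c(1, 2, 3)))
  expect_error(estimate_background(summarize_replicates(no_controls)),
               "control")
})

test_that("control subtraction clips at zero, is monotone, records provenance", {
  sample <- toy_profile(c(ab1 = 500, ab2 = 100))
  ctrl <- toy_profile(c(ab1 = 200, ab2 = 150))
  out <- subtract_control(sample, ctrl, "heat_treated")
  expect_equal(unname(profile_f(out)), c(300, 0))
  expect_identical(out$control_provenance, "heat_treated")
  # monotone: a larger control never increases the output
  bigger <- toy_profile(c(ab1 = 350, ab2 = 150))
  out2 <- subtract_control(sample, bigger)
  expect_true(all(profile_f(out2) <= profile_f(out)))
  mismatched <- toy_profile(c(ab1 = 1, other = 2))
  expect_error(subtract_control(sample, mismatched), "panel")
})

test_that("positivity is strict at multiplier x background and monotone", {
  expect_true(positivity_call(260, 100))
  expect_false(positivity_call(250, 100))  # boundary is negative
  expect_false(positivity_call(100, 150))
  expect_error(positivity_call(100, 0), "positive")
  expect_error(positivity_call(100, -5), "positive")
  # monotone in F, anti-monotone in B
  f_grid <- seq(0, 1000, by = 50)
  calls <- positivity_call(f_grid, 100)
  expect_true(all(diff(as.integer(calls)) >= 0))
  b_grid <- seq(10, 500, by = 10)
  calls_b <- vapply(b_grid, function(b) positivity_call(600, b), logical(1))
  expect_true(all(diff(as.integer(calls_b)) <= 0))
})

test_that("tsv spot tables round-trip and report malformed lines", {
  uni <- make_reference_universe()
  spots <- simulate_assay(uni, sample_spec(c(AG_L1C1 = 1e6)), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spot_table(spots, path)
  back <- read_spot_table(path)
  expect_equal(as.data.frame(back), as.data.frame(spots), tolerance = 1e-12)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("field_id\ttarget\trole\treplicate\tintensity", empty)
  expect_equal(nrow(read_spot_table(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("field_id\ttarget\trole\treplicate\tintensity",
               "f1\tab1\tantibody\t1\t100",
               "f1\tab1\tantibody\t2\tnot_a_number"), bad)
  expect_error(read_spot_table(bad), "line 3")
})

test_that("genepix-like dialect parses the packaged fixture", {
  path <- system.file("extdata", "example_genepix.gpr", package = "fsmi")
  spots <- read_spot_table(path, dialect = "genepix_like")
  expect_s3_class(spots, "spot_table")
  expect_equal(nrow(spots), 18)
  expect_setequal(unique(spots$role),
                  c("antibody", "preimmune", "blank_bsa", "blank_buffer",
                    "fluorescent_frame"))
  profile <- summarize_replicates(spots)
  expect_equal(unname(profile_f(profile)["L1C1"]), 1505)
  expect_equal(unname(profile_f(profile)["L6C1"]), 205)
  expect_equal(profile$background, 97)
  expect_true(positivity_call(profile_f(profile)["L1C1"], profile$background))
  expect_false(positivity_call(profile_f(profile)["L6C1"], profile$background))
})

test_that("profiles round-trip through TSV", {
  spots <- toy_spot_table(list(ab1 = c(100, 120, 110), ab2 = c(5, 6, 7)))
  profile <- summarize_replicates(spots)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(profile, path)
  back <- read_profile(path)
  expect_equal(profile_f(back), profile_f(profile))
  expect_equal(back$background, profile$background)
})

test_that("default panel and layout match the published chip design", {
  panel <- default_panel()
  expect_equal(nrow(panel), 24)
  expect_equal(sum(panel$immunogen_kind != "protein"), 20)
  expect_equal(sum(panel$immunogen_kind == "protein"), 4)
  expect_equal(sum(panel$excluded), 8)
  # every non-protein antibody has a pre-immune partner
  expect_true(all(!is.na(panel$preimmune_code[panel$immunogen_kind != "protein"])))
  expect_equal(n_fields(default_layout()), 24)
  expect_equal(default_layout()$replicate_spots_per_antibody, 3)
  expect_error(slide_layout(replicate_spots_per_antibody = 1), ">= 2")
  expect_error(antibody_panel(data.frame(
    code = c("a", "a"), immunogen_kind = "protein",
    immunogen_name = "x", preimmune_code = NA)), "unique")
})
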