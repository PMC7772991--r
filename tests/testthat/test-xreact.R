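test_that("matrix columns are cognate-normalized, gated, and unit-diagonal", {
  codes <- c("j", "i", "k")
  # assay of immunogen j: cognate 2100, spot i 600, spot k below threshold
  assays <- list(
    j = toy_profile(c(j = 2100, i = 600, k = 240)),
    i = toy_profile(c(j = 150, i = 1800, k = 120)),
    k = toy_profile(c(j = 90, i = 110, k = 900)))
  mat <- build_matrix(assays)
  expect_equal(mat$G["i", "j"], 500 / 2000)   # (600-100)/(2100-100)
  expect_equal(mat$G["k", "j"], 0)            # 240 <= 2.5 x 100: gated to 0
  expect_equal(unname(diag(mat$G)), rep(1, 3))
  # columns i and k have only the cognate bright: unit columns
  expect_equal(unname(mat$G[, "i"]), c(0, 1, 0))
  expect_equal(unname(mat$G[, "k"]), c(0, 0, 1))
})

test_that("matrix is invariant under scaling a panel assay's fluorescences", {
  assays <- list(
    a = toy_profile(c(a = 3000, b = 800)),
    b = toy_profile(c(a = 400, b = 2500)))
  ref <- build_matrix(assays)
  # scale assay a by 3: both F and background scale together
  scaled <- assays
  scaled$a <- toy_profile(c(a = 9000, b = 2400), background = 300)
  expect_equal(build_matrix(scaled)$G, ref$G)
})

test_that("failing cognates are reported for pruning, not silently kept", {
  assays <- list(
    good = toy_profile(c(good = 2000, weak = 600)),
    weak = toy_profile(c(good = 50, weak = 200)))  # self-signal 2x background
  expect_error(build_matrix(assays), "weak")
  retained <- prune_antibodies(assays)
  expect_identical(retained, "good")
  mat <- build_matrix(assays[retained])
  expect_identical(mat$antibody_order, "good")
})

test_that("metadata-driven pruning removes the flagged poor performers", {
  panel <- default_panel()
  f_bright <- stats::setNames(rep(3000, 24), panel$code)
  assays <- lapply(panel$code, function(code) toy_profile(f_bright))
  names(assays) <- panel$code
  # self-signal failures for the four EPS antibodies with no self-signal
  for (code in c("L2S2", "L3S2", "L4S2", "L8S2")) {
    f <- f_bright; f[code] <- 120
    assays[[code]] <- toy_profile(f)
  }
  retained <- prune_antibodies(assays, panel)
  expect_equal(length(retained), 16)
  expect_setequal(retained, reference_antibodies())
  # no failures and no metadata -> identity pruning
  ok <- list(x = toy_profile(c(x = 1000, y = 500)),
             y = toy_profile(c(x = 200, y = 1000)))
  expect_identical(prune_antibodies(ok), c("x", "y"))
})

test_that("graph construction matches the off-diagonal support exactly", {
  # identity matrix: no links, all nodes type B
  eye <- xreact_matrix(diag(4), letters[1:4])
  g0 <- build_graph(eye)
  expect_equal(g0$l, 0)
  expect_true(all(g0$nodes$type == "B"))

  # single entry G[1,2] = 0.5: one link 2 -> 1, node 2 type A
  G <- diag(2); G[1, 2] <- 0.5
  g1 <- build_graph(xreact_matrix(G, c("n1", "n2")))
  expect_equal(g1$l, 1)
  expect_equal(g1$edges$src, "n2")
  expect_equal(g1$edges$dst, "n1")
  expect_equal(g1$edges$weight, 0.5)
  expect_equal(g1$nodes$type, c("B", "A"))

  # property: link count equals positive off-diagonal count (exhaustive)
  set.seed(5)
  for (i in 1:20) {
    G <- random_xreact(n = 8, n_links = sample(4:20, 1))
    g <- build_graph(xreact_matrix(G))
    manual <- 0
    for (r in 1:8) for (cc in 1:8) {
      if (r != cc && G[r, cc] > 0) manual <- manual + 1
    }
    expect_equal(g$l, manual)
    for (k in seq_len(nrow(g$nodes))) {
      expect_equal(g$nodes$type[k] == "A", g$nodes$out_degree[k] > 0)
    }
  }
})

test_that("pruning then building equals building then deleting rows/columns", {
  assays <- list(
    a = toy_profile(c(a = 3000, b = 800, c = 600)),
    b = toy_profile(c(a = 400, b = 2500, c = 300)),
    c = toy_profile(c(a = 150, b = 260, c = 1500)))
  full <- build_matrix(assays)
  keep <- c("a", "c")
  pruned_first <- build_matrix(assays[keep])
  deleted_after <- xreact_matrix(full$G[keep, keep], keep)
  expect_equal(pruned_first$G, deleted_after$G)
})

test_that("matrix and graph serialize to TSV, edge list and GraphML", {
  mat <- reference_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(mat, path)
  back <- read_matrix(path)
  expect_equal(back$G, mat$G)
  expect_identical(back$antibody_order, mat$antibody_order)

  graph <- build_graph(mat)
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(graph, ep)
  edges <- utils::read.delim(ep)
  expect_equal(nrow(edges), 28)

  gp <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(graph, gp)
  g2 <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::ecount(g2), 28)
  expect_equal(igraph::vcount(g2), 16)
})

test_that("zero-noise simulated panel recovers the universe's matrix", {
  uni <- make_reference_universe()
  panel <- simulate_crossreactivity_panel(uni, seed = 1)
  profiles <- lapply(panel, summarize_replicates)
  mat <- build_matrix(profiles)
  truth <- implied_matrix(uni)
  expect_identical(mat$antibody_order, truth$antibody_order)
  expect_lt(max(abs(mat$G - truth$G)), 1e-6)
  # with equal Fmax the implied matrix is the reference topology itself
  expect_equal(truth$G, reference_matrix()$G)
  # a single off-diagonal affinity propagates through the whole pipeline
  antigens <- data.frame(antigen_id = c("agA", "agB"),
                         on_chip_cognate = c("abA", "abB"),
                         stringsAsFactors = FALSE)
  R <- matrix(c(1, 0, 0.25, 1), 2, 2,
              dimnames = list(c("abA", "abB"), c("agA", "agB")))
  small <- antigen_universe(antigens, R,
                            Fmax = c(abA = 5000, abB = 5000), K = 1e4)
  small_panel <- simulate_crossreactivity_panel(small, seed = 2)
  small_mat <- build_matrix(lapply(small_panel, summarize_replicates))
  expect_equal(small_mat$G["abA", "abB"], 0.25, tolerance = 1e-6)
})
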