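# Independent oracles and fixture builders shared across the test files.

# Plain Gaussian elimination with partial pivoting; deliberately written
# from scratch (no solve()/qr()) so it is an independent check on the
# package's deconvolution solver.
gaussian_elimination <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n - 1)) {
    p <- which.max(abs(M[k:n, k])) + k - 1
    if (p != k) M[c(k, p), ] <- M[c(p, k), ]
    for (r in (k + 1):n) {
      factor <- M[r, k] / M[k, k]
      M[r, ] <- M[r, ] - factor * M[k, ]
    }
  }
  x <- numeric(n)
  for (r in n:1) {
    x[r] <- (M[r, n + 1] -
               if (r < n) sum(M[r, (r + 1):n] * x[(r + 1):n]) else 0) / M[r, r]
  }
  x
}

# Random unit-diagonal cross-reactivity matrix with roughly n_links
# off-diagonal entries, resampled until well-conditioned.
random_xreact <- function(n = 16, n_links = 28, cond_max = 1e6) {
  repeat {
    G <- diag(n)
    off <- which(row(G) != col(G))
    picked <- sample(off, n_links)
    G[picked] <- runif(n_links, 0.05, 0.9)
    if (kappa(G, exact = TRUE) < cond_max) break
  }
  rownames(G) <- colnames(G) <- sprintf("ab%02d", seq_len(n))
  G
}

# Small spot table for one field: given named per-antibody triplets and
# blank intensities.
toy_spot_table <- function(ab_reps, blanks = c(50, 50, 50),
                           field = "f1") {
  rows <- do.call(rbind, lapply(names(ab_reps), function(code) {
    data.frame(field_id = field, target = code, role = "antibody",
               replicate = seq_along(ab_reps[[code]]),
               intensity = ab_reps[[code]], stringsAsFactors = FALSE)
  }))
  blank_rows <- data.frame(field_id = field, target = "BSA",
                           role = "blank_bsa",
                           replicate = seq_along(blanks),
                           intensity = blanks, stringsAsFactors = FALSE)
  spot_table(rbind(rows, blank_rows))
}

# An assay_profile built directly from a named F vector (bypassing spot
# tables) for matrix-construction tests.
toy_profile <- function(F, background = 100) {
  structure(
    list(antibodies = data.frame(antibody = names(F), F = unname(F),
                                 cv = 0, n = 3L, high_cv = FALSE,
                                 saturated = FALSE, stringsAsFactors = FALSE),
         controls = data.frame(target = "BSA", role = "blank_bsa",
                               F = background, cv = 0, n = 3L,
                               saturated = FALSE, stringsAsFactors = FALSE),
         background = background,
         preimmune = stats::setNames(numeric(), character()),
         field_id = "toy", control_provenance = character()),
    class = "assay_profile")
}

# The full presence-code decision table: every combination of the four
# binary facts and the code the tree must assign.
decision_table <- function() {
  grid <- expand.grid(f_above = c(FALSE, TRUE), fp_above = c(FALSE, TRUE),
                      ab_type = c("A", "B"),
                      consistency_ok = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  grid$expected <- with(grid, ifelse(
    !f_above, "I",
    ifelse(!fp_above, "II.a",
           ifelse(ab_type == "B", "III",
                  ifelse(consistency_ok, "III", "II.b")))))
  grid
}
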