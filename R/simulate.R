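#' Antigen universe for simulation
#'
#' The stated world of the simulator: a set of antigens (each optionally
#' the cognate of an on-chip antibody), a relative-affinity matrix R
#' (antibody x antigen, entries in \[0, 1\], exactly 1 for cognate pairs),
#' and Langmuir binding parameters: a saturation fluorescence `Fmax` per
#' antibody and a half-saturation constant `K` per antibody-antigen pair.
#' Off-chip antigens (no cognate on the chip) model "nearby" organisms or
#' molecules not represented in the graph — the situations that elicit
#' presence code II.b downstream.
#'
#' @param antigens data frame with columns `antigen_id` and
#'   `on_chip_cognate` (antibody code or `NA`).
#' @param R antibody x antigen matrix of relative affinities.
#' @param Fmax named numeric, saturation fluorescence per antibody (a.u.).
#' @param K half-saturation constant(s): scalar, or antibody x antigen
#'   matrix (units of the sample concentration).
#' @return an object of class `antigen_universe`.
#' @export
antigen_universe <- function(antigens, R, Fmax, K = 1e4) {
  stopifnot(is.data.frame(antigens),
            all(c("antigen_id", "on_chip_cognate") %in% names(antigens)),
            is.matrix(R))
  if (!identical(colnames(R), antigens$antigen_id)) {
    stop("columns of R must match antigens$antigen_id")
  }
  if (any(R < 0 | R > 1)) stop("relative affinities must lie in [0, 1]")
  abs_codes <- rownames(R)
  if (is.null(abs_codes)) stop("R must have antibody codes as rownames")
  if (!all(names(Fmax) == abs_codes)) stop("Fmax must be named by antibody")
  cog <- antigens$on_chip_cognate
  for (a in which(!is.na(cog))) {
    col <- R[, a]
    if (!isTRUE(all.equal(unname(col[cog[a]]), 1))) {
      stop("cognate pair (", cog[a], ", ", antigens$antigen_id[a],
           ") must have unit affinity")
    }
    if (sum(col == 1) != 1) {
      stop("on-chip cognate column ", antigens$antigen_id[a],
           " must have exactly one unit entry")
    }
  }
  if (is.matrix(K)) {
    stopifnot(identical(dim(K), dim(R)))
  } else {
    K <- matrix(K, nrow(R), ncol(R), dimnames = dimnames(R))
  }
  structure(list(antigens = antigens, R = R, Fmax = Fmax, K = K,
                 antibodies = abs_codes),
            class = "antigen_universe")
}

#' Spot-level noise model
#'
#' Fluorescence scanners show multiplicative, roughly lognormal spot
#' noise; each noise draw is a unit-mean lognormal factor whose sigma is
#' derived from the replicate coefficient of variation. The
#' mineral-binding level is an additive term that survives heat treatment
#' (mineral particles sticking to antibody spots), while the biological
#' binding term is ablated by it.
#'
#' @param background_mean mean background fluorescence (a.u., default 100).
#' @param replicate_cv spot-level CV of the multiplicative noise
#'   (default 0.1; 0 gives deterministic output).
#' @param mineral_binding_level additive heat-surviving signal on antibody
#'   spots (a.u., default 0).
#' @return an object of class `noise_model` (also carries
#'   `lognormal_sigma`, the derived meanlog/sdlog parameterisation).
#' @export
noise_model <- function(background_mean = 100, replicate_cv = 0.1,
                        mineral_binding_level = 0) {
  stopifnot(background_mean >= 0, replicate_cv >= 0,
            mineral_binding_level >= 0)
  structure(list(background_mean = background_mean,
                 replicate_cv = replicate_cv,
                 lognormal_sigma = sqrt(log(1 + replicate_cv^2)),
                 mineral_binding_level = mineral_binding_level),
            class = "noise_model")
}

#' Sample specification
#'
#' @param concentrations named numeric vector, antigen_id -> concentration
#'   (cells/mL or a.u.); non-negative. Antigens absent from the vector are
#'   at concentration 0.
#' @param heat_treated was the sample baked (500 degrees C, 3 h) to destroy
#'   organics? Heat treatment zeroes the biological binding term.
#' @return an object of class `sample_spec`.
#' @export
sample_spec <- function(concentrations = numeric(), heat_treated = FALSE) {
  if (length(concentrations) > 0 &&
      (is.null(names(concentrations)) || any(!nzchar(names(concentrations))))) {
    stop("concentrations must be named by antigen_id")
  }
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  structure(list(concentrations = concentrations,
                 heat_treated = isTRUE(heat_treated)),
            class = "sample_spec")
}

# unit-mean lognormal noise factors; exactly 1 at zero CV
lognormal_factors <- function(n, sigma) {
  if (sigma == 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate one microarray field
#'
#' Generates the spot table of a single assay field for a given sample.
#' Each replicate spot of antibody i draws
#' `background * e0 + mineral * e1 + bio_i * e2`, with independent
#' unit-mean lognormal factors `e`, where the biological term is the
#' saturating Langmuir superposition over all antigens,
#' `bio_i = sum_a R[i, a] * Fmax_i * c_a / (c_a + K[i, a])`,
#' and is exactly 0 for heat-treated samples. Blank (BSA / printing
#' buffer) and pre-immune control spots carry background only; the
#' fluorescent frame is a bright constant used for grid localization.
#' Output is deterministic given `seed`.
#'
#' @param universe an [antigen_universe()].
#' @param sample a [sample_spec()].
#' @param layout a [slide_layout()] (sets the replicate count and control
#'   roles).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param field_id field identifier stamped on the rows.
#' @return a [spot_table()].
#' @export
simulate_assay <- function(universe, sample, layout = default_layout(),
                           noise = noise_model(), seed = 1,
                           field_id = "f1") {
  stopifnot(inherits(universe, "antigen_universe"),
            inherits(sample, "sample_spec"),
            inherits(layout, "slide_layout"),
            inherits(noise, "noise_model"))
  conc <- stats::setNames(rep(0, nrow(universe$antigens)),
                          universe$antigens$antigen_id)
  given <- sample$concentrations
  unknown <- setdiff(names(given), names(conc))
  if (length(unknown) > 0) {
    stop("unknown antigen(s) in sample: ", paste(unknown, collapse = ", "))
  }
  conc[names(given)] <- given
  set.seed(as.integer(seed) %% .Machine$integer.max)

  abs_codes <- universe$antibodies
  nrep <- layout$replicate_spots_per_antibody
  sigma <- noise$lognormal_sigma

  # saturating binding term per antibody (0 after heat treatment)
  occupancy <- sweep(universe$K, 2, conc,
                     function(k, c) ifelse(c > 0, c / (c + k), 0))
  bio <- if (sample$heat_treated) {
    rep(0, length(abs_codes))
  } else {
    as.numeric((universe$R * occupancy) %*% rep(1, ncol(universe$R))) *
      universe$Fmax[abs_codes]
  }

  n_ab <- length(abs_codes) * nrep
  ab_rows <- data.frame(
    field_id = field_id,
    target = rep(abs_codes, each = nrep),
    role = "antibody",
    replicate = rep(seq_len(nrep), times = length(abs_codes)),
    intensity = noise$background_mean * lognormal_factors(n_ab, sigma) +
      noise$mineral_binding_level * lognormal_factors(n_ab, sigma) +
      rep(bio, each = nrep) * lognormal_factors(n_ab, sigma),
    stringsAsFactors = FALSE)

  control_rows <- list()
  roles <- layout$control_spot_roles
  make_blanks <- function(target, role) {
    data.frame(field_id = field_id, target = target, role = role,
               replicate = seq_len(nrep),
               intensity = noise$background_mean *
                 lognormal_factors(nrep, sigma),
               stringsAsFactors = FALSE)
  }
  if ("blank_bsa" %in% roles) control_rows$bsa <- make_blanks("BSA", "blank_bsa")
  if ("blank_buffer" %in% roles) {
    control_rows$ppb <- make_blanks("PPB", "blank_buffer")
  }
  if ("preimmune" %in% roles) {
    control_rows$pi <- make_blanks("PI", "preimmune")
  }
  if ("fluorescent_frame" %in% roles) {
    control_rows$frame <- data.frame(
      field_id = field_id, target = "FRAME", role = "fluorescent_frame",
      replicate = seq_len(nrep),
      intensity = 30000 * lognormal_factors(nrep, sigma),
      stringsAsFactors = FALSE)
  }
  spot_table(do.call(rbind, c(list(ab_rows), unname(control_rows))))
}

#' Simulate a one-immunogen-at-a-time cross-reactivity panel
#'
#' One assay per on-chip cognate antigen at a saturating concentration
#' (`sat_factor` times the largest K of that antigen's column), emulating
#' the panel experiment that feeds [build_matrix()]. With zero noise the
#' downstream matrix reproduces the universe's implied cross-reactivity
#' matrix (see [implied_matrix()]) to numerical precision.
#'
#' @inheritParams simulate_assay
#' @param sat_factor multiple of K used as the saturating concentration
#'   (default 1e8, leaving the Langmuir term within 1e-8 of saturation).
#' @return named list, antibody code -> [spot_table()].
#' @export
simulate_crossreactivity_panel <- function(universe,
                                           layout = default_layout(),
                                           noise = noise_model(replicate_cv = 0),
                                           seed = 1, sat_factor = 1e8) {
  stopifnot(inherits(universe, "antigen_universe"))
  cog <- universe$antigens$on_chip_cognate
  on_chip <- which(!is.na(cog))
  out <- list()
  for (idx in seq_along(on_chip)) {
    a <- on_chip[idx]
    conc <- stats::setNames(sat_factor * max(universe$K[, a]),
                            universe$antigens$antigen_id[a])
    out[[cog[a]]] <- simulate_assay(
      universe, sample_spec(conc), layout, noise,
      seed = seed + idx, field_id = paste0("panel_", cog[a]))
  }
  out
}

#' The cross-reactivity matrix a universe implies on the chip
#'
#' For the single-immunogen panel at saturation and zero noise, the
#' estimated entry for spot i in the assay of immunogen j is
#' `R[i, a_j] * Fmax_i / Fmax_j` (where `a_j` is antibody j's cognate
#' antigen), gated by the positivity rule exactly as [build_matrix()]
#' gates it. This is the independent ground truth the recovery tests
#' compare against. With equal `Fmax` across antibodies it reduces to R
#' restricted to on-chip cognate columns.
#'
#' @param universe an [antigen_universe()].
#' @param background background the panel assays will see (a.u.).
#' @param multiplier positivity multiplier.
#' @param weak_link_floor floor below which entries are zeroed.
#' @return an [xreact_matrix()].
#' @export
implied_matrix <- function(universe, background = 100, multiplier = 2.5,
                           weak_link_floor = 0.01) {
  cog <- universe$antigens$on_chip_cognate
  on_chip <- which(!is.na(cog))
  codes <- cog[on_chip]
  fmax <- universe$Fmax[codes]
  n <- length(codes)
  G <- matrix(0, n, n, dimnames = list(codes, codes))
  for (j in seq_len(n)) {
    r <- universe$R[codes, on_chip[j]]
    signal <- r * fmax              # background-subtracted signal at saturation
    pos <- (background + signal) > multiplier * background
    col <- ifelse(pos, signal / signal[j], 0)
    G[, j] <- col
    G[j, j] <- 1
  }
  off <- G > 0 & G < weak_link_floor
  diag(off) <- FALSE
  G[off] <- 0
  xreact_matrix(G, codes)
}

#' Simulate a serial-dilution calibration series
#'
#' Runs [simulate_assay()] at each tested decade of the antibody's cognate
#' antigen, quantifies the cognate spot and the field background, and
#' returns the resulting [dilution_series()]. The noise-free positivity
#' crossing of the underlying curve is available in closed form via
#' [analytic_lod()].
#'
#' @inheritParams simulate_assay
#' @param antibody antibody code whose cognate antigen is titrated.
#' @param decades tested concentrations, strictly increasing
#'   (default `10^(2:6)`).
#' @param tracer_mode stamped on the series (`"single"` or
#'   `"top_prb_mix"`; the simulated chemistry is identical).
#' @return a [dilution_series()].
#' @export
simulate_dilution_series <- function(universe, antibody,
                                     decades = 10^(2:6),
                                     layout = default_layout(),
                                     noise = noise_model(), seed = 1,
                                     tracer_mode = "single") {
  stopifnot(inherits(universe, "antigen_universe"))
  a <- cognate_antigen(universe, antibody)
  f <- b <- numeric(length(decades))
  for (i in seq_along(decades)) {
    spots <- simulate_assay(
      universe, sample_spec(stats::setNames(decades[i], a)), layout, noise,
      seed = seed + i, field_id = paste0("dil_", i))
    profile <- summarize_replicates(spots, layout)
    f[i] <- profile_f(profile)[[antibody]]
    b[i] <- profile$background
  }
  dilution_series(antibody, decades, f, b, tracer_mode)
}

cognate_antigen <- function(universe, antibody) {
  hit <- which(universe$antigens$on_chip_cognate == antibody)
  if (length(hit) != 1) {
    stop("antibody ", antibody, " has no unique cognate antigen in the universe")
  }
  universe$antigens$antigen_id[hit]
}

#' Closed-form noise-free LOD of a simulated dilution series
#'
#' The raw cognate signal at concentration c is
#' `background + Fmax * c / (c + K)`; it passes positivity when
#' `Fmax * c / (c + K) > (multiplier - 1) * background`. The analytic LOD
#' is the lowest tested decade at or above the exact crossing
#' `c* = (multiplier - 1) * background * K / (Fmax - (multiplier - 1) * background)`
#' (`NA` when even saturation stays below threshold or no tested decade
#' reaches the crossing).
#'
#' @inheritParams simulate_dilution_series
#' @param background background level the assay will see (a.u.).
#' @param multiplier positivity multiplier.
#' @return list with `crossing` (exact concentration) and
#'   `lod_concentration` (first tested decade past it, `NA` if none).
#' @export
analytic_lod <- function(universe, antibody, decades = 10^(2:6),
                         background = 100, multiplier = 2.5) {
  a <- cognate_antigen(universe, antibody)
  ai <- match(a, universe$antigens$antigen_id)
  fmax <- universe$Fmax[[antibody]]
  k <- universe$K[antibody, ai]
  need <- (multiplier - 1) * background
  if (fmax <= need) {
    return(list(crossing = Inf, lod_concentration = NA_real_))
  }
  crossing <- need * k / (fmax - need)
  pass <- decades > crossing
  list(crossing = crossing,
       lod_concentration = if (any(pass)) decades[which(pass)[1]] else NA_real_)
}

#' The packaged 16-antibody reference topology
#'
#' A reconstruction of the published antibody graph scale — 16 nodes and
#' 28 directed links — constrained by every cross-reaction named in the
#' source study's results: the L1C1/L1S2/L8C1 (anti-*Azospira*) triangle,
#' the lysate/EPS partner links for the *Dechloromonas* and *Arcobacter*
#' antibodies, the L5C1 -> L6C1 and L5C1 -> L12C1 within-order
#' cross-reactions, the weak L9C1 -> L3C1 reaction, and the five strictly
#' self-reactive (type B) antibodies L2C1, L3C1, L4C1, L7C1 and L10C1.
#' The remaining weak within-family links and all numeric weights are
#' synthetic: the published figure reports the topology graphically, not
#' as numbers.
#'
#' @return data frame with columns `src`, `dst`, `weight` (28 rows).
#' @export
reference_topology <- function() {
  edges <- rbind(
    c("L1C1",  "L1S2",  0.80),
    c("L1C1",  "L8C1",  0.60),
    c("L1S2",  "L1C1",  0.70),
    c("L1S2",  "L8C1",  0.50),
    c("L8C1",  "L1C1",  0.50),
    c("L8C1",  "L1S2",  0.50),
    c("L8C1",  "L6C1",  0.10),
    c("L6C1",  "L6S2",  0.80),
    c("L6C1",  "L5C1",  0.15),
    c("L6C1",  "L11C1", 0.20),
    c("L6C1",  "L12S2", 0.30),
    c("L6C1",  "L12C1", 0.10),
    c("L6S2",  "L6C1",  0.90),
    c("L6S2",  "L11S2", 0.10),
    c("L6S2",  "L11C1", 0.10),
    c("L11C1", "L11S2", 0.70),
    c("L11C1", "L6C1",  0.20),
    c("L11C1", "L6S2",  0.10),
    c("L11S2", "L11C1", 0.60),
    c("L12C1", "L12S2", 0.90),
    c("L12C1", "L5C1",  0.20),
    c("L12S2", "L12C1", 0.80),
    c("L12S2", "L5C1",  0.10),
    c("L5C1",  "L6C1",  0.30),
    c("L5C1",  "L12C1", 0.20),
    c("L5C1",  "L6S2",  0.10),
    c("L9C1",  "L3C1",  0.15),
    c("L9C1",  "L10C1", 0.10))
  data.frame(src = edges[, 1], dst = edges[, 2],
             weight = as.numeric(edges[, 3]), stringsAsFactors = FALSE)
}

#' @rdname reference_topology
#' @return `reference_antibodies()`: the 16 retained antibody codes, in
#'   canonical chip order.
#' @export
reference_antibodies <- function() {
  c("L1C1", "L2C1", "L3C1", "L4C1", "L5C1", "L6C1", "L7C1", "L8C1",
    "L9C1", "L10C1", "L11C1", "L12C1", "L1S2", "L6S2", "L11S2", "L12S2")
}

#' @rdname reference_topology
#' @return `reference_matrix()`: the corresponding [xreact_matrix()]
#'   (unit diagonal plus the 28 weighted links).
#' @export
reference_matrix <- function() {
  codes <- reference_antibodies()
  G <- diag(length(codes))
  dimnames(G) <- list(codes, codes)
  edges <- reference_topology()
  for (e in seq_len(nrow(edges))) {
    G[edges$dst[e], edges$src[e]] <- edges$weight[e]
  }
  xreact_matrix(G, codes)
}

#' Reference antigen universe
#'
#' An [antigen_universe()] whose on-chip part realizes
#' [reference_matrix()] exactly (equal `Fmax` across antibodies, so the
#' implied chip matrix equals R restricted to cognate columns), plus two
#' off-chip "relative" antigens: each binds one lysate antibody strongly
#' (REL_L6 -> L6C1, REL_L12 -> L12C1) while leaving that antibody's
#' expected cross-reaction partners dark — the signature that the
#' deconvolution classifies as II.b. Half-saturation constants are spread
#' over decades to emulate the published spread of detection limits.
#'
#' @param Fmax saturation fluorescence shared by all antibodies
#'   (default 5000 a.u., 50x the default background).
#' @return an [antigen_universe()] with 16 antibodies and 18 antigens.
#' @export
make_reference_universe <- function(Fmax = 5000) {
  codes <- reference_antibodies()
  mat <- reference_matrix()
  antigens <- data.frame(
    antigen_id = c(paste0("AG_", codes), "REL_L6", "REL_L12"),
    on_chip_cognate = c(codes, NA, NA),
    stringsAsFactors = FALSE)
  R <- matrix(0, length(codes), nrow(antigens),
              dimnames = list(codes, antigens$antigen_id))
  R[, seq_along(codes)] <- mat$G
  R["L6C1", "REL_L6"] <- 0.9
  R["L12C1", "REL_L12"] <- 0.85
  fmax <- stats::setNames(rep(Fmax, length(codes)), codes)
  # K spread emulating LODs from ~10^2 to ~10^5 cells/mL
  k_per_ab <- stats::setNames(
    rep(c(1e3, 3e3, 1e4, 3e4), 4)[seq_along(codes)], codes)
  K <- matrix(k_per_ab, length(codes), nrow(antigens),
              dimnames = list(codes, antigens$antigen_id))
  antigen_universe(antigens, R, fmax, K)
}
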