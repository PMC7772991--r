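#' Presence/absence recovery benchmark
#'
#' End-to-end validation of the whole pipeline on synthetic multiplex
#' samples: for each seed, a random subset of the on-chip cognate antigens
#' is spiked at saturation, a field assay and a buffer-only control are
#' simulated with multiplicative spot noise, the profiles are quantified,
#' the control subtracted (as in the published protocol), and the
#' deconvolution classification compared with the ground truth. A call is
#' correct when code III coincides with the cognate antigen being present
#' and any of I/II.a/II.b with it being absent.
#'
#' The signal level is stated relative to background: cognate spots reach
#' `signal_over_background` times the background mean at saturation. The
#' "deconvoluted zero" threshold is an absolute fluorescence cut, so
#' recovery is assessed at the stated signal level; much larger dynamic
#' ranges inflate the noise on deconvoluted values relative to that cut
#' (see the methods vignette).
#'
#' @param n_seeds number of simulated samples (default 100).
#' @param signal_over_background saturating cognate signal as a multiple
#'   of the background mean (default 10).
#' @param replicate_cv spot-level CV (default 0.1).
#' @param subset_sizes candidate numbers of present cognates per sample
#'   (default 3:8).
#' @param background_mean background fluorescence (default 100 a.u.).
#' @param config a [pipeline_config()] supplying the classification
#'   thresholds.
#' @return list with `accuracy`, `n_errors`, `n_pairs` and `per_sample`
#'   (data frame `seed`, `n_present`, `n_errors`).
#' @export
recovery_benchmark <- function(n_seeds = 100, signal_over_background = 10,
                               replicate_cv = 0.1, subset_sizes = 3:8,
                               background_mean = 100,
                               config = pipeline_config()) {
  uni <- make_reference_universe(Fmax = signal_over_background *
                                   background_mean)
  mat <- reference_matrix()
  graph <- build_graph(mat)
  nm <- noise_model(background_mean = background_mean,
                    replicate_cv = replicate_cv)
  codes <- reference_antibodies()
  sat <- 1e4 * max(uni$K)
  per_sample <- data.frame(seed = seq_len(n_seeds), n_present = NA_integer_,
                           n_errors = NA_integer_)
  n_errors <- 0L
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    S <- sample(codes, sample(subset_sizes, 1))
    conc <- stats::setNames(rep(sat, length(S)), paste0("AG_", S))
    spots <- simulate_assay(uni, sample_spec(conc), noise = nm,
                            seed = seed + 1000)
    ctrl <- simulate_assay(uni, sample_spec(), noise = nm,
                           seed = seed + 50000)
    profile <- summarize_replicates(spots)
    B <- profile$background
    profile <- subtract_control(profile, summarize_replicates(ctrl),
                                "buffer_only")
    report <- classify(mat, profile_f(profile), B, graph,
                       multiplier = config$multiplier,
                       dec_fraction = config$dec_fraction,
                       consistency_tolerance = config$consistency_tolerance)
    wrong <- sum((report$table$presence == "III") !=
                   (report$table$antibody %in% S))
    per_sample$n_present[seed] <- length(S)
    per_sample$n_errors[seed] <- wrong
    n_errors <- n_errors + wrong
  }
  n_pairs <- n_seeds * length(codes)
  list(accuracy = 1 - n_errors / n_pairs, n_errors = n_errors,
       n_pairs = n_pairs, per_sample = per_sample)
}
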