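#' Serial-dilution series
#'
#' A titration of one immunogen against its antibody: fluorescence readout
#' at strictly increasing concentrations (cells/mL for whole-cell lysates,
#' ug/mL for proteins and EPS fractions), each with its own background
#' estimate, revealed either with the single cognate tracer antibody or
#' with the pooled tracer mix of the whole panel.
#'
#' @param antibody antibody code.
#' @param concentration numeric vector, strictly increasing, length >= 3.
#' @param F cognate-spot fluorescence at each concentration (a.u.).
#' @param background background estimate at each concentration (recycled
#'   if scalar).
#' @param tracer_mode `"single"` or `"top_prb_mix"`.
#' @return an object of class `dilution_series` (a data frame with
#'   attributes `antibody` and `tracer_mode`).
#' @export
dilution_series <- function(antibody, concentration, F, background,
                            tracer_mode = c("single", "top_prb_mix")) {
  tracer_mode <- match.arg(tracer_mode)
  if (length(concentration) < 3) {
    stop("a dilution series needs at least 3 points")
  }
  if (is.unsorted(concentration, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  stopifnot(length(F) == length(concentration))
  background <- rep_len(background, length(concentration))
  df <- data.frame(concentration = concentration, F = F,
                   background = background)
  structure(df, antibody = antibody, tracer_mode = tracer_mode,
            class = c("dilution_series", "data.frame"))
}

#' Estimate the limit of detection from a dilution series
#'
#' The LOD is the lowest tested concentration whose cognate-spot signal
#' passes the positivity rule (`F > multiplier * B`), reported as a strict
#' decade bound (`"<10^k"`) in the style of published LOD tables; when no
#' point passes, the immunogen is `"not detected"` (printed as a dash in
#' those tables).
#'
#' @param series a [dilution_series()].
#' @param multiplier positivity multiplier (default 2.5).
#' @return a `lod_estimate`: list with `antibody`, `lod_concentration`
#'   (the bounding tested concentration, `NA` when not detected),
#'   `lod_bound` (formatted string) and `tracer_mode`.
#' @export
estimate_lod <- function(series, multiplier = 2.5) {
  stopifnot(inherits(series, "dilution_series"))
  if (is.unsorted(series$concentration, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  pass <- mapply(function(f, b) positivity_call(f, b, multiplier),
                 series$F, series$background)
  conc <- if (any(pass)) series$concentration[which(pass)[1]] else NA_real_
  structure(
    list(antibody = attr(series, "antibody"),
         lod_concentration = conc,
         lod_bound = format_lod_bound(conc),
         tracer_mode = attr(series, "tracer_mode")),
    class = "lod_estimate")
}

#' Format a concentration as a decade LOD bound
#'
#' `1e3` becomes `"<10^3"`, `10` becomes `"<10"`, `NA` becomes
#' `"not detected"`; non-decade concentrations are printed literally.
#'
#' @param conc concentration or `NA`.
#' @return character bound.
#' @export
format_lod_bound <- function(conc) {
  if (is.na(conc)) return("not detected")
  k <- log10(conc)
  if (isTRUE(all.equal(k, round(k)))) {
    k <- round(k)
    if (k == 1) "<10" else paste0("<10^", k)
  } else {
    paste0("<", format(conc))
  }
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat(sprintf("LOD[%s, %s tracer]: %s\n", x$antibody, x$tracer_mode,
              x$lod_bound))
  invisible(x)
}

#' Fit a saturating concentration-response curve
#'
#' Least-squares fit of the Langmuir binding model `F(c) = baseline +
#' Fmax * c / (c + K)` to a dilution series (the same generative form the
#' synthetic-data module uses, so fitted and simulated parameters are
#' directly comparable). Fitting is attempted with [stats::nls()] and
#' falls back to Nelder-Mead least squares; a series whose dynamic range
#' is negligible is reported as flat (`Fmax ~ 0`) and flagged rather than
#' fitted.
#'
#' @param series a [dilution_series()] with at least 4 points.
#' @param flat_tol dynamic range (relative to the mean signal) below which
#'   the series counts as flat (default 0.05).
#' @return list with `Fmax`, `K`, `baseline`, `converged`, `flat` and
#'   `rss` (residual sum of squares).
#' @export
fit_response_curve <- function(series, flat_tol = 0.05) {
  stopifnot(inherits(series, "dilution_series"))
  if (nrow(series) < 4) stop("curve fitting needs at least 4 points")
  conc <- series$concentration
  f <- series$F
  rng <- diff(range(f))
  if (rng <= flat_tol * max(mean(f), .Machine$double.eps)) {
    return(list(Fmax = 0, K = NA_real_, baseline = mean(f),
                converged = FALSE, flat = TRUE, rss = sum((f - mean(f))^2)))
  }
  half <- min(f) + rng / 2
  k0 <- conc[which.min(abs(f - half))]
  start <- list(baseline = min(f), Fmax = rng, K = max(k0, min(conc[conc > 0])))
  fit <- tryCatch(
    stats::nls(f ~ baseline + Fmax * conc / (conc + K), start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- as.list(stats::coef(fit))
    return(list(Fmax = p$Fmax, K = p$K, baseline = p$baseline,
                converged = TRUE, flat = FALSE,
                rss = sum(stats::resid(fit)^2)))
  }
  obj <- function(par) {
    pred <- par[1] + par[2] * conc / (conc + exp(par[3]))
    sum((f - pred)^2)
  }
  opt <- stats::optim(c(start$baseline, start$Fmax, log(start$K)), obj,
                      control = list(maxit = 2000))
  list(Fmax = opt$par[2], K = exp(opt$par[3]), baseline = opt$par[1],
       converged = opt$convergence == 0, flat = FALSE, rss = opt$value)
}

#' Select the working concentration from a tracer titration
#'
#' Given a titration of the tracer antibody at a fixed immunogen
#' concentration, picks the smallest tracer concentration that reaches at
#' least `plateau_fraction` of the plateau signal. A plateau is considered
#' present when the signal gain over the last dilution step is within
#' `rise_tol` of the top signal; a series that is still rising steeply at
#' its highest concentration is flagged instead.
#'
#' @param series a [dilution_series()] over tracer concentrations.
#' @param plateau_fraction fraction of the plateau signal to reach
#'   (default 0.9).
#' @param rise_tol maximum relative rise over the final step for a plateau
#'   call (default 0.1).
#' @return list with `concentration` (`NA` when flagged), `plateau`
#'   (plateau signal) and `flagged`.
#' @export
select_working_dilution <- function(series, plateau_fraction = 0.9,
                                    rise_tol = 0.1) {
  stopifnot(inherits(series, "dilution_series"))
  f <- series$F
  n <- length(f)
  plateau <- max(f)
  still_rising <- f[n] >= f[n - 1] * (1 + rise_tol)
  if (still_rising) {
    return(list(concentration = NA_real_, plateau = plateau, flagged = TRUE))
  }
  idx <- which(f >= plateau_fraction * plateau)[1]
  list(concentration = series$concentration[idx], plateau = plateau,
       flagged = FALSE)
}

#' Series and LOD-table I/O
#'
#' A dilution series round-trips through a TSV with columns `antibody`,
#' `concentration`, `F`, `background`; an LOD table mirrors the published
#' panel table layout (`antibody`, `LOD`, `LOD_TOP-PRB`).
#'
#' @param series a [dilution_series()].
#' @param path file path.
#' @return `path` (writers, invisibly) or the read object.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dilution_series"))
  out <- data.frame(antibody = attr(series, "antibody"),
                    concentration = series$concentration, F = series$F,
                    background = series$background)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @param tracer_mode tracer mode to stamp on the read series.
#' @export
read_series <- function(path, tracer_mode = "single") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("antibody", "concentration", "F", "background")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("series file missing columns: ", paste(missing_cols, collapse = ", "))
  }
  dilution_series(df$antibody[1], df$concentration, df$F, df$background,
                  tracer_mode)
}

#' @rdname write_series
#' @param lods list of `lod_estimate`s for the single tracer, and
#'   optionally a parallel list for the tracer mix.
#' @param lods_mix optional list of `lod_estimate`s with the tracer mix.
#' @export
write_lod_table <- function(lods, path, lods_mix = NULL) {
  ab <- vapply(lods, `[[`, character(1), "antibody")
  out <- data.frame(antibody = ab,
                    LOD = vapply(lods, `[[`, character(1), "lod_bound"),
                    stringsAsFactors = FALSE)
  if (!is.null(lods_mix)) {
    mix <- stats::setNames(vapply(lods_mix, `[[`, character(1), "lod_bound"),
                           vapply(lods_mix, `[[`, character(1), "antibody"))
    out[["LOD_TOP-PRB"]] <- unname(mix[ab])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
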