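#' Summarize replicate spots into a per-antibody fluorescence profile
#'
#' Collapses the replicate spots of one microarray field into a single
#' fluorescence value F per antibody (the replicate median, robust to one
#' bad spot), records the replicate coefficient of variation and quality
#' flags, and estimates the field background from the blank control spots
#' (see [estimate_background()]).
#'
#' @param spots a [spot_table()]; must contain a single field unless
#'   `field` selects one.
#' @param layout the [slide_layout()] the table was printed with; antibody
#'   replicate groups must be complete with respect to
#'   `layout$replicate_spots_per_antibody`.
#' @param field optional field id to extract from a multi-field table.
#' @param cv_limit replicate CV above which an antibody is flagged
#'   (default 0.25).
#' @param saturation intensity ceiling above which a spot counts as
#'   saturated (default 65535 a.u., the 16-bit scanner convention).
#' @return an `assay_profile`: list with `antibodies` (data frame
#'   `antibody`, `F`, `cv`, `n`, `high_cv`, `saturated`), `controls`
#'   (summarized control spots), `background` (pooled blank median, `NA`
#'   when no control spots are present), `preimmune` (named vector of
#'   per-pre-immune-spot medians, diagnostics only) and `field_id`.
#' @export
summarize_replicates <- function(spots, layout = default_layout(),
                                 field = NULL, cv_limit = 0.25,
                                 saturation = 65535) {
  stopifnot(inherits(spots, "spot_table"), inherits(layout, "slide_layout"))
  df <- as.data.frame(spots)
  if (!is.null(field)) df <- df[df$field_id == as.character(field), ]
  fields <- unique(df$field_id)
  if (length(fields) > 1) {
    stop("spot table spans fields ", paste(fields, collapse = ", "),
         "; pass `field` to pick one")
  }
  if (nrow(df) == 0) stop("no spots to summarize")

  summarize_group <- function(d) {
    m <- stats::median(d$intensity)
    mu <- mean(d$intensity)
    cv <- if (mu > 0) stats::sd(d$intensity) / mu else 0
    data.frame(target = d$target[1], role = d$role[1], F = m,
               cv = cv, n = nrow(d),
               saturated = any(d$intensity >= saturation),
               stringsAsFactors = FALSE)
  }
  groups <- split(df, paste(df$target, df$role, sep = "\r"))
  summary <- do.call(rbind, lapply(groups, summarize_group))
  rownames(summary) <- NULL

  ab <- summary[summary$role == "antibody", ]
  incomplete <- ab$n != layout$replicate_spots_per_antibody
  if (any(incomplete)) {
    bad <- ab[incomplete, ][1, ]
    stop(sprintf(
      "antibody %s in field %s has %d replicate spots, expected %d",
      bad$target, fields, bad$n, layout$replicate_spots_per_antibody))
  }
  antibodies <- data.frame(antibody = ab$target, F = ab$F, cv = ab$cv,
                           n = ab$n, high_cv = ab$cv > cv_limit,
                           saturated = ab$saturated,
                           stringsAsFactors = FALSE)
  antibodies <- antibodies[order(match(antibodies$antibody, df$target)), ]
  rownames(antibodies) <- NULL
  controls <- summary[summary$role != "antibody", ]
  rownames(controls) <- NULL

  profile <- structure(
    list(antibodies = antibodies, controls = controls,
         background = NA_real_,
         preimmune = stats::setNames(
           controls$F[controls$role == "preimmune"],
           controls$target[controls$role == "preimmune"]),
         field_id = fields, control_provenance = character()),
    class = "assay_profile")
  if (any(controls$role %in% c("blank_bsa", "blank_buffer", "preimmune"))) {
    profile$background <- estimate_background(profile)
  }
  profile
}

#' Estimate the field background from blank control spots
#'
#' The background B is the pooled median of the summarized intensities of
#' all blank spots: BSA spots, protein-printing-buffer spots and
#' pre-immune antiserum spots. The per-antibody pre-immune values are kept
#' separately on the profile for diagnostics; they do not get subtracted
#' per antibody.
#'
#' @param profile an `assay_profile` from [summarize_replicates()].
#' @return background B (a.u.).
#' @export
estimate_background <- function(profile) {
  stopifnot(inherits(profile, "assay_profile"))
  blanks <- profile$controls[
    profile$controls$role %in% c("blank_bsa", "blank_buffer", "preimmune"), ]
  if (nrow(blanks) == 0) {
    stop("no blank control spots (BSA, printing buffer or pre-immune) in profile")
  }
  stats::median(blanks$F)
}

#' Subtract a control assay from a sample assay
#'
#' Within-chip negative controls remove non-specific fluorescence: either a
#' buffer-only incubation developed with the same tracer mix, or a
#' heat-treated aliquot of the sample (500 degrees C, 3 h) in which organic
#' molecules are destroyed so that any remaining signal reflects
#' mineral-particle binding. Per antibody, `F_out = max(F_sample -
#' F_control, 0)`; fluorescence profiles are non-negative by convention
#' (the deconvolution step, in contrast, never clips).
#'
#' @param sample,control `assay_profile`s over the same antibody set.
#' @param provenance what the control was: `"buffer_only"` or
#'   `"heat_treated"`; recorded on the returned profile.
#' @return the corrected `assay_profile`.
#' @export
subtract_control <- function(sample, control,
                             provenance = c("buffer_only", "heat_treated")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(sample, "assay_profile"),
            inherits(control, "assay_profile"))
  if (!identical(sort(sample$antibodies$antibody),
                 sort(control$antibodies$antibody))) {
    stop("sample and control profiles cover different antibody panels")
  }
  idx <- match(sample$antibodies$antibody, control$antibodies$antibody)
  out <- sample
  out$antibodies$F <- pmax(sample$antibodies$F - control$antibodies$F[idx], 0)
  out$control_provenance <- c(sample$control_provenance, provenance)
  out
}

#' Positivity call
#'
#' A signal is positive only when the fluorescence strictly exceeds
#' `multiplier` times the background level; the default multiplier is 2.5.
#' A signal exactly at the threshold is negative.
#'
#' @param F fluorescence value(s), a.u.
#' @param B background, a.u.; must be positive.
#' @param multiplier threshold multiplier (> 0).
#' @return logical vector, `TRUE` where `F > multiplier * B`.
#' @export
positivity_call <- function(F, B, multiplier = 2.5) {
  if (!is.numeric(B) || length(B) != 1 || is.na(B) || B <= 0) {
    stop("background B must be a single positive number")
  }
  if (multiplier <= 0) stop("multiplier must be > 0")
  F > multiplier * B
}

#' Write / read an assay profile as TSV
#'
#' Columns: `antibody`, `F`, `background`, `cv`, `flags` (comma-joined
#' quality flags, empty when clean).
#'
#' @param profile an `assay_profile`.
#' @param path file path.
#' @return `path` invisibly, or the read `assay_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "assay_profile"))
  ab <- profile$antibodies
  flags <- vapply(seq_len(nrow(ab)), function(i) {
    paste(c(if (ab$high_cv[i]) "high_cv", if (ab$saturated[i]) "saturated"),
          collapse = ",")
  }, character(1))
  out <- data.frame(antibody = ab$antibody, F = ab$F,
                    background = profile$background, cv = ab$cv,
                    flags = flags, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("antibody", "F", "background", "cv", "flags")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("profile file missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$flags[is.na(df$flags)] <- ""
  antibodies <- data.frame(
    antibody = as.character(df$antibody), F = df$F, cv = df$cv,
    n = NA_integer_,
    high_cv = grepl("high_cv", df$flags),
    saturated = grepl("saturated", df$flags),
    stringsAsFactors = FALSE)
  structure(
    list(antibodies = antibodies,
         controls = data.frame(target = character(), role = character(),
                               F = numeric(), cv = numeric(), n = integer(),
                               saturated = logical(),
                               stringsAsFactors = FALSE),
         background = df$background[1],
         preimmune = stats::setNames(numeric(), character()),
         field_id = NA_character_, control_provenance = character()),
    class = "assay_profile")
}

#' Convenience accessor: named fluorescence vector of a profile
#' @param profile an `assay_profile`.
#' @return named numeric vector of per-antibody F values.
#' @export
profile_f <- function(profile) {
  stopifnot(inherits(profile, "assay_profile"))
  stats::setNames(profile$antibodies$F, profile$antibodies$antibody)
}

#' @export
print.assay_profile <- function(x, ...) {
  cat(sprintf("assay_profile: field %s, %d antibodies, background = %s\n",
              x$field_id, nrow(x$antibodies),
              format(x$background, digits = 4)))
  if (length(x$control_provenance)) {
    cat("control subtraction:", paste(x$control_provenance, collapse = " + "), "\n")
  }
  print(utils::head(x$antibodies, 10))
  if (nrow(x$antibodies) > 10) cat("...\n")
  invisible(x)
}
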