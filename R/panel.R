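#' Antibody panel metadata
#'
#' An `AntibodyPanel` is the roster of capture antibodies printed on the
#' microarray: for each antibody its short code (e.g. `"L6C1"`), the kind of
#' immunogen it was raised against (whole-cell lysate, exopolysaccharide
#' fraction, or purified protein), the immunogen name, and the code of its
#' pre-immune serum partner (printed as an antibody-specific blank).
#'
#' @param entries data frame with columns `code`, `immunogen_kind`
#'   (`"cell_lysate"`, `"eps_fraction"` or `"protein"`), `immunogen_name`,
#'   `preimmune_code` (`NA` allowed for protein antibodies only) and,
#'   optionally, `excluded` (logical poor-performer flag) plus free columns
#'   such as LOD annotations.
#' @return an object of class `antibody_panel` (a validated data frame).
#' @export
antibody_panel <- function(entries) {
  stopifnot(is.data.frame(entries))
  required <- c("code", "immunogen_kind", "immunogen_name", "preimmune_code")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("panel entries missing columns: ", paste(missing_cols, collapse = ", "))
  }
  entries$code <- as.character(entries$code)
  if (anyDuplicated(entries$code)) {
    stop("antibody codes must be unique")
  }
  kinds <- c("cell_lysate", "eps_fraction", "protein")
  if (!all(entries$immunogen_kind %in% kinds)) {
    stop("immunogen_kind must be one of: ", paste(kinds, collapse = ", "))
  }
  needs_preimmune <- entries$immunogen_kind != "protein"
  if (any(needs_preimmune & is.na(entries$preimmune_code))) {
    stop("every non-protein antibody needs a pre-immune partner")
  }
  if (is.null(entries$excluded)) entries$excluded <- FALSE
  structure(entries, class = c("antibody_panel", "data.frame"))
}

#' Default antibody panel of the perchlorate-reducing-bacteria chip
#'
#' The packaged panel: 20 polyclonal antibodies raised against whole-cell
#' lysates (`*C1` codes) and exopolysaccharide fractions (`*S2` codes) of
#' perchlorate-reducing strains, plus 4 antibodies against the two key
#' enzymes of perchlorate respiration (perchlorate reductase and chlorite
#' dismutase). The published limit-of-detection bounds (cells/mL, decade
#' bounds, with the single tracer and with the pooled TOP-PRB tracer mix)
#' ship as annotation columns; `"-"` marks immunogens never detected.
#'
#' Eight antibodies carry `excluded = TRUE`: the four EPS antibodies that
#' failed to give positive signals against their own antigens in sandwich
#' format (L2S2, L3S2, L4S2, L8S2) and the four anti-protein antibodies,
#' whose purified targets capture well but expose no free epitope to the
#' tracer. These are the poor performers dropped when the antibody graph is
#' built.
#'
#' @return an [antibody_panel()] with 24 rows.
#' @export
default_panel <- function() {
  strains <- data.frame(
    code = c("L1C1", "L2C1", "L3C1", "L4C1", "L5C1", "L6C1", "L7C1", "L8C1",
             "L9C1", "L10C1", "L11C1", "L12C1",
             "L1S2", "L2S2", "L3S2", "L4S2", "L6S2", "L8S2", "L11S2", "L12S2"),
    immunogen_kind = c(rep("cell_lysate", 12), rep("eps_fraction", 8)),
    immunogen_name = c(
      "Azospira suillum PS", "Magnetospirillum bellicus VDY",
      "Ideonella dechloratans", "Dechlorobacter hydrogenophilus LT-1",
      "Propionivibrio militaris MP", "Dechloromonas agitata CKB",
      "Magnetospirillum sp. WD", "Azospira sp. ZAP",
      "Shewanella algae", "Dechloromarinus chlorophilus NSS",
      "Dechloromonas aromatica RCB", "Arcobacter sp. CAB",
      "Azospira suillum PS EPS", "Magnetospirillum bellicus VDY EPS",
      "Ideonella dechloratans EPS", "Dechlorobacter hydrogenophilus LT-1 EPS",
      "Dechloromonas agitata CKB EPS", "Azospira sp. ZAP EPS",
      "Dechloromonas aromatica RCB EPS", "Arcobacter sp. CAB EPS"),
    preimmune_code = paste0("P", 1:20),
    lod = c("<10^3", "<10^2", "<10^3", "<10^3", "<10^3", "<10^3", "<10^5",
            "<10^3", "<10^2", "<10^4", "<10^3", "<10^3",
            "<10^4", "-", "-", "<10^3", "<10^2", "<10^3", "<10^5", "<10^6"),
    lod_top_prb = c("<10^3", "<10^2", "<10^3", "<10^4", "<10^3", "<10",
                    "<10^5", "<10^3", "<10^2", "<10^5", "<10^3", "<10^5",
                    "<10^5", "-", "-", "<10^4", "<10", "<10^3", "<10^5", "-"),
    stringsAsFactors = FALSE
  )
  proteins <- data.frame(
    code = c("A-PCR", "A-PCR_A/B", "A-Cld", "A-295"),
    immunogen_kind = "protein",
    immunogen_name = c("perchlorate reductase", "perchlorate reductase A/B",
                       "chlorite dismutase", "perchlorate reductase 295"),
    preimmune_code = NA_character_,
    lod = "-", lod_top_prb = "-",
    stringsAsFactors = FALSE
  )
  entries <- rbind(strains, proteins)
  # poor performers in sandwich format: four EPS antibodies with no
  # self-signal, and the four anti-protein antibodies
  entries$excluded <- entries$code %in%
    c("L2S2", "L3S2", "L4S2", "L8S2", proteins$code)
  antibody_panel(entries)
}

#' Slide layout
#'
#' Geometry of one slide: identical microarray fields arranged in a
#' `fields_rows` x `fields_cols` grid (each field takes one sample under a
#' multi-well gasket), the number of replicate spots printed per antibody,
#' and which control spot roles are present.
#'
#' @param fields_rows,fields_cols field grid dimensions; the default 3 x 8
#'   gives 24 simultaneous assays per slide.
#' @param replicate_spots_per_antibody replicate spots per antibody per
#'   field; must be at least 2 (default 3, triplicate printing).
#' @param control_spot_roles character vector of control roles printed on
#'   each field.
#' @return an object of class `slide_layout`.
#' @export
slide_layout <- function(fields_rows = 3, fields_cols = 8,
                         replicate_spots_per_antibody = 3,
                         control_spot_roles = c("blank_bsa", "blank_buffer",
                                                "preimmune",
                                                "fluorescent_frame")) {
  stopifnot(fields_rows >= 1, fields_cols >= 1)
  if (replicate_spots_per_antibody < 2) {
    stop("replicate_spots_per_antibody must be >= 2")
  }
  known <- c("blank_bsa", "blank_buffer", "preimmune", "fluorescent_frame")
  if (!all(control_spot_roles %in% known)) {
    stop("unknown control roles: ",
         paste(setdiff(control_spot_roles, known), collapse = ", "))
  }
  structure(
    list(fields_rows = fields_rows, fields_cols = fields_cols,
         replicate_spots_per_antibody = replicate_spots_per_antibody,
         control_spot_roles = control_spot_roles),
    class = "slide_layout")
}

#' @rdname slide_layout
#' @export
default_layout <- function() slide_layout()

#' Number of analysis fields on a slide
#' @param layout a [slide_layout()].
#' @return integer field count.
#' @export
n_fields <- function(layout) {
  stopifnot(inherits(layout, "slide_layout"))
  layout$fields_rows * layout$fields_cols
}

#' @export
print.slide_layout <- function(x, ...) {
  cat(sprintf("slide_layout: %d x %d fields (%d assays), %d replicate spots/antibody\n",
              x$fields_rows, x$fields_cols, n_fields(x),
              x$replicate_spots_per_antibody))
  cat("control roles:", paste(x$control_spot_roles, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.antibody_panel <- function(x, ...) {
  cat(sprintf("antibody_panel: %d antibodies (%d excluded as poor performers)\n",
              nrow(x), sum(x$excluded)))
  print.data.frame(x, ...)
  invisible(x)
}
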