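#' Spot tables
#'
#' A `spot_table` models quantified scanner output: one row per printed
#' spot, with the field it belongs to, the printed target (antibody code or
#' control identity), the spot role, a replicate index and the raw
#' fluorescence intensity in arbitrary units.
#'
#' @param df data frame with columns `field_id`, `target`, `role`,
#'   `replicate`, `intensity`. `role` is `"antibody"` or one of the control
#'   roles (`"blank_bsa"`, `"blank_buffer"`, `"preimmune"`,
#'   `"fluorescent_frame"`).
#' @return an object of class `spot_table`.
#' @export
spot_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("field_id", "target", "role", "replicate", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("spot table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  roles <- c("antibody", "blank_bsa", "blank_buffer", "preimmune",
             "fluorescent_frame")
  bad <- !df$role %in% roles
  if (any(bad)) {
    stop("unknown spot role(s): ", paste(unique(df$role[bad]), collapse = ", "))
  }
  if (nrow(df) > 0 && (!is.numeric(df$intensity) || any(is.na(df$intensity)) ||
                       any(df$intensity < 0))) {
    stop("spot intensities must be non-negative numbers")
  }
  df <- df[, required]
  df$field_id <- as.character(df$field_id)
  df$target <- as.character(df$target)
  df$replicate <- as.integer(df$replicate)
  structure(df, class = c("spot_table", "data.frame"))
}

#' Read a per-spot intensity table
#'
#' Two dialects are supported. `"tsv"` is the package's native format: a
#' tab-separated file with header `field_id  target  role  replicate
#' intensity`. `"genepix_like"` accepts GenePix-results-style exports:
#' tab-separated with an arbitrary metadata header block which is skipped
#' until the column-header row naming `Block`, `Row`, `Column`, `ID`,
#' `F635 Median` and `B635 Median` is found; `Block` becomes the field,
#' `ID` the target, and the median foreground (`F635 Median`) the spot
#' intensity. Roles are inferred from the ID: `BSA` and `PPB`/`BUFFER`
#' map to the two blank roles, `P<number>` to pre-immune spots, `FRAME`
#' to the fluorescent frame, anything else is an antibody spot. Replicate
#' indices are assigned in file order within each (field, target) group.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"genepix_like"`.
#' @return a [spot_table()].
#' @export
read_spot_table <- function(path, dialect = c("tsv", "genepix_like")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    read_spot_table_tsv(path)
  } else {
    read_spot_table_genepix(path)
  }
}

read_spot_table_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || (length(lines) == 1 && !nzchar(lines[1]))) {
    return(empty_spot_table())
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  required <- c("field_id", "target", "role", "replicate", "intensity")
  if (!all(required %in% header)) {
    stop("line 1: expected tab-separated header with columns ",
         paste(required, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) return(empty_spot_table())
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(header))) {
    bad <- which(nfield != length(header))[1]
    stop(sprintf("line %d: expected %d tab-separated fields, found %d",
                 bad + 1L, length(header), nfield[bad]))
  }
  mat <- do.call(rbind, parts)
  colnames(mat) <- header
  df <- as.data.frame(mat, stringsAsFactors = FALSE)[, required]
  rep_num <- suppressWarnings(as.integer(df$replicate))
  int_num <- suppressWarnings(as.numeric(df$intensity))
  if (anyNA(rep_num)) {
    stop(sprintf("line %d: non-integer replicate index '%s'",
                 which(is.na(rep_num))[1] + 1L,
                 df$replicate[which(is.na(rep_num))[1]]))
  }
  if (anyNA(int_num) || any(int_num < 0)) {
    bad <- which(is.na(int_num) | int_num < 0)[1]
    stop(sprintf("line %d: invalid intensity '%s' (must be a non-negative number)",
                 bad + 1L, df$intensity[bad]))
  }
  df$replicate <- rep_num
  df$intensity <- int_num
  spot_table(df)
}

read_spot_table_genepix <- function(path) {
  lines <- readLines(path)
  is_header <- grepl("Block", lines) & grepl("F635 Median", lines)
  if (!any(is_header)) {
    stop("no GenePix-style column header (with \"Block\" and \"F635 Median\") found in ", path)
  }
  skip <- which(is_header)[1] - 1L
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          stringsAsFactors = FALSE)
  needed <- c("Block", "Row", "Column", "ID", "F635 Median", "B635 Median")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("GenePix-style table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  id <- as.character(df$ID)
  role <- rep("antibody", nrow(df))
  role[toupper(id) == "BSA"] <- "blank_bsa"
  role[toupper(id) %in% c("PPB", "BUFFER")] <- "blank_buffer"
  role[grepl("^P[0-9]+$", id)] <- "preimmune"
  role[toupper(id) == "FRAME"] <- "fluorescent_frame"
  out <- data.frame(field_id = as.character(df$Block), target = id,
                    role = role, replicate = NA_integer_,
                    intensity = as.numeric(df[["F635 Median"]]),
                    stringsAsFactors = FALSE)
  out$replicate <- stats::ave(seq_len(nrow(out)),
                              out$field_id, out$target,
                              FUN = seq_along)
  spot_table(out)
}

empty_spot_table <- function() {
  spot_table(data.frame(field_id = character(), target = character(),
                        role = character(), replicate = integer(),
                        intensity = numeric(), stringsAsFactors = FALSE))
}

#' Write a spot table in the native TSV dialect
#'
#' `read_spot_table(write_spot_table(x, path))` is the identity.
#'
#' @param x a [spot_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(x, path) {
  stopifnot(inherits(x, "spot_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
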