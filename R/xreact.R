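#' Cross-reactivity matrix
#'
#' The N x N matrix G of an antibody microarray: `G[i, j]` is the extent of
#' cross-reactivity of antibody i's spot when the cognate immunogen of
#' antibody j is assayed, expressed relative to the cognate signal, so that
#' `G[j, j] = 1` for every antibody. Entries that failed the positivity
#' rule in the source assay are exactly 0.
#'
#' @param G numeric matrix with non-negative entries and unit diagonal.
#' @param antibody_order character vector of antibody codes naming the
#'   rows/columns.
#' @return an object of class `xreact_matrix`.
#' @export
xreact_matrix <- function(G, antibody_order = rownames(G)) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  if (is.null(antibody_order) || length(antibody_order) != nrow(G)) {
    stop("antibody_order must name every row/column of G")
  }
  if (any(G < 0)) stop("cross-reactivity weights must be non-negative")
  if (any(abs(diag(G) - 1) > 1e-12)) stop("G must have unit diagonal (G[j,j] = 1)")
  dimnames(G) <- list(antibody_order, antibody_order)
  structure(list(G = G, antibody_order = antibody_order),
            class = "xreact_matrix")
}

#' Build the cross-reactivity matrix from single-immunogen panel assays
#'
#' Each panel assay incubates exactly one cognate immunogen (at its working
#' concentration) on a full microarray field and is revealed with the full
#' tracer mix; the resulting profile yields one column of G. With
#' background-subtracted signals, `G[i, j] = (F_i - B) / (F_j - B)` from
#' the assay of immunogen j, gated by the positivity rule: spots that do
#' not exceed `multiplier * B` contribute an exact 0. The diagonal is 1 by
#' construction. After gating, off-diagonal entries below
#' `weak_link_floor` are zeroed to guard against background-ratio noise.
#'
#' @param panel_assays named list mapping each immunogen's antibody code to
#'   the `assay_profile` of its single-immunogen assay.
#' @param multiplier positivity multiplier (default 2.5).
#' @param weak_link_floor minimum retained off-diagonal weight
#'   (default 0.01).
#' @return an [xreact_matrix()] over `names(panel_assays)`.
#' @export
build_matrix <- function(panel_assays, multiplier = 2.5,
                         weak_link_floor = 0.01) {
  codes <- names(panel_assays)
  if (is.null(codes) || any(!nzchar(codes))) {
    stop("panel_assays must be a named list (immunogen code -> assay_profile)")
  }
  n <- length(codes)
  failed <- character()
  G <- matrix(0, n, n, dimnames = list(codes, codes))
  for (j in seq_len(n)) {
    profile <- panel_assays[[j]]
    stopifnot(inherits(profile, "assay_profile"))
    f <- profile_f(profile)
    if (!all(codes %in% names(f))) {
      stop("assay for ", codes[j], " does not cover the full antibody set")
    }
    f <- f[codes]
    B <- profile$background
    pos <- positivity_call(f, B, multiplier)
    if (!pos[j]) {
      failed <- c(failed, codes[j])
      next
    }
    col <- ifelse(pos, (f - B) / (f[j] - B), 0)
    col[col < 0] <- 0
    G[, j] <- col
    G[j, j] <- 1
  }
  if (length(failed) > 0) {
    stop("cognate spot fails positivity for: ", paste(failed, collapse = ", "),
         "; prune these antibodies first (see prune_antibodies)")
  }
  off <- G > 0 & G < weak_link_floor
  diag(off) <- FALSE
  G[off] <- 0
  xreact_matrix(G, codes)
}

#' Prune poor-performing antibodies before matrix construction
#'
#' An antibody is retained only if (a) its cognate self-signal passes the
#' positivity rule in its own single-immunogen assay and (b) it is not
#' flagged `excluded` in the panel metadata (the packaged panel flags the
#' four EPS antibodies with no self-signal and the four anti-protein
#' antibodies, reducing the 24-antibody chip to the 16-node graph).
#'
#' @param panel_assays named list of `assay_profile`s as in
#'   [build_matrix()].
#' @param panel optional [antibody_panel()] supplying `excluded` flags.
#' @param multiplier positivity multiplier (default 2.5).
#' @return character vector of retained antibody codes, in assay order.
#' @export
prune_antibodies <- function(panel_assays, panel = NULL, multiplier = 2.5) {
  codes <- names(panel_assays)
  keep <- vapply(codes, function(code) {
    profile <- panel_assays[[code]]
    f <- profile_f(profile)
    if (!code %in% names(f)) return(FALSE)
    isTRUE(positivity_call(f[[code]], profile$background, multiplier))
  }, logical(1))
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "antibody_panel"))
    excluded <- panel$code[panel$excluded]
    keep <- keep & !codes %in% excluded
  }
  retained <- codes[keep]
  if (length(retained) == 0) stop("pruning removed every antibody")
  retained
}

#' Derive the directed antibody graph from a cross-reactivity matrix
#'
#' Nodes are the antibodies; a directed link j -> i with weight `G[i, j]`
#' exists for every positive off-diagonal entry (immunogen j lights spot
#' i). A node is type A when it has out-going links (its immunogen
#' cross-reacts forward onto other spots) and type B otherwise.
#'
#' @param mat an [xreact_matrix()].
#' @return an `antibody_graph`: list with `nodes` (data frame `code`,
#'   `out_degree`, `type`), `edges` (data frame `src`, `dst`, `weight`)
#'   and `l`, the link count.
#' @export
build_graph <- function(mat) {
  stopifnot(inherits(mat, "xreact_matrix"))
  G <- mat$G
  codes <- mat$antibody_order
  idx <- which(G > 0 & row(G) != col(G), arr.ind = TRUE)
  edges <- data.frame(src = codes[idx[, "col"]], dst = codes[idx[, "row"]],
                      weight = G[idx], stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$src, codes), match(edges$dst, codes)), ]
  rownames(edges) <- NULL
  out_degree <- vapply(codes, function(code) sum(edges$src == code),
                       integer(1))
  nodes <- data.frame(code = codes, out_degree = out_degree,
                      type = ifelse(out_degree > 0, "A", "B"),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, l = nrow(edges)),
            class = "antibody_graph")
}

#' @export
print.antibody_graph <- function(x, ...) {
  cat(sprintf("antibody_graph: %d nodes, %d links (%d type A, %d type B)\n",
              nrow(x$nodes), x$l, sum(x$nodes$type == "A"),
              sum(x$nodes$type == "B")))
  invisible(x)
}

#' @export
print.xreact_matrix <- function(x, ...) {
  cat(sprintf("xreact_matrix: %d antibodies, %d positive off-diagonal entries\n",
              length(x$antibody_order),
              sum(x$G > 0) - length(x$antibody_order)))
  invisible(x)
}

#' Matrix and graph I/O
#'
#' The matrix is written as a TSV with antibody codes as header row and
#' first column; the graph as an edge-list TSV (`src`, `dst`, `weight`) or
#' as GraphML.
#'
#' @param mat an [xreact_matrix()].
#' @param path file path.
#' @return `path` (writers, invisibly) or the read object.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "xreact_matrix"))
  df <- data.frame(antibody = mat$antibody_order,
                   as.data.frame(mat$G, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  codes <- as.character(df[[1]])
  G <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(G), codes)) {
    stop("matrix file row and column antibody codes disagree")
  }
  rownames(G) <- codes
  xreact_matrix(G, codes)
}

#' @rdname write_matrix
#' @param graph an `antibody_graph` from [build_graph()].
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "antibody_graph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "antibody_graph"))
  g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                     vertices = graph$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
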