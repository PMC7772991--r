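#' Deconvolute a multiplex fluorescence profile
#'
#' In a multiplex sandwich immunoassay the fluorescence F_i of antibody i's
#' spot is approximately the sum of the contributions of all antibodies
#' that cross-react with it: `F_i = sum_j G[i, j] * F'_j`. Deconvolution
#' inverts this linear system to recover the per-antibody signals F',
#' which attribute each spot's brightness to the antigens actually driving
#' it. Deconvoluted values may legitimately be negative: a negative F'
#' flags a spot that is dimmer than its in-array cross-reactors predict.
#'
#' When G is singular or numerically ill-conditioned (2-norm condition
#' number above `cond_limit`), the minimum-norm least-squares solution is
#' returned and the `ill_conditioned` flag set, so that field data always
#' yield a report rather than an exception.
#'
#' @param mat an [xreact_matrix()].
#' @param F observed fluorescence vector (length N; a named vector is
#'   reordered to the matrix's antibody order).
#' @param cond_limit condition-number cutoff for switching to the
#'   pseudoinverse (default 1e8).
#' @return list with `F_prime` (named), `residual` (`||G F' - F||`),
#'   `ill_conditioned` (logical) and `condition` (estimated 2-norm
#'   condition number).
#' @export
deconvolve <- function(mat, F, cond_limit = 1e8) {
  stopifnot(inherits(mat, "xreact_matrix"))
  G <- mat$G
  codes <- mat$antibody_order
  if (!is.null(names(F))) {
    if (!setequal(names(F), codes)) {
      stop("names of F do not match the matrix antibody order")
    }
    F <- F[codes]
  }
  if (length(F) != length(codes)) {
    stop(sprintf("F has length %d but the matrix has %d antibodies",
                 length(F), length(codes)))
  }
  sv <- svd(G)
  condition <- if (min(sv$d) > 0) max(sv$d) / min(sv$d) else Inf
  ill <- !is.finite(condition) || condition > cond_limit
  if (ill) {
    warning(sprintf(
      "cross-reactivity matrix is ill-conditioned (condition %.3g); returning minimum-norm least-squares solution",
      condition))
    tol <- max(dim(G)) * .Machine$double.eps * max(sv$d)
    d_inv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    f_prime <- sv$v %*% (d_inv * crossprod(sv$u, F))
  } else {
    f_prime <- solve(G, F)
  }
  f_prime <- stats::setNames(as.numeric(f_prime), codes)
  residual <- sqrt(sum((as.numeric(G %*% f_prime) - as.numeric(F))^2))
  list(F_prime = f_prime, residual = residual, ill_conditioned = ill,
       condition = condition)
}

# One antibody's presence code from the four binary facts of the decision
# tree. Total and exclusive by construction; B-type nodes can never reach
# II.b because the consistency branch is only entered for type A.
classify_one <- function(f_above, fp_above, ab_type, consistency_ok) {
  stopifnot(ab_type %in% c("A", "B"))
  if (!f_above) return("I")
  if (!fp_above) return("II.a")
  if (ab_type == "B") return("III")
  if (consistency_ok) "III" else "II.b"
}

#' Classify each antibody of a deconvoluted profile into presence codes
#'
#' After deconvolution, every antibody is assigned one of four presence
#' codes describing what its spot's fluorescence means:
#'
#' * **I** — no significant signal (`F <= theta_pos`): the cognate antigen
#'   is not in the sample.
#' * **II.a** — significant signal but deconvoluted signal near zero
#'   (`F' <= theta_dec`): the spot is fully explained by in-array
#'   cross-reactors; the cognate antigen is absent, a related one (whose
#'   antibody may or may not be on the chip) is present.
#' * **II.b** — significant signal and significant F', but the antibody
#'   (type A) fails the out-neighbour consistency check: were its cognate
#'   antigen really present, it would light its cross-reaction partners
#'   more strongly than observed. The signal is attributed to a related
#'   antigen certainly *not* represented on the chip.
#' * **III** — significant signal and F', with a consistent cross-reaction
#'   pattern (or a type-B node with no forward cross-reactions to check):
#'   the cognate antigen, or a close relative, is present.
#'
#' Thresholds: `theta_pos = multiplier * B` (the positivity threshold) and
#' `theta_dec = dec_fraction * theta_pos` (the "deconvoluted ~ zero"
#' threshold; deconvoluted values live in fluorescence units because
#' `G[j, j] = 1`). The consistency check for a type-A antibody i examines
#' every out-link i -> k whose expected signal `G[k, i] * F'_i` itself
#' exceeds `theta_pos`, and requires the observed `F_k >=
#' consistency_tolerance * G[k, i] * F'_i`; an undetectably small expected
#' cross-reaction cannot fail a node.
#'
#' @inheritParams deconvolve
#' @param graph the `antibody_graph` of `mat` (defaults to
#'   [build_graph()] of `mat`); supplies the A/B node types.
#' @param B background level (a.u.).
#' @param multiplier positivity multiplier (default 2.5).
#' @param dec_fraction `theta_dec` as a fraction of `theta_pos`
#'   (default 0.5).
#' @param consistency_tolerance minimum observed/expected ratio for an
#'   out-neighbour signal to count as consistent (default 0.5).
#' @return a `deconv_report`: list with `table` (data frame `antibody`,
#'   `F`, `F_prime`, `ab_type`, `presence`, `top_explainer`, `residual`),
#'   `contributions` (per antibody, the named vector `G[i, j] * F'_j` over
#'   all j with `G[i, j] > 0`), `explanations` (per antibody, the II.a
#'   explaining set: j != i with `G[i, j] > 0` and `F'_j > theta_dec`),
#'   solver diagnostics and the thresholds used.
#' @export
classify <- function(mat, F, B, graph = build_graph(mat), multiplier = 2.5,
                     dec_fraction = 0.5, consistency_tolerance = 0.5) {
  stopifnot(inherits(mat, "xreact_matrix"),
            inherits(graph, "antibody_graph"))
  if (multiplier <= 0 || dec_fraction <= 0 || consistency_tolerance <= 0) {
    stop("multiplier, dec_fraction and consistency_tolerance must be > 0")
  }
  codes <- mat$antibody_order
  if (!identical(graph$nodes$code, codes)) {
    stop("graph node set does not match the matrix antibody order")
  }
  G <- mat$G
  sol <- deconvolve(mat, F)
  if (!is.null(names(F))) F <- F[codes]
  F <- stats::setNames(as.numeric(F), codes)
  fp <- sol$F_prime
  theta_pos <- multiplier * B
  theta_dec <- dec_fraction * theta_pos
  types <- stats::setNames(graph$nodes$type, graph$nodes$code)

  contributions <- explanations <- vector("list", length(codes))
  names(contributions) <- names(explanations) <- codes
  presence <- character(length(codes))
  top_explainer <- rep(NA_character_, length(codes))

  for (i in seq_along(codes)) {
    code <- codes[i]
    donors <- which(G[i, ] > 0)
    contrib <- stats::setNames(G[i, donors] * fp[donors], codes[donors])
    contributions[[i]] <- sort(contrib, decreasing = TRUE)
    expl_idx <- donors[codes[donors] != code & fp[donors] > theta_dec]
    expl <- stats::setNames(G[i, expl_idx] * fp[expl_idx], codes[expl_idx])
    explanations[[i]] <- sort(expl, decreasing = TRUE)
    if (length(expl) > 0) top_explainer[i] <- names(explanations[[i]])[1]

    consistency_ok <- TRUE
    if (types[[code]] == "A") {
      out_idx <- which(G[, i] > 0)
      out_idx <- out_idx[out_idx != i]
      expected <- G[out_idx, i] * fp[i]
      checked <- expected > theta_pos
      consistency_ok <- all(F[out_idx][checked] >=
                              consistency_tolerance * expected[checked])
    }
    presence[i] <- classify_one(F[i] > theta_pos, fp[i] > theta_dec,
                                types[[code]], consistency_ok)
  }

  table <- data.frame(antibody = codes, F = F, F_prime = fp,
                      ab_type = unname(types[codes]), presence = presence,
                      top_explainer = top_explainer,
                      residual = sol$residual,
                      stringsAsFactors = FALSE)
  rownames(table) <- NULL
  structure(
    list(table = table, contributions = contributions,
         explanations = explanations, residual = sol$residual,
         ill_conditioned = sol$ill_conditioned, condition = sol$condition,
         thresholds = list(background = B, multiplier = multiplier,
                           dec_fraction = dec_fraction,
                           consistency_tolerance = consistency_tolerance,
                           theta_pos = theta_pos, theta_dec = theta_dec)),
    class = "deconv_report")
}

#' Ranked contribution breakdown for one antibody
#'
#' Decomposes an antibody's observed fluorescence into the contributions
#' `G[i, j] * F'_j` of every cross-reacting antibody (including itself),
#' sorted in decreasing order. The contributions sum to `F_i` up to the
#' solver residual.
#'
#' @param report a `deconv_report` from [classify()].
#' @param antibody antibody code.
#' @return named numeric vector of contributions, decreasing.
#' @export
explain <- function(report, antibody) {
  stopifnot(inherits(report, "deconv_report"))
  if (!antibody %in% names(report$contributions)) {
    stop("unknown antibody: ", antibody)
  }
  report$contributions[[antibody]]
}

#' @export
print.deconv_report <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf(
    "deconv_report: %d antibodies; theta_pos = %.4g, theta_dec = %.4g%s\n",
    nrow(x$table), th$theta_pos, th$theta_dec,
    if (x$ill_conditioned) " [ill-conditioned solve]" else ""))
  tab <- x$table
  tab$code <- paste(tab$ab_type, tab$presence, sep = ".")
  print(tab[, c("antibody", "F", "F_prime", "code", "top_explainer")],
        digits = 4)
  invisible(x)
}

#' Report I/O
#'
#' TSV export carries columns `antibody`, `F`, `F_prime`, `ab_type`,
#' `presence_code`, `top_explainer`, `residual`; the JSON export
#' additionally serializes the full contribution/explanation structure and
#' the thresholds used.
#'
#' @param report a `deconv_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "deconv_report"))
  out <- report$table
  names(out)[names(out) == "presence"] <- "presence_code"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "deconv_report"))
  payload <- list(
    table = report$table,
    contributions = lapply(report$contributions, as.list),
    explanations = lapply(report$explanations, as.list),
    residual = report$residual,
    ill_conditioned = report$ill_conditioned,
    thresholds = report$thresholds)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
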