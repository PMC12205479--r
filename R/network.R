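EDGE_SIGNS <- c("activating", "repressing", "unknown")
EDGE_MODES <- c("direct", "indirect", "unknown")
EDGE_EVIDENCE <- c("eY1H", "in_vitro", "target_direct", "target_indirect",
                   "transactivation")

sign_value <- function(sign) {
  # numeric sign for products; NA propagates "unknown"
  unname(c(activating = 1, repressing = -1, unknown = NA_real_)[sign])
}

#' Build a signed regulatory network from edge records
#'
#' Validates records against the edge schema (columns `source`, `target`,
#' `sign`, `mode`, `evidence`, optionally `species` and `citation`), filters
#' by evidence layer, drops duplicate `(source, target, evidence)` triples
#' with a warning, and infers the node set. Self-edges are allowed and
#' represent autoregulation.
#'
#' @param edge_records Data frame of edge records.
#' @param evidence_filter Character vector of evidence layers to keep
#'   (default: all).
#' @param output_node Optional label of the network's transcriptional output
#'   (e.g. `"AtNIR1"`); stored on the network.
#' @return A `signed_network` list with `nodes`, `edges`, `output_node`.
#' @export
build_network <- function(edge_records, evidence_filter = EDGE_EVIDENCE,
                          output_node = NULL) {
  req <- c("source", "target", "sign", "mode", "evidence")
  miss <- setdiff(req, names(edge_records))
  if (length(miss) > 0) stop("missing edge columns: ",
                             paste(miss, collapse = ", "))
  errs <- character(0)
  bad_sign <- which(!(edge_records$sign %in% EDGE_SIGNS))
  if (length(bad_sign) > 0) {
    errs <- c(errs, paste0("row ", bad_sign, ": unknown sign token '",
                           edge_records$sign[bad_sign], "'"))
  }
  bad_mode <- which(!(edge_records$mode %in% EDGE_MODES))
  if (length(bad_mode) > 0) {
    errs <- c(errs, paste0("row ", bad_mode, ": unknown mode token '",
                           edge_records$mode[bad_mode], "'"))
  }
  bad_ev <- which(!(edge_records$evidence %in% EDGE_EVIDENCE))
  if (length(bad_ev) > 0) {
    errs <- c(errs, paste0("row ", bad_ev, ": unknown evidence token '",
                           edge_records$evidence[bad_ev], "'"))
  }
  if (length(errs) > 0) stop("invalid edge records:\n  ",
                             paste(errs, collapse = "\n  "))
  edges <- edge_records[edge_records$evidence %in% evidence_filter, ,
                        drop = FALSE]
  key <- paste(edges$source, edges$target, edges$evidence, sep = "\r")
  if (anyDuplicated(key)) {
    warning("dropping ", sum(duplicated(key)),
            " duplicate (source, target, evidence) record(s)")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$source, edges$target))),
                 edges = edges, output_node = output_node),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (!is.null(x$output_node))
                paste0(", output ", x$output_node) else ""))
  invisible(x)
}

#' Restrict a network to direct-mode edges
#'
#' @param net A [build_network()] result.
#' @return A `signed_network` containing only `mode == "direct"` edges.
#' @export
direct_network <- function(net) {
  build_network(net$edges[net$edges$mode == "direct", , drop = FALSE],
                output_node = net$output_node)
}

net_igraph <- function(net, drop_self = FALSE) {
  edges <- net$edges
  if (drop_self) edges <- edges[edges$source != edges$target, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target"), drop = FALSE],
    directed = TRUE, vertices = data.frame(name = net$nodes))
  g
}

#' Find autoregulatory loops
#'
#' One motif per self-edge in the network.
#'
#' @param net A `signed_network`.
#' @return Data frame with columns `gene`, `sign`, `evidence`.
#' @export
find_autoregulation <- function(net) {
  sel <- net$edges$source == net$edges$target
  data.frame(gene = net$edges$source[sel], sign = net$edges$sign[sel],
             evidence = net$edges$evidence[sel], stringsAsFactors = FALSE)
}

edge_sign_lookup <- function(net) {
  # first matching record wins; census runs on one evidence layer at a time
  key <- paste(net$edges$source, net$edges$target, sep = "\r")
  signs <- net$edges$sign[!duplicated(key)]
  setNames(signs, key[!duplicated(key)])
}

path_sign_label <- function(signs) {
  v <- sign_value(signs)
  if (anyNA(v)) return("unknown")
  if (prod(v) > 0) "activating" else "repressing"
}

#' Enumerate feedforward loops
#'
#' A feedforward loop is a direct edge `X -> Z` together with a distinct
#' simple path `X -> ... -> Z` of length 2 to `max_path_len` (self-edges are
#' excluded from paths). Classic triads have `kind = "ffl"`; longer
#' indirect paths yield `kind = "multinode_ffl"`. The result is deduplicated
#' and deterministically ordered.
#'
#' @param net A `signed_network` (census one evidence layer at a time).
#' @param max_path_len Maximum indirect-path length (edges; default 2).
#' @return Data frame with columns `kind`, `members`
#'   (slash-separated `X/Y.../Z`), `source`, `intermediates`, `target`,
#'   `direct_sign`, `path_sign`, `coherence`.
#' @export
enumerate_ffls <- function(net, max_path_len = 2) {
  stopifnot(max_path_len >= 2)
  out <- data.frame(kind = character(), members = character(),
                    source = character(), intermediates = character(),
                    target = character(), direct_sign = character(),
                    path_sign = character(), coherence = character(),
                    stringsAsFactors = FALSE)
  if (nrow(net$edges) == 0) return(out)
  g <- net_igraph(net, drop_self = TRUE)
  sgn <- edge_sign_lookup(net)
  direct <- net$edges[net$edges$source != net$edges$target, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(direct))) {
    x <- direct$source[i]; z <- direct$target[i]
    paths <- igraph::all_simple_paths(g, from = x, to = z,
                                      mode = "out", cutoff = max_path_len)
    for (p in paths) {
      nodes <- names(p)
      if (length(nodes) < 3) next  # the direct edge itself
      mids <- nodes[-c(1, length(nodes))]
      edge_keys <- paste(nodes[-length(nodes)], nodes[-1], sep = "\r")
      psign <- path_sign_label(sgn[edge_keys])
      dsign <- direct$sign[i]
      coher <- if (dsign == "unknown" || psign == "unknown") "unknown"
               else if (dsign == psign) "coherent" else "incoherent"
      rows[[length(rows) + 1]] <- data.frame(
        kind = if (length(mids) == 1) "ffl" else "multinode_ffl",
        members = paste(nodes, collapse = "/"),
        source = x, intermediates = paste(mids, collapse = "/"),
        target = z, direct_sign = dsign, path_sign = psign,
        coherence = coher, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(out)
  res <- do.call(rbind, rows)
  res <- res[!duplicated(res$members), , drop = FALSE]
  res <- res[order(res$kind, res$members), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify feedforward-loop coherence
#'
#' Coherent iff the sign of the direct edge equals the product of the signs
#' along the indirect path (with `(-) * (-) = +`); `"unknown"` if any sign is
#' unknown.
#'
#' @param motif One row of an [enumerate_ffls()] result (or a list with
#'   `kind`, `direct_sign`, `path_sign`).
#' @return `"coherent"`, `"incoherent"` or `"unknown"`.
#' @export
classify_coherence <- function(motif) {
  if (!(motif$kind %in% c("ffl", "multinode_ffl"))) {
    stop("coherence is defined for feedforward-loop motifs only")
  }
  if (motif$direct_sign == "unknown" || motif$path_sign == "unknown") {
    return("unknown")
  }
  if (motif$direct_sign == motif$path_sign) "coherent" else "incoherent"
}

#' Read a signed edge list from TSV
#'
#' Columns: `source`, `target`, `sign`, `mode`, `evidence`, and optionally
#' `species`, `citation`. Lines starting with `#` are comments.
#'
#' @param path TSV path.
#' @return Data frame of edge records.
#' @export
read_edges <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a signed edge list to TSV
#'
#' @param edges Edge-record data frame (e.g. `net$edges`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network in DOT format
#'
#' Activating edges are drawn as arrows, repressing edges with tee heads.
#'
#' @param net A `signed_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(net, path) {
  lines <- c("digraph circuit {")
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    head <- switch(e$sign, activating = "normal", repressing = "tee",
                   "empty")
    lines <- c(lines, sprintf('  "%s" -> "%s" [arrowhead=%s];',
                              e$source, e$target, head))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
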