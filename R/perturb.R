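# Qualitative knockout-effect prediction by path-sign propagation.
# Predictions are made on the direct-regulation layer against the network's
# transcriptional output node (NIR1, standing in for the nitrate-responsive
# reporter it drives).

#' Net sign of regulation from a node to the output
#'
#' Enumerates all simple directed paths from `node` to `output` over
#' direct-mode edges; the sign of a path is the product of its edge signs.
#' Returns `"positive"`/`"negative"` when all paths agree, `"mixed"` when
#' they conflict or any sign on a path is unknown, `"none"` when no path
#' exists.
#'
#' @param net A `signed_network` (only direct-mode edges are used).
#' @param node Source gene label.
#' @param output Output gene label (must be in the network).
#' @return One of `"positive"`, `"negative"`, `"mixed"`, `"none"`.
#' @export
net_path_sign <- function(net, node, output) {
  net <- direct_network(net)
  if (!(output %in% net$nodes)) stop("output node ", output,
                                     " not in network")
  if (!(node %in% net$nodes)) return("none")
  if (identical(node, output)) return("none")
  g <- net_igraph(net, drop_self = TRUE)
  sgn <- edge_sign_lookup(net)
  paths <- igraph::all_simple_paths(g, from = node, to = output,
                                    mode = "out")
  if (length(paths) == 0) return("none")
  labels <- vapply(paths, function(p) {
    nodes <- names(p)
    keys <- paste(nodes[-length(nodes)], nodes[-1], sep = "\r")
    path_sign_label(sgn[keys])
  }, character(1))
  if (any(labels == "unknown")) return("mixed")
  if (all(labels == "activating")) return("positive")
  if (all(labels == "repressing")) return("negative")
  "mixed"
}

#' Construct a genotype
#'
#' @param knocked_out Character vector of knocked-out gene labels (empty =
#'   wild type).
#' @param label Display label, e.g. `"Atarf18-2/anac032-cc-s-1"`.
#' @return A `genotype` list.
#' @export
genotype <- function(knocked_out, label = NULL) {
  knocked_out <- unique(as.character(knocked_out))
  if (is.null(label)) {
    label <- if (length(knocked_out) == 0) "WT"
             else paste(knocked_out, collapse = "/")
  }
  structure(list(knocked_out = knocked_out, label = label),
            class = "genotype")
}

reachable_from <- function(g, from) {
  # node names reachable from `from` along directed edges (excluding itself
  # unless on a cycle)
  ord <- igraph::subcomponent(g, from, mode = "out")
  setdiff(names(ord), from)
}

#' Predict the qualitative knockout effect on the output node
#'
#' Single knockouts follow the net path sign: a purely positive regulator's
#' knockout lowers reporter output, a purely negative regulator's knockout
#' raises it, and an unconnected gene gives `"unconnected"`. For multi-gene
#' knockouts the downstream-epistasis rule applies: among knocked-out genes
#' with a path to the output, a gene dominates another if it is reachable
#' from it along direct edges; if a unique dominance-maximal gene exists its
#' single-knockout direction is returned, if several maximal genes agree
#' that shared direction is returned, and conflicting or mixed-sign cases
#' are `"indeterminate"`. The wild type is `"unchanged"`.
#'
#' @param net A `signed_network`; only direct-mode edges are used.
#' @param geno A [genotype()] (or character vector of knocked-out genes).
#' @param output Output gene label (defaults to the network's
#'   `output_node`).
#' @return A `prediction` list with `genotype`, `direction` (one of
#'   `higher`, `lower`, `unchanged`, `indeterminate`, `unconnected`),
#'   `dominant_node` and a `rationale` text trace.
#' @export
predict_genotype <- function(net, geno, output = net$output_node) {
  if (is.character(geno)) geno <- genotype(geno)
  if (is.null(output)) stop("no output node given")
  net <- direct_network(net)
  ko <- geno$knocked_out
  missing <- setdiff(ko, net$nodes)
  if (length(missing) > 0) {
    stop("genotype names node(s) absent from the network: ",
         paste(missing, collapse = ", "))
  }
  mk <- function(direction, dominant, rationale) {
    structure(list(genotype = geno, direction = direction,
                   dominant_node = dominant, rationale = rationale),
              class = "prediction")
  }
  if (length(ko) == 0) return(mk("unchanged", NA_character_, "wild type"))
  signs <- vapply(ko, net_path_sign, character(1), net = net,
                  output = output)
  single_dir <- function(s) switch(s, positive = "lower", negative = "higher",
                                   mixed = "indeterminate", none =
                                     "unconnected")
  connected <- ko[signs != "none"]
  if (length(connected) == 0) {
    return(mk("unconnected", NA_character_,
              paste0("no path from {", paste(ko, collapse = ", "),
                     "} to ", output)))
  }
  g <- net_igraph(net, drop_self = TRUE)
  # n dominates m iff n is reachable from m (n lies downstream of m);
  # m is non-maximal when some other knocked-out gene strictly dominates it
  dominated <- vapply(connected, function(m) {
    any(vapply(setdiff(connected, m), function(n)
      n %in% reachable_from(g, m) && !(m %in% reachable_from(g, n)),
      logical(1)))
  }, logical(1))
  maximal <- connected[!dominated]
  dirs <- vapply(signs[maximal], single_dir, character(1))
  trace <- paste0("connected KOs: ", paste(connected, collapse = ", "),
                  "; dominance-maximal: ", paste(maximal, collapse = ", "),
                  "; path signs: ",
                  paste(maximal, signs[maximal], sep = "=", collapse = ", "))
  if (any(dirs == "indeterminate")) {
    return(mk("indeterminate", NA_character_,
              paste0(trace, "; mixed path signs")))
  }
  if (length(unique(dirs)) == 1) {
    return(mk(unname(dirs[1]), maximal[1], trace))
  }
  mk("indeterminate", NA_character_,
     paste0(trace, "; maximal knockouts disagree"))
}

#' @export
print.prediction <- function(x, ...) {
  cat(sprintf("%s -> %s%s\n", x$genotype$label, x$direction,
              if (!is.na(x$dominant_node))
                paste0(" (dominant: ", x$dominant_node, ")") else ""))
  invisible(x)
}

#' Qualitative direction from luminescence dose-response data
#'
#' The mutant-vs-wild-type difference in mean normalized luminescence is
#' regressed on nitrate concentration; the direction is the sign of the
#' slope, subject to a relative-change threshold at the highest dose
#' (default 10% of the wild-type signal).
#'
#' @param obs Data frame with columns `nitrate_mM` and
#'   `normalized_luminescence` for the mutant.
#' @param wt Same for the wild type.
#' @param threshold Relative-change threshold (default 0.1).
#' @return `"higher"`, `"lower"` or `"unchanged"`.
#' @export
direction_from_luminescence <- function(obs, wt, threshold = 0.1) {
  mmean <- tapply(obs$normalized_luminescence, obs$nitrate_mM, mean)
  wmean <- tapply(wt$normalized_luminescence, wt$nitrate_mM, mean)
  doses <- sort(as.numeric(intersect(names(mmean), names(wmean))))
  d <- mmean[as.character(doses)] - wmean[as.character(doses)]
  slope <- coef(lm(d ~ doses))[["doses"]]
  top <- as.character(max(doses))
  rel <- abs(d[[top]]) / wmean[[top]]
  if (rel < threshold) return("unchanged")
  if (slope > 0) "higher" else "lower"
}

#' Compare predictions with observed reporter directions
#'
#' @param predictions List of [predict_genotype()] results (or a data frame
#'   with `label` and `direction`).
#' @param observations Data frame with columns `label` and
#'   `observed_direction` (qualitative, vs wild type).
#' @return List with `table` (per-genotype `label`, `predicted`, `observed`,
#'   `status` in match/mismatch/untestable) and `summary` counts. Genotypes
#'   observed but never predicted are flagged with status `"unmatched"`.
#' @export
compare_to_observations <- function(predictions, observations) {
  if (is.data.frame(predictions)) {
    pred <- predictions
  } else {
    pred <- data.frame(
      label = vapply(predictions, function(p) p$genotype$label,
                     character(1)),
      direction = vapply(predictions, `[[`, character(1), "direction"),
      stringsAsFactors = FALSE)
  }
  tab <- merge(observations[, c("label", "observed_direction")], pred,
               by = "label", all.x = TRUE)
  status <- ifelse(is.na(tab$direction), "unmatched",
            ifelse(tab$direction %in% c("unconnected", "indeterminate"),
                   "untestable",
            ifelse(tab$direction == tab$observed_direction,
                   "match", "mismatch")))
  if (any(status == "unmatched")) {
    warning("observed genotype(s) without a prediction: ",
            paste(tab$label[status == "unmatched"], collapse = ", "))
  }
  tab <- data.frame(label = tab$label, predicted = tab$direction,
                    observed = tab$observed_direction, status = status,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       summary = c(match = sum(status == "match"),
                   mismatch = sum(status == "mismatch"),
                   untestable = sum(status == "untestable"),
                   unmatched = sum(status == "unmatched")))
}

#' Write a concordance report
#'
#' @param report [compare_to_observations()] result.
#' @param path Output TSV path; a `.txt` summary is written alongside.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(report, path) {
  write.table(report$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  txt <- sub("\\.tsv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  writeLines(c("prediction/observation concordance",
               sprintf("  %s: %d", names(report$summary), report$summary)),
             txt)
  invisible(path)
}
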