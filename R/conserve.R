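# Ortholog-aware cross-species comparison of direct regulatory networks.
# Paralogs are collapsed to canonical, species-agnostic group labels (e.g.
# AtNLP6/AtNLP7/SlNLP7A/SlNLP7B -> "NLP") before edge sets are intersected.

#' Read an ortholog map
#'
#' TSV with columns `species`, `gene`, `group`. Every gene maps to exactly
#' one canonical, species-agnostic group label.
#'
#' @param path TSV path.
#' @return Data frame with class `ortholog_map`.
#' @export
read_ortholog_map <- function(path) {
  map <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ortholog_map(map)
}

#' Construct an ortholog map from a data frame
#'
#' @param map Data frame with columns `species`, `gene`, `group`.
#' @return Validated `ortholog_map`.
#' @export
ortholog_map <- function(map) {
  stopifnot(all(c("species", "gene", "group") %in% names(map)))
  key <- paste(map$species, map$gene)
  if (anyDuplicated(key)) {
    stop("gene(s) mapped to more than one group: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  class(map) <- c("ortholog_map", class(map))
  map
}

map_lookup <- function(map, species, genes) {
  m <- map[map$species == species, , drop = FALSE]
  m$group[match(genes, m$gene)]
}

#' Rewrite a network onto canonical ortholog-group labels
#'
#' Edges are rewritten to `(group_source, group_target, sign, mode)` and
#' duplicates collapsed. Edges whose canonical endpoints carry conflicting
#' signs are removed from the main set and returned as conflict records.
#'
#' @param net A `signed_network` whose edges carry a `species` column (or
#'   pass `species`).
#' @param map An [ortholog_map()].
#' @param species Species code used to look up genes in the map; defaults to
#'   the (single) species of the network's edges.
#' @param unmapped `"error"` (default) or `"drop"` for nodes absent from the
#'   map; dropped nodes are reported with a warning.
#' @return List with `edges` (canonical edge data frame: `source`, `target`,
#'   `sign`, `mode`, `n_merged`), `conflicts` (same shape), and `species`.
#' @export
canonicalize <- function(net, map, species = NULL,
                         unmapped = c("error", "drop")) {
  unmapped <- match.arg(unmapped)
  if (is.null(species)) {
    sp <- unique(net$edges$species)
    if (length(sp) != 1) stop("network edges span species: ",
                              paste(sp, collapse = ", "),
                              "; pass `species` explicitly")
    species <- sp
  }
  groups <- map_lookup(map, species, net$nodes)
  if (anyNA(groups)) {
    bad <- net$nodes[is.na(groups)]
    if (unmapped == "error") {
      stop("node(s) with no ortholog-group mapping for species ", species,
           ": ", paste(bad, collapse = ", "))
    }
    warning("dropping unmapped node(s): ", paste(bad, collapse = ", "))
  }
  lut <- setNames(groups, net$nodes)
  e <- net$edges
  e$gsource <- lut[e$source]; e$gtarget <- lut[e$target]
  e <- e[!is.na(e$gsource) & !is.na(e$gtarget), , drop = FALSE]
  key <- paste(e$gsource, e$gtarget, e$mode, sep = "\r")
  agg <- lapply(split(e, key), function(part) {
    data.frame(source = part$gsource[1], target = part$gtarget[1],
               sign = if (length(unique(part$sign)) == 1) part$sign[1]
                      else "conflict",
               mode = part$mode[1], n_merged = nrow(part),
               stringsAsFactors = FALSE)
  })
  can <- do.call(rbind, agg)
  rownames(can) <- NULL
  conflicts <- can[can$sign == "conflict", , drop = FALSE]
  can <- can[can$sign != "conflict", , drop = FALSE]
  can <- can[order(can$source, can$target), , drop = FALSE]
  rownames(can) <- rownames(conflicts) <- NULL
  list(edges = can, conflicts = conflicts, species = species)
}

canonical_key <- function(edges) {
  paste(edges$source, edges$target, edges$sign, sep = "\r")
}

#' Intersect two canonicalized networks
#'
#' Conserved edges agree in source group, target group and sign, and are
#' direct-mode on both sides. Same-topology, opposite-sign pairs are
#' classified `"rewired"` and listed in both species-specific outputs with a
#' cross-reference column.
#'
#' @param canA,canB Results of [canonicalize()] on the two networks (same
#'   map).
#' @return List with data frames `conserved`, `onlyA`, `onlyB`; the
#'   species-specific frames carry a logical `rewired` column.
#' @export
intersect_networks <- function(canA, canB) {
  a <- canA$edges[canA$edges$mode == "direct", , drop = FALSE]
  b <- canB$edges[canB$edges$mode == "direct", , drop = FALSE]
  ka <- canonical_key(a); kb <- canonical_key(b)
  conserved <- a[ka %in% kb, , drop = FALSE]
  onlyA <- a[!(ka %in% kb), , drop = FALSE]
  onlyB <- b[!(kb %in% ka), , drop = FALSE]
  topo <- function(e) paste(e$source, e$target, sep = "\r")
  onlyA$rewired <- topo(onlyA) %in% topo(onlyB)
  onlyB$rewired <- topo(onlyB) %in% topo(onlyA)
  ord <- function(e) { e <- e[order(e$source, e$target), , drop = FALSE]
                       rownames(e) <- NULL; e }
  list(conserved = ord(conserved), onlyA = ord(onlyA), onlyB = ord(onlyB))
}

#' Annotate species-specific edges whose genes lack an ortholog
#'
#' Adds an `ortholog_absent` flag to a species-specific edge frame for
#' groups absent from the other species in the map (e.g. ANAC032, which has
#' no clear tomato ortholog).
#'
#' @param edges A species-specific edge frame from [intersect_networks()].
#' @param map The [ortholog_map()].
#' @param other_species Species code of the other network.
#' @return `edges` with a logical `ortholog_absent` column.
#' @export
flag_ortholog_absent <- function(edges, map, other_species) {
  present <- unique(map$group[map$species == other_species])
  edges$ortholog_absent <- !(edges$source %in% present) |
    !(edges$target %in% present)
  edges
}
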