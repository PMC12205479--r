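# Packaged edge-list fixtures encoding the study's networks, the ortholog
# map, and the reporter-assay genotype tables.

#' Path to a packaged fixture file
#'
#' Available fixtures: `at_direct`, `sl_direct`, `ey1h_at`, `invitro_at`,
#' `orthologs`, `parot_genotypes_at`, `parot_genotypes_sl`,
#' `synthetic_arf_like_pwm`.
#'
#' @param name Fixture name (without extension).
#' @return Absolute file path.
#' @export
nrc_fixture <- function(name) {
  ext <- if (name == "synthetic_arf_like_pwm") ".txt" else ".tsv"
  path <- system.file("extdata", paste0(name, ext), package = "nitrocircuit")
  if (path == "") stop("unknown fixture: ", name)
  path
}

#' Load a packaged circuit fixture as a signed network
#'
#' @param name One of `"at_direct"`, `"sl_direct"`, `"ey1h_at"`,
#'   `"invitro_at"`.
#' @param evidence_filter Evidence layers to keep (default: all).
#' @return A `signed_network`; the direct fixtures carry their species'
#'   nitrite reductase gene as `output_node`.
#' @export
circuit_fixture <- function(name, evidence_filter = EDGE_EVIDENCE) {
  records <- read_edges(nrc_fixture(name))
  output <- switch(name, at_direct = "AtNIR1", sl_direct = "SlNIR1", NULL)
  build_network(records, evidence_filter = evidence_filter,
                output_node = output)
}

#' Load a packaged reporter-assay genotype table
#'
#' @param species `"At"` or `"Sl"`.
#' @return List with `genotypes` (list of [genotype()]) and `observations`
#'   (data frame `label`, `observed_direction`).
#' @export
parot_genotypes <- function(species = c("At", "Sl")) {
  species <- match.arg(species)
  tab <- read.delim(nrc_fixture(paste0("parot_genotypes_",
                                       tolower(species))),
                    comment.char = "#", stringsAsFactors = FALSE)
  genos <- lapply(seq_len(nrow(tab)), function(i) {
    genotype(strsplit(tab$knocked_out[i], ",")[[1]], tab$label[i])
  })
  list(genotypes = genos,
       observations = tab[, c("label", "observed_direction")])
}

#' Load the packaged ortholog map
#'
#' @return An [ortholog_map()].
#' @export
ortholog_fixture <- function() {
  read_ortholog_map(nrc_fixture("orthologs"))
}
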