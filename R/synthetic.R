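# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes: zero-order background promoters with planted motif
# instances, open-chromatin tracks covering a chosen fraction of planted
# sites, signed digraphs with a controlled number of planted feedforward
# loops, nitrate dose-response luminescence with genotype effects, and Ct
# tables with known fold changes. All generators are pure functions of
# (spec, seed).

#' Specification for synthetic promoter data
#'
#' @param seed Integer RNG seed.
#' @param seq_length Region length in bp.
#' @param tss_index 0-based index of the TSS within the region (default two
#'   thirds in, giving a 2:1 upstream:downstream split as in the Arabidopsis
#'   region convention).
#' @param base_composition Zero-order base frequencies (A, C, G, T; sums
#'   to 1).
#' @param planted_motifs Data frame with columns `motif` (sequence to
#'   plant), `position` (TSS-relative start of the oriented occurrence) and
#'   `strand`.
#' @param peak_coverage Fraction of planted sites covered by synthetic
#'   open-chromatin peaks (0..1).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(seed = 1L, seq_length = 3000L, tss_index = NULL,
                       base_composition = rep(0.25, 4),
                       planted_motifs = NULL, peak_coverage = 1) {
  if (abs(sum(base_composition) - 1) > 1e-9) {
    stop("base composition must sum to 1")
  }
  if (peak_coverage < 0 || peak_coverage > 1) {
    stop("peak_coverage must lie in [0, 1]")
  }
  if (is.null(tss_index)) tss_index <- as.integer(floor(seq_length * 2 / 3))
  if (is.null(planted_motifs)) {
    planted_motifs <- data.frame(motif = character(), position = integer(),
                                 strand = character(),
                                 stringsAsFactors = FALSE)
  }
  structure(list(seed = as.integer(seed), seq_length = as.integer(seq_length),
                 tss_index = as.integer(tss_index),
                 base_composition = setNames(base_composition, DNA_BASES),
                 planted_motifs = planted_motifs,
                 peak_coverage = peak_coverage),
            class = "synth_spec")
}

#' Generate a synthetic promoter region with planted motif sites
#'
#' Background bases are drawn i.i.d. from the spec's zero-order composition;
#' planted motifs are written at their recorded TSS-relative positions and
#' strands. Identical seeds give byte-identical output.
#'
#' @param spec A [synth_spec()].
#' @param gene_id Identifier for the synthetic region.
#' @return List with `region` (a `promoter_region`), `truth` (data frame of
#'   planted sites with TSS-relative `start`, `end`, `strand`, `motif`) and
#'   `peaks` (a [merge_intervals()] peak set covering `peak_coverage` of the
#'   planted sites).
#' @export
gen_promoter <- function(spec, gene_id = "synth_gene") {
  set.seed(spec$seed)
  L <- spec$seq_length
  bases <- sample(DNA_BASES, L, replace = TRUE, prob = spec$base_composition)
  pm <- spec$planted_motifs
  occupied <- integer(0)
  truth <- list()
  if (nrow(pm) > 0) {
    for (i in seq_len(nrow(pm))) {
      word <- toupper(pm$motif[i])
      k <- nchar(word)
      idx <- spec$tss_index + pm$position[i]  # 0-based oriented index
      if (idx < 0 || idx + k > L) {
        stop("planted motif ", word, " at position ", pm$position[i],
             " does not fit within the region")
      }
      cells <- (idx + 1):(idx + k)
      if (any(cells %in% occupied)) {
        stop("planted motifs overlap at position ", pm$position[i])
      }
      occupied <- c(occupied, cells)
      w <- word
      if (pm$strand[i] == "-") {
        w <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(word)))
      }
      bases[cells] <- strsplit(w, "")[[1]]
      truth[[i]] <- data.frame(motif = word, start = pm$position[i],
                               end = pm$position[i] + k,
                               strand = pm$strand[i],
                               abs_start = idx, abs_end = idx + k,
                               stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(motif = character(), start = integer(), end = integer(),
               strand = character(), abs_start = integer(),
               abs_end = integer(), stringsAsFactors = FALSE)
  chrom <- "synth1"
  region <- structure(list(
    gene_id = gene_id,
    interval = genomic_interval(chrom, 0L, L, "+"),
    strand = "+", tss = spec$tss_index,
    sequence = paste(bases, collapse = ""),
    tss_index = spec$tss_index,
    tss_offset = local({ tss <- spec$tss_index; function(pos) pos - tss })),
    class = "promoter_region")
  peaks <- merge_intervals(genomic_interval(chrom, 0L, 1L)[0, , drop = FALSE])
  if (nrow(truth) > 0 && spec$peak_coverage > 0) {
    n_cov <- round(spec$peak_coverage * nrow(truth))
    if (n_cov > 0) {
      sel <- sort(sample(seq_len(nrow(truth)), n_cov))
      pad <- 20L
      iv <- genomic_interval(chrom,
                             pmax(truth$abs_start[sel] - pad, 0L),
                             pmin(truth$abs_end[sel] + pad, L))
      peaks <- merge_intervals(iv, tissue_label = "synthetic")
    }
  }
  list(region = region, truth = truth, peaks = peaks)
}

#' Generate a random signed network with planted feedforward loops
#'
#' Builds a signed digraph on `n_nodes` containing exactly
#' `n_planted_ffls` three-node feedforward loops: the planted triads are
#' wired explicitly and additional random edges are accepted only if they
#' create no incidental loop (rejection sampling with bounded retries).
#'
#' @param n_nodes Node count.
#' @param n_edges Total edge budget (must be at least `3 * n_planted_ffls`).
#' @param n_planted_ffls Number of planted triads (node-disjoint; requires
#'   `3 * n_planted_ffls <= n_nodes`).
#' @param p_activating Probability that an edge is activating.
#' @param seed RNG seed.
#' @param max_tries Bound on rejection-sampling attempts per extra edge.
#' @return List with `network` (a `signed_network`) and `planted` (data
#'   frame of planted triads `x`, `y`, `z`).
#' @export
gen_network <- function(n_nodes = 10, n_edges = 12, n_planted_ffls = 2,
                        p_activating = 0.6, seed = 1L, max_tries = 200) {
  if (3 * n_planted_ffls > n_nodes) {
    stop("planted FFL count infeasible: need 3 nodes per disjoint triad")
  }
  if (n_edges < 3 * n_planted_ffls) {
    stop("edge budget below the 3 edges per planted triad")
  }
  set.seed(seed)
  nodes <- sprintf("g%02d", seq_len(n_nodes))
  adj <- matrix(FALSE, n_nodes, n_nodes, dimnames = list(nodes, nodes))
  rand_sign <- function(k) ifelse(runif(k) < p_activating,
                                  "activating", "repressing")
  planted <- list()
  edges <- list()
  add_edge <- function(u, v) {
    adj[u, v] <<- TRUE
    edges[[length(edges) + 1]] <<- c(u, v)
  }
  pool <- sample(nodes)
  for (i in seq_len(n_planted_ffls)) {
    tri <- pool[(3 * i - 2):(3 * i)]
    add_edge(tri[1], tri[2]); add_edge(tri[2], tri[3])
    add_edge(tri[1], tri[3])
    planted[[i]] <- data.frame(x = tri[1], y = tri[2], z = tri[3],
                               stringsAsFactors = FALSE)
  }
  creates_ffl <- function(u, v) {
    # u->v closing a 2-path, becoming the last leg, or the first leg
    ui <- match(u, nodes); vi <- match(v, nodes)
    through <- which(adj[ui, ] & adj[, vi])          # u->w->v with u->v new
    if (length(setdiff(nodes[through], c(u, v))) > 0) return(TRUE)
    downstream <- which(adj[vi, ] & adj[ui, ])       # u->v->z with u->z
    if (length(setdiff(nodes[downstream], c(u, v))) > 0) return(TRUE)
    upstream <- which(adj[, ui] & adj[, vi])         # x->u->v with x->v
    if (length(setdiff(nodes[upstream], c(u, v))) > 0) return(TRUE)
    FALSE
  }
  n_extra <- n_edges - 3 * n_planted_ffls
  for (i in seq_len(n_extra)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      u <- sample(nodes, 1); v <- sample(nodes, 1)
      if (u == v || adj[u, v] || creates_ffl(u, v)) next
      add_edge(u, v); placed <- TRUE; break
    }
    if (!placed) {
      stop("could not place edge ", i, " of ", n_extra,
           " without creating an incidental feedforward loop; ",
           "reduce the edge budget")
    }
  }
  em <- do.call(rbind, edges)
  records <- data.frame(source = em[, 1], target = em[, 2],
                        sign = rand_sign(nrow(em)), mode = "direct",
                        evidence = "target_direct", species = "synthetic",
                        stringsAsFactors = FALSE)
  planted <- if (length(planted) > 0) do.call(rbind, planted) else
    data.frame(x = character(), y = character(), z = character(),
               stringsAsFactors = FALSE)
  list(network = build_network(records), planted = planted)
}

#' Generate synthetic reporter observations for a set of genotypes
#'
#' Wild-type expected normalized luminescence follows the spec'd
#' dose-response (monotone increasing in nitrate); each mutant's expected
#' curve is scaled per its [predict_genotype()] direction (`lower` x
#' `scale_lower`, `higher` x `scale_higher`, otherwise unchanged), with
#' multiplicative lognormal noise of coefficient of variation `noise_cv` and
#' `n_reps` biological replicates per condition.
#'
#' @param net A `signed_network` with a defined output node.
#' @param genotypes List of [genotype()] objects (wild type added
#'   automatically).
#' @param dose_response Named numeric vector mapping nitrate mM to WT
#'   expected normalized luminescence.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.2).
#' @param scale_lower,scale_higher Mutant effect-size scale factors
#'   (synthetic conventions, defaults 0.3 and 2).
#' @param n_reps Biological replicates per genotype x dose (default 4).
#' @param seed RNG seed.
#' @param output Output node (defaults to the network's).
#' @return List with `observations` (long data frame: `label`,
#'   `nitrate_mM`, `replicate`, `normalized_luminescence`) and `truth`
#'   (data frame `label`, `direction` of the generating effect).
#' @export
gen_parot <- function(net, genotypes, dose_response = c(`0` = 1, `1` = 3,
                                                        `10` = 6),
                      noise_cv = 0.2, scale_lower = 0.3, scale_higher = 2,
                      n_reps = 4, seed = 1L, output = net$output_node) {
  set.seed(seed)
  doses <- as.numeric(names(dose_response))
  sdlog <- sqrt(log(1 + noise_cv^2))
  genos <- c(list(genotype(character(0), "WT")), genotypes)
  rows <- list(); truth <- list()
  for (geno in genos) {
    dir <- if (length(geno$knocked_out) == 0) "unchanged" else
      predict_genotype(net, geno, output = output)$direction
    fac <- switch(dir, lower = scale_lower, higher = scale_higher, 1)
    expected <- dose_response * fac
    noise <- if (noise_cv > 0) {
      rlnorm(length(doses) * n_reps, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(doses) * n_reps)
    rows[[geno$label]] <- data.frame(
      label = geno$label,
      nitrate_mM = rep(doses, each = n_reps),
      replicate = rep(seq_len(n_reps), times = length(doses)),
      normalized_luminescence = rep(expected, each = n_reps) * noise,
      stringsAsFactors = FALSE)
    truth[[geno$label]] <- data.frame(label = geno$label, direction = dir,
                                      stringsAsFactors = FALSE)
  }
  list(observations = do.call(rbind, unname(rows)),
       truth = do.call(rbind, unname(truth)))
}

#' Derive observed directions from synthetic (or real) reporter data
#'
#' Applies [direction_from_luminescence()] per genotype against the wild
#' type rows (`label == wt_label`).
#'
#' @param observations Long observation data frame from [gen_parot()].
#' @param wt_label Wild-type label (default `"WT"`).
#' @param threshold Relative-change threshold (default 0.1).
#' @return Data frame `label`, `observed_direction`.
#' @export
observed_directions <- function(observations, wt_label = "WT",
                                threshold = 0.1) {
  wt <- observations[observations$label == wt_label, , drop = FALSE]
  labs <- setdiff(unique(observations$label), wt_label)
  data.frame(
    label = labs,
    observed_direction = vapply(labs, function(l) {
      direction_from_luminescence(
        observations[observations$label == l, , drop = FALSE], wt,
        threshold = threshold)
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate qPCR Ct records with known fold changes
#'
#' Ct values are constructed so that [fold_change_ddct()] recovers the true
#' fold change exactly at zero noise; Gaussian noise on the Ct scale is
#' added otherwise.
#'
#' @param true_fold_changes Positive numeric vector of target fold changes.
#' @param noise_sd Gaussian Ct noise standard deviation (default 0).
#' @param ct_ref Reference-gene Ct level (default 20).
#' @param ct_target_base Target-gene Ct in the empty-vector condition
#'   (default 25).
#' @param seed RNG seed.
#' @return Data frame with one row per fold change: `true_fold_change`,
#'   `ct_target_tf`, `ct_ref_tf`, `ct_target_ev`, `ct_ref_ev`.
#' @export
gen_qpcr <- function(true_fold_changes, noise_sd = 0, ct_ref = 20,
                     ct_target_base = 25, seed = 1L) {
  if (any(true_fold_changes <= 0)) stop("fold changes must be > 0")
  set.seed(seed)
  n <- length(true_fold_changes)
  ddct <- -log2(true_fold_changes)
  out <- data.frame(
    true_fold_change = true_fold_changes,
    ct_target_tf = ct_target_base + ddct + rnorm(n, 0, noise_sd),
    ct_ref_tf = ct_ref + rnorm(n, 0, noise_sd),
    ct_target_ev = ct_target_base + rnorm(n, 0, noise_sd),
    ct_ref_ev = ct_ref + rnorm(n, 0, noise_sd))
  out
}
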