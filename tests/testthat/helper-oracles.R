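# Independent oracles used across the suite. These deliberately use naive
# exhaustive algorithms, not the package's code paths.

# Exhaustive PWM p-value: enumerate all 4^k words, score with the continuous
# log-odds matrix, sum background probabilities of words scoring >= threshold.
enum_pvalue <- function(motif, threshold) {
  lo <- nitrocircuit::log_odds(motif)
  k <- ncol(lo)
  words <- as.matrix(expand.grid(rep(list(1:4), k)))
  sc <- rowSums(matrix(lo[cbind(as.vector(words), rep(1:k, each = nrow(words)))],
                       nrow(words), k))
  bg <- motif$background
  wp <- exp(rowSums(matrix(log(bg)[as.vector(words)], nrow(words), k)))
  sum(wp[sc >= threshold - 1e-12])
}

# All distinct achievable scores of a PWM (for picking tie thresholds).
enum_scores <- function(motif) {
  lo <- nitrocircuit::log_odds(motif)
  k <- ncol(lo)
  words <- as.matrix(expand.grid(rep(list(1:4), k)))
  sort(unique(rowSums(
    matrix(lo[cbind(as.vector(words), rep(1:k, each = nrow(words)))],
           nrow(words), k))), decreasing = TRUE)
}

# Brute-force 3-node feedforward-loop triads: ordered triples (x, y, z) of
# distinct nodes with edges x->y, y->z and x->z.
brute_ffl_triads <- function(net) {
  e <- net$edges[net$edges$source != net$edges$target, , drop = FALSE]
  has <- function(a, b) any(e$source == a & e$target == b)
  nodes <- net$nodes
  out <- character(0)
  for (x in nodes) for (y in nodes) for (z in nodes) {
    if (x != y && y != z && x != z &&
        has(x, y) && has(y, z) && has(x, z)) {
      out <- c(out, paste(x, y, z, sep = "/"))
    }
  }
  sort(out)
}

random_signed_network <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  sel <- runif(nrow(pairs)) < p_edge
  e <- pairs[sel, , drop = FALSE]
  e$sign <- sample(c("activating", "repressing"), nrow(e), replace = TRUE)
  e$mode <- "direct"
  e$evidence <- "target_direct"
  nitrocircuit::build_network(e)
}

random_pwm <- function(k, seed) {
  set.seed(seed)
  probs <- matrix(rexp(4 * k), 4, k)
  probs <- sweep(probs, 2, colSums(probs), "/")
  nitrocircuit::pwm_motif(sprintf("rand%d_%d", k, seed), probs)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
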