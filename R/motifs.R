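DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Construct a position weight matrix motif
#'
#' Per-position base probabilities with a zero-order background. A
#' pseudocount is distributed proportionally to the background frequencies
#' before renormalization so that no probability is exactly zero.
#'
#' @param name Motif name.
#' @param probs 4 x L numeric matrix of base probabilities; rows A, C, G, T
#'   (each column sums to 1).
#' @param background Length-4 zero-order background frequencies (A, C, G, T);
#'   must sum to 1 and be strictly positive.
#' @param pseudocount Probability mass redistributed toward the background at
#'   each position (default 0.01).
#' @return A `pwm_motif` object.
#' @export
pwm_motif <- function(name, probs, background = rep(0.25, 4),
                      pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("probs must be a 4 x L matrix (rows A,C,G,T)")
  if (any(abs(colSums(probs) - 1) > 1e-6)) {
    stop("each PWM column must sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    stop("background must be strictly positive and sum to 1")
  }
  probs <- sweep(probs, 1, 0, "+")
  probs <- probs * (1 - pseudocount) + pseudocount * background
  probs <- sweep(probs, 2, colSums(probs), "/")
  rownames(probs) <- DNA_BASES
  structure(list(name = name, probs = probs,
                 background = setNames(background, DNA_BASES),
                 pseudocount = pseudocount, length = ncol(probs)),
            class = "pwm_motif")
}

#' Construct a degenerate IUPAC consensus pattern
#'
#' @param name Motif name.
#' @param pattern String over the IUPAC nucleotide alphabet, e.g.
#'   `"TGNCYYTT"`.
#' @return An `iupac_pattern` object.
#' @export
iupac_pattern <- function(name, pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(list(name = name, pattern = paste(chars, collapse = ""),
                 length = length(chars)),
            class = "iupac_pattern")
}

#' Convert an IUPAC pattern to a 0/1-style PWM
#'
#' Allowed bases at each position share the probability mass uniformly; the
#' usual pseudocount then guarantees strictly positive entries.
#'
#' @inheritParams pwm_motif
#' @param pattern An [iupac_pattern()] or a pattern string.
#' @return A [pwm_motif()].
#' @export
iupac_to_pwm <- function(pattern, name = NULL, background = rep(0.25, 4),
                         pseudocount = 0.01) {
  if (is.character(pattern)) pattern <- iupac_pattern(pattern, pattern)
  if (is.null(name)) name <- pattern$name
  chars <- strsplit(pattern$pattern, "")[[1]]
  probs <- vapply(chars, function(ch) {
    allowed <- IUPAC_SETS[[ch]]
    p <- setNames(numeric(4), DNA_BASES)
    p[allowed] <- 1 / length(allowed)
    p
  }, numeric(4))
  pwm_motif(name, probs, background = background, pseudocount = pseudocount)
}

#' Background match probability of an IUPAC pattern
#'
#' The probability that a random k-mer drawn from the zero-order background
#' matches the degenerate pattern; serves as the p-value attached to exact
#' consensus matches.
#'
#' @param pattern An [iupac_pattern()] or pattern string.
#' @param background Zero-order base frequencies (A, C, G, T).
#' @return A probability.
#' @export
iupac_match_prob <- function(pattern, background = rep(0.25, 4)) {
  if (is.character(pattern)) pattern <- iupac_pattern(pattern, pattern)
  background <- setNames(background, DNA_BASES)
  chars <- strsplit(pattern$pattern, "")[[1]]
  prod(vapply(chars, function(ch) sum(background[IUPAC_SETS[[ch]]]),
              numeric(1)))
}

#' Per-position log-odds scores of a PWM
#'
#' `entry(i, b) = log(probs(i, b) / background(b))`, in natural log units
#' (nats).
#'
#' @param motif A [pwm_motif()].
#' @return 4 x L numeric matrix of log-odds scores (rows A, C, G, T).
#' @export
log_odds <- function(motif) {
  stopifnot(inherits(motif, "pwm_motif"))
  if (any(motif$background <= 0)) stop("zero background frequency")
  log(motif$probs / motif$background)
}

#' Reverse complement of a PWM motif
#'
#' @param motif A [pwm_motif()].
#' @return A [pwm_motif()] for the reverse-complement preference.
#' @export
reverse_complement_pwm <- function(motif) {
  probs <- motif$probs[4:1, ncol(motif$probs):1, drop = FALSE]
  rownames(probs) <- DNA_BASES
  pwm_motif(paste0(motif$name, "_rc"), probs,
            background = unname(motif$background), pseudocount = 0)
}

# Integer-lattice score distribution of a PWM under its background.
# Returns list(offset, probs) where score s*gran has probability
# probs[s - offset + 1]. State count is bounded by `max_states`; the
# granularity actually used is returned.
pwm_score_distribution <- function(lo, background, gran, max_states = 4e6) {
  L <- ncol(lo)
  m_int <- round(lo / gran)
  lo_min <- sum(apply(m_int, 2, min)); lo_max <- sum(apply(m_int, 2, max))
  if (lo_max - lo_min + 1 > max_states) return(NULL)
  # DP: point mass at 0, shifted/accumulated one position at a time;
  # offsets tracked relative to the running minimum
  cur_min <- 0L
  cur <- 1
  for (j in seq_len(L)) {
    vals <- m_int[, j]
    vmin <- min(vals)
    width <- length(cur) + (max(vals) - vmin)
    nxt <- numeric(width)
    for (b in 1:4) {
      off <- vals[b] - vmin
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + cur * background[b]
    }
    cur <- nxt
    cur_min <- cur_min + vmin
  }
  list(offset = cur_min, probs = cur, gran = gran, m_int = m_int)
}

# Survival lookup: P(S_int >= s_int) for the lattice distribution.
lattice_survival <- function(dist) {
  surv <- rev(cumsum(rev(dist$probs)))
  function(s_int) {
    i <- s_int - dist$offset + 1
    i <- pmax(pmin(i, length(surv) + 1), 1)
    ifelse(i > length(surv), 0, surv[i])
  }
}

#' Exact PWM score p-value by dynamic programming
#'
#' Computes `P(score >= threshold)` for the log-odds score of a random k-mer
#' drawn from the zero-order background, via dynamic programming over
#' integer-discretized scores. The granularity is refined (factor 8 per step,
#' bounded by a state cap) until two successive refinements agree within
#' `tol`. Exact ties with the threshold count as `>=`: the integer threshold
#' carries a motif-length lattice margin so words scoring exactly `threshold`
#' are never lost to rounding.
#'
#' @param motif A [pwm_motif()].
#' @param threshold Log-odds score threshold (nats).
#' @param gran Initial discretization granularity (default 1e-3).
#' @param tol Absolute convergence tolerance on the p-value (default 1e-8).
#' @param max_states Cap on the DP state count per refinement.
#' @return A probability in `[0, 1]`; monotone non-increasing in `threshold`.
#' @export
score_pvalue <- function(motif, threshold, gran = 1e-3, tol = 1e-8,
                         max_states = 4e6) {
  stopifnot(inherits(motif, "pwm_motif"), is.finite(threshold))
  lo <- log_odds(motif)
  bg <- motif$background
  max_score <- sum(apply(lo, 2, max)); min_score <- sum(apply(lo, 2, min))
  if (threshold > max_score) return(0)
  if (threshold <= min_score) return(1)
  L <- ncol(lo)
  p_prev <- NA_real_
  g <- gran
  repeat {
    dist <- pwm_score_distribution(lo, bg, g, max_states)
    if (is.null(dist)) break
    surv <- lattice_survival(dist)
    # margin of L lattice units: ties (and rounding jitter) count as >=
    t_int <- as.integer(round(threshold / g)) - L
    p <- surv(t_int)
    if (!is.na(p_prev) && abs(p - p_prev) <= tol) return(p)
    p_prev <- p
    g <- g / 8
  }
  p_prev
}

#' Read motifs from a MEME-format file
#'
#' Supports the minimal MEME motif text format (`MEME version`, `ALPHABET`,
#' `Background letter frequencies`, `MOTIF` blocks with
#' `letter-probability matrix` headers).
#'
#' @param path Path to a MEME motif file.
#' @param pseudocount Pseudocount passed to [pwm_motif()].
#' @return A list of [pwm_motif()] objects.
#' @export
read_meme <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) > 0 && bg_i[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      labs <- toupper(toks[seq(1, length(toks), 2)])
      nums <- suppressWarnings(as.numeric(toks[seq(2, length(toks), 2)]))
      m <- match(DNA_BASES, labs)
      if (!anyNA(m) && !anyNA(nums[m])) bg <- nums[m]
    }
  }
  motif_i <- grep("^MOTIF", lines)
  out <- list()
  for (mi in motif_i) {
    name <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[(mi + 1):length(lines)])
    if (length(hdr) == 0) next
    hdr <- mi + hdr[1]
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])
    w <- suppressWarnings(as.integer(w))
    rows <- list(); i <- hdr + 1
    while (i <= length(lines)) {
      toks <- suppressWarnings(as.numeric(
        strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(toks) != 4 || any(is.na(toks))) break
      rows[[length(rows) + 1]] <- toks
      i <- i + 1
      if (!is.na(w) && length(rows) == w) break
    }
    probs <- t(do.call(rbind, rows))  # 4 x L, rows A,C,G,T
    out[[name]] <- pwm_motif(name, probs, background = bg,
                             pseudocount = pseudocount)
  }
  out
}

#' Read a PWM from a plain 4-column probability table
#'
#' One row per motif position, columns `A`, `C`, `G`, `T` (tab- or
#' whitespace-separated, with a header line).
#'
#' @param path File path.
#' @param name Motif name (defaults to the file's base name).
#' @inheritParams pwm_motif
#' @return A [pwm_motif()].
#' @export
read_pwm_table <- function(path, name = NULL, background = rep(0.25, 4),
                           pseudocount = 0.01) {
  tab <- read.delim(path, sep = "", header = TRUE, comment.char = "#")
  stopifnot(all(DNA_BASES %in% toupper(names(tab))))
  names(tab) <- toupper(names(tab))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pwm_motif(name, t(as.matrix(tab[, DNA_BASES])), background = background,
            pseudocount = pseudocount)
}

#' The printed consensus motifs of the nitrate sub-circuit factors
#'
#' Degenerate binding-site consensi for the circuit's transcription factors:
#' NLP6/NLP7 (`TGNCYYTT`), DREB26 (`YCRCCGHC`), ANAC032 via its close
#' relative ATAF1 (`KACGTR`), and the auxin response elements `TGTCTC`,
#' `TGTCGG` and the permissive `TGTCNN` used by the paired-site rule.
#'
#' @return Named list of [iupac_pattern()] objects.
#' @export
nitrate_motifs <- function() {
  list(NLP7    = iupac_pattern("NLP7", "TGNCYYTT"),
       NLP6    = iupac_pattern("NLP6", "TGNCYYTT"),
       DREB26  = iupac_pattern("DREB26", "YCRCCGHC"),
       ANAC032 = iupac_pattern("ANAC032", "KACGTR"),
       ARF_TGTCTC = iupac_pattern("ARF_TGTCTC", "TGTCTC"),
       ARF_TGTCGG = iupac_pattern("ARF_TGTCGG", "TGTCGG"),
       ARF_TGTCNN = iupac_pattern("ARF_TGTCNN", "TGTCNN"))
}
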