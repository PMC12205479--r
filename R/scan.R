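# FIMO-style occurrence scanning. A "window" is one motif-length stretch of
# the oriented region sequence on one strand; p-values for PWM windows come
# from the same integer score lattice as the dynamic-programming null
# distribution, so window p-values and the null are self-consistent.

empty_hits <- function() {
  data.frame(gene_id = character(), motif = character(), kind = character(),
             start = integer(), end = integer(), strand = character(),
             score = numeric(), p_value = numeric(), q_value = numeric(),
             chrom = character(), abs_start = integer(), abs_end = integer(),
             stringsAsFactors = FALSE)
}

region_fields <- function(region) {
  if (inherits(region, "promoter_region")) {
    list(gene_id = region$gene_id, seq = region$sequence,
         tss_index = region$tss_index, chrom = region$interval$chrom,
         gstart = region$interval$start, gend = region$interval$end,
         strand = region$strand)
  } else {
    s <- as.character(region)
    list(gene_id = "seq", seq = s, tss_index = 0L, chrom = NA_character_,
         gstart = 0L, gend = nchar(s), strand = "+")
  }
}

# oriented 0-based index -> absolute genomic coordinates of a k-long window
abs_coords <- function(rf, i0, k) {
  if (rf$strand == "+") {
    list(abs_start = rf$gstart + i0, abs_end = rf$gstart + i0 + k)
  } else {
    list(abs_start = rf$gend - i0 - k, abs_end = rf$gend - i0)
  }
}

# Score every window of `seq` (character) with integer log-odds `m_int`
# (4 x L). Returns integer scores; windows containing non-ACGT are NA.
score_windows_int <- function(seq, m_int) {
  L <- ncol(m_int)
  codes <- match(strsplit(seq, "")[[1]], DNA_BASES)
  n <- length(codes) - L + 1
  if (n < 1) return(integer(0))
  sc <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n - 1)]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    sc <- sc + m_int[cbind(cj, j)]
  }
  sc[!ok] <- NA
  sc
}

scan_pwm_full <- function(region, motif, p_cutoff, gran = 1e-4,
                          max_states = 4e6) {
  rf <- region_fields(region)
  lo <- log_odds(motif)
  L <- ncol(lo)
  out <- list(hits = empty_hits(), pvalues = numeric(0), n_windows = 0L)
  if (is.na(rf$seq) || nchar(rf$seq) < L) return(out)
  dist <- pwm_score_distribution(lo, motif$background, gran, max_states)
  if (is.null(dist)) {
    dist <- pwm_score_distribution(lo, motif$background, gran * 10, max_states)
  }
  surv <- lattice_survival(dist)
  lo_rc <- log_odds(reverse_complement_pwm(motif))
  m_rc_int <- round(lo_rc / dist$gran)
  hit_rows <- list()
  pvals <- numeric(0)
  for (strand in c("+", "-")) {
    m_int <- if (strand == "+") dist$m_int else m_rc_int
    sc <- score_windows_int(rf$seq, m_int)
    keep <- !is.na(sc)
    p <- rep(NA_real_, length(sc))
    p[keep] <- surv(sc[keep])
    pvals <- c(pvals, p[keep])
    sel <- which(keep & p <= p_cutoff)
    if (length(sel) > 0) {
      ac <- abs_coords(rf, sel - 1L, L)
      hit_rows[[strand]] <- data.frame(
        gene_id = rf$gene_id, motif = motif$name, kind = "pwm",
        start = (sel - 1L) - rf$tss_index,
        end = (sel - 1L) - rf$tss_index + L,
        strand = strand, score = sc[sel] * dist$gran, p_value = p[sel],
        q_value = NA_real_, chrom = rf$chrom,
        abs_start = ac$abs_start, abs_end = ac$abs_end,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows) > 0) do.call(rbind, hit_rows) else empty_hits()
  rownames(hits) <- NULL
  list(hits = hits, pvalues = pvals, n_windows = length(pvals))
}

scan_iupac_full <- function(region, motif) {
  rf <- region_fields(region)
  L <- motif$length
  out <- list(hits = empty_hits(), n_windows = 0L,
              p_match = iupac_match_prob(motif))
  if (is.na(rf$seq) || nchar(rf$seq) < L) return(out)
  subject <- Biostrings::DNAString(rf$seq)
  pat <- Biostrings::DNAString(motif$pattern)
  rows <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
    m <- Biostrings::matchPattern(p, subject, fixed = FALSE)
    # windows containing N in the subject must not match: re-filter, since
    # fixed=FALSE lets subject ambiguity codes satisfy the pattern
    starts <- Biostrings::start(m)
    if (length(starts) > 0) {
      words <- substring(rf$seq, starts, starts + L - 1)
      starts <- starts[!grepl("[^ACGT]", words)]
    }
    if (length(starts) > 0) {
      i0 <- starts - 1L
      ac <- abs_coords(rf, i0, L)
      rows[[strand]] <- data.frame(
        gene_id = rf$gene_id, motif = motif$name, kind = "iupac",
        start = i0 - rf$tss_index, end = i0 - rf$tss_index + L,
        strand = strand, score = -log10(out$p_match),
        p_value = out$p_match, q_value = NA_real_, chrom = rf$chrom,
        abs_start = ac$abs_start, abs_end = ac$abs_end,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows) > 0) do.call(rbind, rows) else empty_hits()
  rownames(hits) <- NULL
  n_win <- max(nchar(rf$seq) - L + 1L, 0L)
  list(hits = hits, n_windows = as.integer(2L * n_win),
       p_match = out$p_match)
}

#' Scan a promoter region for motif occurrences
#'
#' Both strands are scanned. For a [pwm_motif()], windows are scored with the
#' log-odds matrix and only windows with `p_value <= p_cutoff` are reported;
#' windows containing non-ACGT characters are skipped. For an
#' [iupac_pattern()], every exact degenerate match is reported as a candidate
#' site (the printed consensus rule) with the pattern's background match
#' probability as its p-value; `p_cutoff` is not applied to consensus
#' matches, since even a perfect match to a short degenerate consensus can
#' carry a p-value above typical PWM cutoffs.
#'
#' Hit coordinates are TSS-relative (negative upstream) when `region` is a
#' [extract_region()] result; for a plain character sequence, position 0 is
#' the first base.
#'
#' @param region A `promoter_region` or a character sequence over
#'   `{A,C,G,T,N}`.
#' @param motif A [pwm_motif()] or [iupac_pattern()].
#' @param p_cutoff Window p-value cutoff for PWM scanning (default 1e-4).
#' @param gran Score-lattice granularity for PWM p-values.
#' @return A hit data frame (columns `gene_id`, `motif`, `kind`, `start`,
#'   `end`, `strand`, `score` (nats for PWM hits), `p_value`, `q_value`,
#'   `chrom`, `abs_start`, `abs_end`). A motif longer than the region yields
#'   an empty result.
#' @export
scan_sequence <- function(region, motif, p_cutoff = 1e-4, gran = 1e-4) {
  if (inherits(motif, "pwm_motif")) {
    scan_pwm_full(region, motif, p_cutoff, gran)$hits
  } else if (inherits(motif, "iupac_pattern")) {
    scan_iupac_full(region, motif)$hits
  } else {
    stop("motif must be a pwm_motif or an iupac_pattern")
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up q-values via [stats::p.adjust()]. The family is whatever vector is
#' passed in; for motif scans that is all windows tested for one motif across
#' the scanned region set.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Pair nearby auxin-response TGTCNN occurrences
#'
#' Pairs of `TGTCNN` occurrences spaced less than `max_gap` bp apart (gap
#' measured from the end of the first hit to the start of the second, strict
#' inequality) are annotated as candidate composite ARF binding sites. Only
#' immediate neighbours in coordinate order are paired; any strand
#' combination pairs.
#'
#' @param hits Hit data frame from a single region (TGTCNN occurrences).
#' @param max_gap Maximum inter-motif gap in bp (exclusive; default 14).
#' @return Data frame of pairs with columns `gene_id`, `start1`, `end1`,
#'   `strand1`, `start2`, `end2`, `strand2`, `gap`.
#' @export
find_arf_pairs <- function(hits, max_gap = 14) {
  stopifnot(max_gap >= 0)
  out <- data.frame(gene_id = character(), start1 = integer(),
                    end1 = integer(), strand1 = character(),
                    start2 = integer(), end2 = integer(),
                    strand2 = character(), gap = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(hits) < 2) return(out)
  if (length(unique(hits$gene_id)) > 1) {
    stop("find_arf_pairs expects hits from a single region")
  }
  h <- hits[order(hits$start, hits$strand), , drop = FALSE]
  gaps <- h$start[-1] - h$end[-nrow(h)]
  sel <- which(gaps < max_gap)
  if (length(sel) == 0) return(out)
  data.frame(gene_id = h$gene_id[sel],
             start1 = h$start[sel], end1 = h$end[sel],
             strand1 = h$strand[sel],
             start2 = h$start[sel + 1], end2 = h$end[sel + 1],
             strand2 = h$strand[sel + 1], gap = gaps[sel],
             stringsAsFactors = FALSE)
}

#' Call candidate transcription-factor binding sites across regions
#'
#' Runs the full candidate-site pipeline: per-region scans of every motif,
#' Benjamini-Hochberg adjustment within each motif's scan batch (family =
#' all windows tested for that motif across the region set), the
#' high-confidence flag at `q <= q_cutoff`, open-chromatin annotation, and
#' the paired-TGTCNN composite ARF rule.
#'
#' PWM hits must pass `p_cutoff`; degenerate consensus (IUPAC) hits are
#' retained as candidate sites regardless of score, with their
#' high-confidence flag still determined by the q-value.
#'
#' @param regions List of `promoter_region` objects.
#' @param motif_set List of [pwm_motif()] / [iupac_pattern()] objects.
#' @param peaks Optional [merge_intervals()] peak set for open-chromatin
#'   flags.
#' @param p_cutoff PWM window p-value cutoff (default 1e-4).
#' @param q_cutoff q-value threshold for the high-confidence flag
#'   (default 0.05).
#' @param max_gap ARF pair rule gap (default 14; strict inequality).
#' @return List with `hits` (data frame sorted by region then position, with
#'   `q_value`, `high_confidence` and `in_open_chromatin` columns) and
#'   `arf_pairs` (composite-site data frame).
#' @export
call_candidate_sites <- function(regions, motif_set, peaks = NULL,
                                 p_cutoff = 1e-4, q_cutoff = 0.05,
                                 max_gap = 14) {
  if (!is.null(names(regions))) regions <- unname(regions)
  ok <- vapply(regions, function(r) !is.na(region_fields(r)$seq), logical(1))
  if (any(!ok)) {
    warning("skipping region(s) with no sequence: ",
            paste(vapply(regions[!ok], function(r) region_fields(r)$gene_id,
                         character(1)), collapse = ", "))
    regions <- regions[ok]
  }
  all_hits <- list()
  arf_pairs <- list()
  for (motif in motif_set) {
    if (inherits(motif, "pwm_motif")) {
      scans <- lapply(regions, scan_pwm_full, motif = motif,
                      p_cutoff = p_cutoff)
      pvals <- unlist(lapply(scans, `[[`, "pvalues"))
      hits <- do.call(rbind, lapply(scans, `[[`, "hits"))
      if (nrow(hits) > 0) {
        # q-values over the full window family: reported hits have the
        # smallest p-values, so their BH ranks are their ranks among all
        # tested windows
        q_all <- bh_adjust(pvals)
        hits$q_value <- q_all[match(hits$p_value, pvals)]
      }
    } else {
      scans <- lapply(regions, scan_iupac_full, motif = motif)
      hits <- do.call(rbind, lapply(scans, `[[`, "hits"))
      m <- sum(vapply(scans, `[[`, integer(1), "n_windows"))
      if (nrow(hits) > 0) {
        # analytic BH: k matches share p0, remaining windows are non-matches
        hits$q_value <- pmin(1, hits$p_value * m / nrow(hits))
      }
    }
    all_hits[[motif$name]] <- hits
    if (identical(toupper(if (inherits(motif, "iupac_pattern"))
                          motif$pattern else ""), "TGTCNN")) {
      for (h in split(hits, hits$gene_id)) {
        pr <- find_arf_pairs(h, max_gap = max_gap)
        if (nrow(pr) > 0) arf_pairs[[length(arf_pairs) + 1]] <- pr
      }
    }
  }
  hits <- do.call(rbind, all_hits)
  if (is.null(hits)) hits <- empty_hits()
  rownames(hits) <- NULL
  hits$high_confidence <- !is.na(hits$q_value) & hits$q_value <= q_cutoff
  if (!is.null(peaks)) {
    hits <- annotate_open_chromatin(hits, peaks)
  } else {
    hits$in_open_chromatin <- rep(FALSE, nrow(hits))
  }
  hits <- hits[order(hits$gene_id, hits$start, hits$motif), , drop = FALSE]
  rownames(hits) <- NULL
  arf_pairs <- if (length(arf_pairs) > 0) do.call(rbind, arf_pairs) else
    find_arf_pairs(empty_hits())
  rownames(arf_pairs) <- NULL
  list(hits = hits, arf_pairs = arf_pairs)
}

#' Write motif hits to TSV or BED6
#'
#' BED6 output uses absolute 0-based half-open coordinates with the score
#' column set to `-log10(p)`.
#'
#' @param hits Hit data frame from [call_candidate_sites()] or
#'   [scan_sequence()].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = hits$chrom, start = hits$abs_start,
                      end = hits$abs_end,
                      name = paste(hits$motif, hits$gene_id, sep = "|"),
                      score = round(-log10(hits$p_value), 3),
                      strand = hits$strand)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
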