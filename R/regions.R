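# Internal coordinate convention: 0-based, half-open [start, end), as in BED.
# GFF-like (1-based, inclusive) input is converted on ingest.

#' Construct a genomic interval
#'
#' Intervals are 0-based and half-open (`[start, end)`), the convention used
#' throughout the package and shared with the BED format.
#'
#' @param chrom Sequence identifier.
#' @param start 0-based start position.
#' @param end End position (exclusive); must be greater than `start`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A one-row `data.frame` with class `genomic_interval` columns
#'   `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(length(start) == length(end))
  chrom <- rep_len(as.character(chrom), length(start))
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval must satisfy start < end")
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  out <- data.frame(chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    strand = rep_len(as.character(strand), length(chrom)),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", class(out))
  out
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param tss Transcription start site (0-based position of the first
#'   transcribed base). When a gene has several transcripts, use the earliest
#'   annotated TSS, i.e. the transcript start most distal in the direction of
#'   transcription.
#' @param span_start,span_end Transcript span, 0-based half-open.
#' @return A `gene_model` list.
#' @export
gene_model <- function(gene_id, chrom, strand, tss, span_start, span_end) {
  stopifnot(strand %in% c("+", "-"))
  if (span_end <= span_start) stop("transcript span must satisfy start < end")
  if (tss < span_start || tss > span_end) {
    stop("TSS must lie within or at the boundary of the transcript span")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tss = as.integer(tss),
                 span = genomic_interval(chrom, span_start, span_end, strand)),
            class = "gene_model")
}

#' Read gene models from a GFF3-like annotation file
#'
#' Gene features (1-based, inclusive coordinates) are converted to the
#' internal 0-based half-open convention. The earliest annotated TSS is taken
#' as the transcript start most distal in the direction of transcription.
#'
#' @param path Path to a GFF3 file containing `gene` (or `mRNA`) features
#'   with an `ID` attribute.
#' @return A list of [gene_model()] objects, named by gene id.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "mRNA", "transcript")
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  out <- lapply(seq_along(gr), function(i) {
    st <- as.character(GenomicRanges::strand(gr[i]))
    s0 <- GenomicRanges::start(gr[i]) - 1L   # to 0-based
    e0 <- GenomicRanges::end(gr[i])          # half-open
    tss <- if (st == "+") s0 else e0 - 1L
    gene_model(ids[i], as.character(GenomicRanges::seqnames(gr[i])),
               st, tss, s0, e0)
  })
  names(out) <- ids
  out
}

as_iranges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

#' Extract a TSS-anchored promoter region
#'
#' Returns the window `upstream_len` bases upstream to `downstream_len` bases
#' downstream of the gene's TSS, in strand-aware orientation. The window is
#' clipped at chromosome bounds and truncated where it overlaps the transcript
#' of another protein-coding gene. Minus-strand regions are returned
#' reverse-complemented so the sequence reads 5' to 3' relative to the gene.
#'
#' TSS-relative coordinates are negative upstream and positive downstream;
#' `tss_offset` maps absolute genomic positions onto this axis and satisfies
#' `tss_offset(tss) == 0`.
#'
#' @param gene A [gene_model()].
#' @param upstream_len,downstream_len Window extents in bp (non-negative).
#' @param neighbors List of [gene_model()] for neighboring protein-coding
#'   genes (the gene itself is ignored if present).
#' @param genome Optional named `Biostrings::DNAStringSet` (or named character
#'   vector) with chromosome sequences; when supplied the region sequence is
#'   extracted, otherwise `sequence` is `NA`.
#' @param chrom_length Optional chromosome length for bounds clipping;
#'   inferred from `genome` when available.
#' @return A `promoter_region` list with elements `gene_id`, `interval`,
#'   `strand`, `tss`, `sequence`, `tss_index` (0-based index of the TSS base
#'   in the oriented sequence) and `tss_offset` (a function).
#' @export
extract_region <- function(gene, upstream_len, downstream_len,
                           neighbors = list(), genome = NULL,
                           chrom_length = NULL) {
  stopifnot(inherits(gene, "gene_model"),
            upstream_len >= 0, downstream_len >= 0)
  tss <- gene$tss
  if (!is.null(genome) && is.null(chrom_length)) {
    if (gene$chrom %in% names(genome)) {
      chrom_length <- length(Biostrings::DNAString(as.character(
        genome[[gene$chrom]])))
    }
  }
  if (!is.null(chrom_length) && (tss < 0 || tss >= chrom_length)) {
    stop("TSS of ", gene$gene_id, " lies outside chromosome bounds")
  }
  if (gene$strand == "+") {
    s <- tss - upstream_len; e <- tss + downstream_len
  } else {
    s <- tss - downstream_len; e <- tss + upstream_len
  }
  s <- max(s, 0L)
  if (!is.null(chrom_length)) e <- min(e, chrom_length)
  # truncate at overlapping neighbor transcripts, keeping the TSS
  for (nb in neighbors) {
    if (identical(nb$gene_id, gene$gene_id) ||
        !identical(nb$chrom, gene$chrom)) next
    ns <- nb$span$start; ne <- nb$span$end
    if (ne <= s || ns >= e) next               # no overlap with window
    if (ne <= tss) s <- max(s, ne)             # neighbor on the low side
    else if (ns > tss) e <- min(e, ns)         # neighbor on the high side
    else stop("neighbor transcript ", nb$gene_id, " spans the TSS of ",
              gene$gene_id, "; cannot extract a promoter window")
  }
  if (e <= s) {
    stop("promoter window for ", gene$gene_id,
         " is empty after clipping/truncation (window [", s, ", ", e, "))")
  }
  seq <- NA_character_
  if (!is.null(genome) && gene$chrom %in% names(genome)) {
    chrseq <- Biostrings::DNAString(as.character(genome[[gene$chrom]]))
    seq <- as.character(Biostrings::subseq(chrseq, start = s + 1L, end = e))
    if (gene$strand == "-") {
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    }
  }
  # oriented index of the TSS base within [s, e)
  tss_index <- if (gene$strand == "+") tss - s else (e - 1L) - tss
  offset_fun <- if (gene$strand == "+") {
    function(pos) pos - tss
  } else {
    function(pos) tss - pos
  }
  structure(list(gene_id = gene$gene_id,
                 interval = genomic_interval(gene$chrom, s, e, gene$strand),
                 strand = gene$strand, tss = tss, sequence = seq,
                 tss_index = as.integer(tss_index), tss_offset = offset_fun),
            class = "promoter_region")
}

#' @export
print.promoter_region <- function(x, ...) {
  cat(sprintf("promoter_region %s %s:[%d,%d) strand %s, TSS %d, %s bp\n",
              x$gene_id, x$interval$chrom, x$interval$start, x$interval$end,
              x$strand, x$tss, x$interval$end - x$interval$start))
  invisible(x)
}

#' Length of the oriented promoter sequence
#' @param region A `promoter_region`.
#' @return Integer length in bp.
#' @export
region_length <- function(region) {
  region$interval$end - region$interval$start
}

#' Merge overlapping and abutting intervals into a peak set
#'
#' Overlapping and bookended (gap = 0) intervals are combined; intervals
#' separated by one or more bases are kept apart, matching the conventional
#' behaviour of interval-merge tools. Output is sorted and pairwise
#' non-overlapping.
#'
#' @param intervals A `genomic_interval` data frame (any number of rows).
#' @param tissue_label Free-text label carried on the peak set (e.g. "root").
#' @return A `peak_set`: a `genomic_interval` data frame with attribute
#'   `tissue_label`.
#' @export
merge_intervals <- function(intervals, tissue_label = "") {
  if (nrow(intervals) == 0) {
    out <- intervals
  } else {
    if (any(intervals$end <= intervals$start)) {
      stop("negative- or zero-length interval in input")
    }
    parts <- split(intervals, intervals$chrom)
    merged <- lapply(names(parts), function(ch) {
      ir <- IRanges::reduce(as_iranges(parts[[ch]]))  # merges abutting runs
      genomic_interval(ch, IRanges::start(ir) - 1L, IRanges::end(ir), ".")
    })
    out <- do.call(rbind, merged)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "tissue_label") <- tissue_label
  class(out) <- unique(c("peak_set", "genomic_interval", class(out)))
  out
}

#' Flag motif hits that fall in open chromatin
#'
#' Each hit gains `in_open_chromatin = TRUE` iff it overlaps a peak by at
#' least 1 bp under the half-open convention. Hits on chromosomes absent from
#' the peak set are flagged `FALSE` with a warning. The hit count is
#' unchanged.
#'
#' @param hits A data frame of hits with columns `chrom`, `abs_start`,
#'   `abs_end` (absolute 0-based half-open coordinates).
#' @param peaks A [merge_intervals()] peak set.
#' @return `hits` with a logical `in_open_chromatin` column.
#' @export
annotate_open_chromatin <- function(hits, peaks) {
  flag <- rep(FALSE, nrow(hits))
  if (nrow(hits) > 0 && nrow(peaks) > 0) {
    missing_chrom <- !(hits$chrom %in% peaks$chrom)
    if (any(missing_chrom)) {
      warning("hits on chromosome(s) absent from the peak set flagged FALSE: ",
              paste(unique(hits$chrom[missing_chrom]), collapse = ", "))
    }
    for (ch in intersect(unique(hits$chrom), unique(peaks$chrom))) {
      hi <- which(hits$chrom == ch)
      hir <- IRanges::IRanges(hits$abs_start[hi] + 1L, hits$abs_end[hi])
      pir <- as_iranges(peaks[peaks$chrom == ch, , drop = FALSE])
      flag[hi] <- IRanges::overlapsAny(hir, pir)
    }
  }
  hits$in_open_chromatin <- flag
  hits
}

#' Read a BED file of peaks
#'
#' BED is 0-based half-open, matching the internal convention.
#'
#' @param path BED3/BED6 file path.
#' @param tissue_label Label stored on the resulting peak set.
#' @return A merged [merge_intervals()] peak set.
#' @export
read_bed <- function(path, tissue_label = "") {
  gr <- rtracklayer::import(path, format = "bed")
  iv <- genomic_interval(as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr) - 1L,
                         GenomicRanges::end(gr),
                         ".")
  merge_intervals(iv, tissue_label = tissue_label)
}

#' Write intervals to a BED file
#'
#' @param intervals A `genomic_interval` data frame (e.g. a peak set).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(intervals$start + 1L, intervals$end),
    strand = ifelse(intervals$strand == ".", "*", intervals$strand))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Species presets for promoter-region extents
#'
#' Region extents used for each species: Arabidopsis (`At`) 2000 bp upstream /
#' 1000 bp downstream of the TSS; tomato (`Sl`) 5000 bp upstream / 2000 bp
#' downstream.
#'
#' @param species `"At"` or `"Sl"`.
#' @return List with `upstream_len` and `downstream_len`.
#' @export
species_preset <- function(species = c("At", "Sl")) {
  species <- match.arg(species)
  switch(species,
         At = list(upstream_len = 2000L, downstream_len = 1000L),
         Sl = list(upstream_len = 5000L, downstream_len = 2000L))
}
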