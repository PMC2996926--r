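#' Remove repetitive query sequences from a hit table
#'
#' Queries (BAC-end sequences or probe source sequences) with 10 or more
#' hits on the comparator genome are considered repetitive and removed
#' entirely.
#'
#' @param hits Data.frame with `query_id`, `target_chrom`, `target_pos`.
#' @param max_hits Maximum allowed hits per query (default 9).
#' @return The filtered hit table.
#' @export
filter_repetitive_queries <- function(hits, max_hits = 9L) {
  if (!nrow(hits)) return(hits)
  tal <- table(hits$query_id)
  keep <- hits$query_id %in% names(tal)[tal <= max_hits]
  hits[keep, , drop = FALSE]
}

#' Anchor contigs onto a comparator genome
#'
#' Per contig and chromosome, hit positions are chained by 1-D single
#' linkage: consecutive positions strictly less than `window` apart join
#' one chain. Chains supported by two or more distinct query sequences
#' become anchors spanning `[min pos, max pos]`. A contig may anchor
#' several regions and several chromosomes.
#'
#' @param hits Filtered hit table (`query_id`, `target_chrom`,
#'   `target_pos`).
#' @param query_contig Data.frame mapping `query_id` to `contig_id`.
#' @param window Chaining window in bp (200 kb against a compact genome,
#'   1 Mb against a sparser one, per the anchoring protocol).
#' @return Data.frame of anchors: `contig_id`, `target_chrom`, `start`,
#'   `end`, `n_queries`, `queries` (comma-joined).
#' @export
anchor_to_genome <- function(hits, query_contig, window) {
  if (!is.numeric(window) || window <= 0) stop("window must be positive")
  empty <- data.frame(contig_id = integer(0), target_chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_queries = integer(0), queries = character(0))
  if (!nrow(hits)) return(empty)
  hits <- merge(hits, query_contig, by = "query_id")
  if (!nrow(hits)) return(empty)
  hits <- hits[order(hits$contig_id, hits$target_chrom, hits$target_pos), ]
  out <- list()
  for (key in split(seq_len(nrow(hits)),
                    list(hits$contig_id, hits$target_chrom), drop = TRUE)) {
    h <- hits[key, , drop = FALSE]
    gaps <- diff(h$target_pos)
    chain <- cumsum(c(0, gaps >= window))
    for (ch in split(seq_len(nrow(h)), chain)) {
      q <- unique(h$query_id[ch])
      if (length(q) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        contig_id = h$contig_id[ch[1]], target_chrom = h$target_chrom[ch[1]],
        start = min(h$target_pos[ch]), end = max(h$target_pos[ch]),
        n_queries = length(q), queries = paste(sort(q), collapse = ","))
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$target_chrom, res$start, res$contig_id), ]
  rownames(res) <- NULL
  res
}

#' Fraction of a genome covered by anchors
#'
#' Anchor intervals are unioned per chromosome (overlaps counted once) and
#' the summed span is divided by the total genome length.
#'
#' @param anchors Anchor table from [anchor_to_genome()].
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @return Covered fraction in `[0, 1]`.
#' @export
anchor_coverage <- function(anchors, chrom_lengths) {
  total <- sum(chrom_lengths)
  if (!nrow(anchors)) return(0)
  covered <- 0
  for (chrom in unique(anchors$target_chrom)) {
    a <- anchors[anchors$target_chrom == chrom, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = round(a$start),
                                           end = round(a$end)))
    covered <- covered + sum(IRanges::end(ir) - IRanges::start(ir))
  }
  covered / total
}

#' Gene-density track in fixed-width bins
#'
#' Counts genes per bin along each chromosome; a gene is assigned to the
#' bin containing its start coordinate, so counts are conserved.
#'
#' @param genes Data.frame with `chrom`, `start` (0-based bp).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param bin Bin width in bp (default 200 kb).
#' @return Data.frame with `chrom`, `bin_index` (0-based), `bin_start`,
#'   `count`; the last bin of a chromosome may be partial.
#' @export
gene_density <- function(genes, chrom_lengths, bin = 200000) {
  rows <- lapply(names(chrom_lengths), function(chrom) {
    n_bins <- max(1L, as.integer(ceiling(chrom_lengths[[chrom]] / bin)))
    idx <- 0:(n_bins - 1L)
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    counts <- tabulate(pmin(floor(g$start / bin), n_bins - 1L) + 1L, n_bins)
    data.frame(chrom = chrom, bin_index = idx, bin_start = idx * bin,
               count = counts)
  })
  do.call(rbind, rows)
}

#' Gene-density enrichment of anchored regions
#'
#' A bin is covered when any anchor overlaps it. Reports mean gene density
#' of covered versus uncovered bins, the fraction of the top
#' `top_fraction` highest-density bins that are covered, and the overall
#' covered bin fraction (ties in density broken by chromosome and bin
#' order).
#'
#' @param anchors Anchor table from [anchor_to_genome()].
#' @param track Density track from [gene_density()].
#' @param bin Bin width used to build the track.
#' @param top_fraction Fraction of bins counted as high-density
#'   (default 0.30).
#' @return List with `mean_density_covered`, `mean_density_uncovered`,
#'   `top_covered_fraction`, `overall_covered_fraction`.
#' @export
density_enrichment <- function(anchors, track, bin = 200000,
                               top_fraction = 0.30) {
  covered <- logical(nrow(track))
  if (nrow(anchors)) {
    for (chrom in unique(anchors$target_chrom)) {
      sel <- track$chrom == chrom
      if (!any(sel)) next
      a <- anchors[anchors$target_chrom == chrom, , drop = FALSE]
      bins <- IRanges::IRanges(start = track$bin_start[sel] + 1,
                               width = bin)
      ai <- IRanges::IRanges(start = round(a$start) + 1,
                             end = pmax(round(a$end), round(a$start) + 1))
      covered[sel] <- IRanges::overlapsAny(bins, ai)
    }
  }
  ord <- order(-track$count, track$chrom, track$bin_index)
  n_top <- ceiling(top_fraction * nrow(track))
  top <- ord[seq_len(n_top)]
  list(mean_density_covered = if (any(covered)) mean(track$count[covered])
       else 0,
       mean_density_uncovered = if (any(!covered)) mean(track$count[!covered])
       else 0,
       top_covered_fraction = mean(covered[top]),
       overall_covered_fraction = mean(covered))
}

#' Genome coverage implied by contig CB lengths
#'
#' Sums consensus-band lengths over contigs, converts to bp with the
#' average band size, and divides by the genome size.
#'
#' @param assembly An `fp_assembly` object (or list of contigs).
#' @param genome_bp Genome size in bp.
#' @param avg_band_bp Average band size in bp (default 4097, the
#'   all-fingerprint average; the Lander-Waterman calculator uses 4096).
#' @return Estimated covered fraction.
#' @export
cb_coverage <- function(assembly, genome_bp, avg_band_bp = 4097) {
  contigs <- if (inherits(assembly, "fp_assembly")) assembly$contigs
  else assembly
  if (!length(contigs)) return(0)
  sum(vapply(contigs, `[[`, numeric(1), "cb_length")) * avg_band_bp /
    genome_bp
}
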