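#' Filter probe-BAC hybridization evidence for anchoring
#'
#' Removes repetitive probes (total hits of 30 or more by default) and
#' promiscuous BACs (8 or more distinct probes by default, suspected
#' hybridization artifacts). Filtering is sequential: probe tallies are
#' computed on the input matrix, BAC tallies on the probe-filtered matrix
#' (so blanket repetitive probes do not drag every BAC over the cap).
#'
#' @param pairs Data.frame with `probe_id`, `bac_id` (one row per hit).
#' @param probe_max Maximum allowed hits per probe (default 29; probes with
#'   `hits > probe_max` are removed).
#' @param bac_max Maximum allowed distinct probes per BAC (default 7).
#' @return List with `pairs` (filtered), `probe_tally`, `bac_tally`,
#'   `removed_probes`, `removed_bacs`.
#' @export
filter_hybridization <- function(pairs, probe_max = 29L, bac_max = 7L) {
  pairs <- unique(pairs[c("probe_id", "bac_id")])
  probe_tally <- table(pairs$probe_id)
  removed_probes <- names(probe_tally)[probe_tally > probe_max]
  kept <- pairs[!(pairs$probe_id %in% removed_probes), , drop = FALSE]
  bac_tally <- table(kept$bac_id)
  removed_bacs <- names(bac_tally)[bac_tally > bac_max]
  keep <- !(pairs$probe_id %in% removed_probes) &
    !(pairs$bac_id %in% removed_bacs)
  list(pairs = pairs[keep, , drop = FALSE],
       probe_tally = probe_tally, bac_tally = bac_tally,
       removed_probes = removed_probes, removed_bacs = removed_bacs)
}

## clone -> contig id lookup for an assembly (buried clones included).
.clone_contig_map <- function(assembly) {
  maps <- lapply(assembly$contigs, function(ct)
    stats::setNames(rep(ct$contig_id, length(ct$members)), ct$members))
  if (!length(maps)) return(integer(0))
  do.call(c, maps)
}

#' Anchor contigs onto a genetic map
#'
#' Joins filtered probe-BAC pairs to contig membership. For every
#' (marker, contig) combination the number of distinct supporting member
#' BACs is counted; records supported by a single BAC-probe pair are
#' flagged weak and are not used for map placement. Only markers present
#' on the map produce records; hits to singleton BACs are reported
#' separately.
#'
#' @param assembly An `fp_assembly` object.
#' @param pairs Filtered hybridization pairs (`probe_id`, `bac_id`), e.g.
#'   `filter_hybridization(...)$pairs`.
#' @param map Genetic map data.frame (`marker_id`, `group`, `cM`).
#' @return Data.frame of anchor records (`contig_id`, `marker_id`, `group`,
#'   `cM`, `supporting_bacs`, `weak`) with attribute `singleton_pairs`
#'   (probe hits to BACs outside contigs).
#' @export
anchor_contigs <- function(assembly, pairs, map) {
  stopifnot(inherits(assembly, "fp_assembly"))
  cmap <- .clone_contig_map(assembly)
  on_map <- pairs$probe_id %in% map$marker_id
  pairs <- pairs[on_map, , drop = FALSE]
  in_contig <- pairs$bac_id %in% names(cmap)
  singleton_pairs <- pairs[!in_contig, , drop = FALSE]
  pairs <- pairs[in_contig, , drop = FALSE]
  if (!nrow(pairs)) {
    rec <- data.frame(contig_id = integer(0), marker_id = character(0),
                      group = integer(0), cM = numeric(0),
                      supporting_bacs = integer(0), weak = logical(0))
    attr(rec, "singleton_pairs") <- singleton_pairs
    return(rec)
  }
  pairs$contig_id <- unname(cmap[pairs$bac_id])
  pairs$marker_id <- pairs$probe_id
  agg <- stats::aggregate(bac_id ~ marker_id + contig_id, data = pairs,
                          FUN = function(x) length(unique(x)))
  names(agg)[names(agg) == "bac_id"] <- "supporting_bacs"
  mi <- match(agg$marker_id, map$marker_id)
  rec <- data.frame(contig_id = agg$contig_id, marker_id = agg$marker_id,
                    group = map$group[mi], cM = map$cM[mi],
                    supporting_bacs = agg$supporting_bacs,
                    weak = agg$supporting_bacs == 1L)
  rec <- rec[order(rec$group, rec$cM, rec$contig_id, rec$marker_id), ]
  rownames(rec) <- NULL
  attr(rec, "singleton_pairs") <- singleton_pairs
  rec
}

#' Summarise anchoring per linkage group
#'
#' One row per homologous group: map loci, distinct markers producing at
#' least one non-weak anchor, anchored contig records (with multiplicity, a
#' contig counts once per anchoring marker) and the average contigs
#' anchored per anchoring marker.
#'
#' @param records Anchor records from [anchor_contigs()].
#' @param map Genetic map data.frame.
#' @return Data.frame with `group`, `n_loci`, `anchoring_markers`,
#'   `anchored_contigs`, `unique_contigs`, `contigs_per_marker`.
#' @export
anchor_summary <- function(records, map) {
  strong <- records[!records$weak, , drop = FALSE]
  groups <- sort(unique(map$group))
  rows <- lapply(groups, function(g) {
    r <- strong[strong$group == g, , drop = FALSE]
    nm <- length(unique(r$marker_id))
    data.frame(group = g,
               n_loci = sum(map$group == g),
               anchoring_markers = nm,
               anchored_contigs = nrow(r),
               unique_contigs = length(unique(r$contig_id)),
               contigs_per_marker = if (nm) nrow(r) / nm else NA_real_)
  })
  out <- do.call(rbind, rows)
  out[out$anchoring_markers > 0 | out$n_loci > 0, , drop = FALSE]
}

#' Classify contigs by probe repetitiveness content
#'
#' `REPEAT_ONLY` when all probes hitting the contig are moderately or
#' highly repetitive, `LOWCOPY_ENRICHED` when strictly more than 60% of its
#' probes are low copy, `MIXED` otherwise, `UNPROBED` when no probe hits.
#'
#' @param assembly An `fp_assembly` object.
#' @param pairs Hybridization pairs (`probe_id`, `bac_id`).
#' @param probe_classes Data.frame with `probe_id` and `class` (as from
#'   [classify_probe()], e.g. `cbind(probe_id, classify_probe(hits))`).
#' @param low_fraction Enrichment threshold (default 0.60, strict).
#' @return Data.frame with `contig_id`, `n_probes`, `low_fraction`,
#'   `class`.
#' @export
classify_contigs <- function(assembly, pairs, probe_classes,
                             low_fraction = 0.60) {
  stopifnot(inherits(assembly, "fp_assembly"))
  cmap <- .clone_contig_map(assembly)
  pairs <- pairs[pairs$bac_id %in% names(cmap), , drop = FALSE]
  pairs$contig_id <- unname(cmap[pairs$bac_id])
  cls <- stats::setNames(probe_classes$class, probe_classes$probe_id)
  ids <- vapply(assembly$contigs, `[[`, integer(1), "contig_id")
  rows <- lapply(ids, function(cid) {
    probes <- unique(pairs$probe_id[pairs$contig_id == cid])
    probes <- probes[probes %in% names(cls)]
    if (!length(probes))
      return(data.frame(contig_id = cid, n_probes = 0L,
                        low_fraction = NA_real_, class = "UNPROBED"))
    frac <- mean(cls[probes] == "LOW")
    klass <- if (frac == 0) "REPEAT_ONLY"
    else if (frac > low_fraction) "LOWCOPY_ENRICHED"
    else "MIXED"
    data.frame(contig_id = cid, n_probes = length(probes),
               low_fraction = frac, class = klass)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig_id = integer(0), n_probes = integer(0),
                      low_fraction = numeric(0), class = character(0))
  out
}

#' Flag organelle (e.g. chloroplast) contigs
#'
#' A contig is flagged when at least `min_evidence` of its member-derived
#' sequences (BAC-end sequences or probe source sequences) match an
#' organelle reference in the supplied hit table.
#'
#' @param assembly An `fp_assembly` object.
#' @param organelle_hits Data.frame with `clone_id` (the contig member the
#'   sequence derives from) and `seq_id` (the matching sequence).
#' @param min_evidence Minimum distinct matching sequences (default 2).
#' @return Integer vector of flagged contig ids.
#' @export
flag_organelle <- function(assembly, organelle_hits, min_evidence = 2L) {
  stopifnot(inherits(assembly, "fp_assembly"))
  if (!nrow(organelle_hits)) return(integer(0))
  cmap <- .clone_contig_map(assembly)
  hits <- organelle_hits[organelle_hits$clone_id %in% names(cmap), ,
                         drop = FALSE]
  if (!nrow(hits)) return(integer(0))
  hits$contig_id <- unname(cmap[hits$clone_id])
  tal <- tapply(hits$seq_id, hits$contig_id, function(x) length(unique(x)))
  sort(as.integer(names(tal)[tal >= min_evidence]))
}
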