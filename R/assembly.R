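## ---- internal helpers ------------------------------------------------

.bands_of <- function(profiles) lapply(profiles, `[[`, "bands")

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

## Shared-evidence counts per clone pair: named vector key -> count.
.marker_pair_counts <- function(marker_sets, valid_ids) {
  keys <- character(0)
  for (cl in marker_sets) {
    cl <- sort(intersect(cl, valid_ids))
    if (length(cl) < 2L) next
    cmb <- utils::combn(cl, 2L)
    keys <- c(keys, .pair_key(cmb[1, ], cmb[2, ]))
  }
  if (!length(keys)) return(integer(0))
  tb <- table(keys)
  stats::setNames(as.integer(tb), names(tb))
}

## Evidence data.frame (marker_id, kind, clone_id) -> list of clone sets.
.marker_sets <- function(evidence, max_hits = Inf, kinds = c("PROBE", "HICF_CONTIG")) {
  if (is.null(evidence) || !nrow(evidence)) return(list())
  evidence <- unique(evidence[evidence$kind %in% kinds,
                              c("marker_id", "kind", "clone_id")])
  sets <- split(evidence$clone_id, evidence$marker_id)
  kind <- vapply(split(evidence$kind, evidence$marker_id), `[[`, "", 1L)
  keep <- kind == "HICF_CONTIG" | lengths(sets) <= max_hits
  sets[keep]
}

## Smallest matching-band count any pair in the set could need at the most
## relaxed cutoff; used to prune the all-pairs scan.
.global_min_match <- function(n_bands, params, cutoff) {
  ns <- sort(unique(n_bands[n_bands >= 2L]))
  if (!length(ns)) return(NA_integer_)
  n_hi <- max(ns)
  for (n_lo in ns) {
    t <- .min_match_threshold2(n_lo, n_hi, params, cutoff)
    if (!is.na(t)) return(t)
  }
  NA_integer_
}

## ---- CB map ----------------------------------------------------------

#' Build the consensus-band (CB) map of a contig
#'
#' Greedy seeded layout: the best-scoring clone pair seeds the consensus;
#' remaining clones are inserted in order of most matches to the current
#' consensus, each contributing its unmatched bands. A clone is flagged Q
#' when fewer than half of its bands align to its best-supporting fellow
#' member (an order-independent reading of the "poor CB fit" rule: the
#' multiset consensus eventually absorbs every band, so the fit of a clone
#' is judged against the member that supports it best — high-band-count
#' bridge clones joining two unrelated groups align well under 50% and are
#' flagged). CB offsets are shortest-path distances (edge weight = mean
#' unshared bands) from one extreme clone, so offsets order the clones
#' along the contig.
#'
#' @param members Clone ids of the contig.
#' @param profiles Named list of [band_profile()] objects.
#' @param params A [score_params()] object.
#' @return List with `offsets` (named, CB units), `cb_length`, `q_clones`,
#'   `consensus` (band values). `cb_length` always lies between the
#'   largest member band count and the summed band counts.
#' @export
build_cb_map <- function(members, profiles, params) {
  stopifnot(length(members) >= 1L)
  members <- sort(members)
  bands <- .bands_of(profiles[members])
  n <- lengths(bands)
  if (length(members) == 1L)
    return(list(offsets = stats::setNames(0, members),
                cb_length = n[[1]], q_clones = character(0),
                consensus = bands[[1]]))

  ap <- cpp_all_pairs(bands, params$tolerance, params$channel_span, 0L)
  mmat <- matrix(0L, length(members), length(members))
  if (nrow(ap)) {
    mmat[cbind(ap$i, ap$j)] <- ap$m
    mmat[cbind(ap$j, ap$i)] <- ap$m
  }

  # seed: best-scoring pair, ties to lexicographically smallest ids
  best <- which(mmat == max(mmat), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  seed <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  placed <- c(seed[[1]], seed[[2]])
  mp <- cpp_match_pairs(bands[[seed[[1]]]], bands[[seed[[2]]]],
                        params$tolerance, params$channel_span)
  un2 <- setdiff(seq_along(bands[[seed[[2]]]]), mp[, 2])
  consensus <- sort(unique(c(bands[[seed[[1]]]], bands[[seed[[2]]]][un2])))

  while (length(placed) < length(members)) {
    rest <- setdiff(seq_along(members), placed)
    mc <- cpp_match_many(consensus, bands[rest], params$tolerance,
                         params$channel_span)
    pick <- rest[order(-mc, rest)][1]
    mp <- cpp_match_pairs(consensus, bands[[pick]], params$tolerance,
                          params$channel_span)
    un <- setdiff(seq_along(bands[[pick]]), mp[, 2])
    consensus <- sort(unique(c(consensus, bands[[pick]][un])))
    placed <- c(placed, pick)
  }
  # Q: best pairwise support below half the clone's bands
  best_m <- apply(mmat, 1, max)
  q <- ifelse(n > 0, best_m / n, 0) < 0.5

  # offsets from a weighted layout graph over matching pairs
  w <- numeric(0); ei <- integer(0); ej <- integer(0)
  if (nrow(ap)) {
    ei <- ap$i; ej <- ap$j
    w <- pmax(0, (n[ei] + n[ej]) / 2 - ap$m)
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(as.character(seq_along(members)))
  if (length(ei))
    g <- igraph::add_edges(g, rbind(as.character(ei), as.character(ej)),
                           weight = w)
  offsets <- rep(NA_real_, length(members))
  compm <- igraph::components(g)$membership
  shift <- 0
  for (cmp in sort(unique(compm))) {
    vs <- which(compm == cmp)
    d0 <- igraph::distances(g, v = as.character(vs[1]),
                            to = as.character(vs))[1, ]
    far <- vs[order(-d0, vs)][1]
    d <- igraph::distances(g, v = as.character(far),
                           to = as.character(vs))[1, ]
    offsets[vs] <- shift + d
    shift <- max(offsets[vs]) + 10
  }
  list(offsets = stats::setNames(offsets, members),
       cb_length = length(consensus),
       q_clones = members[q], consensus = consensus)
}

## Construct an fp_contig from members.
.make_contig <- function(id, members, profiles, params, per_end = 2L,
                         buried = stats::setNames(character(0), character(0))) {
  cb <- build_cb_map(members, profiles, params)
  ct <- list(contig_id = id, members = sort(members), offsets = cb$offsets,
             cb_length = cb$cb_length, q_clones = cb$q_clones,
             consensus = cb$consensus, buried = buried,
             terminal = list())
  ct$terminal <- .contig_terminals(ct, per_end)
  class(ct) <- "fp_contig"
  ct
}

## Terminal clones per end (unburied, extreme CB offsets).
.contig_terminals <- function(contig, per_end = 2L) {
  un <- setdiff(contig$members, names(contig$buried))
  un <- un[order(contig$offsets[un], un)]
  list(left = utils::head(un, per_end), right = utils::tail(un, per_end))
}

#' @export
print.fp_contig <- function(x, ...) {
  cat(sprintf("<fp_contig> Ctg%d: %d clones, CB length %d, %d Q\n",
              x$contig_id, length(x$members), x$cb_length,
              length(x$q_clones)))
  invisible(x)
}

## Assemble an fp_assembly object from contig member lists.
.as_assembly <- function(stage, contig_members, all_ids, profiles, params,
                         provenance = list(), excluded = character()) {
  contig_members <- contig_members[order(vapply(contig_members, min, ""))]
  contigs <- lapply(seq_along(contig_members), function(k)
    .make_contig(k, contig_members[[k]], profiles, params))
  in_contig <- unlist(contig_members, use.names = FALSE)
  structure(list(stage = stage, contigs = contigs,
                 singletons = sort(setdiff(all_ids, in_contig)),
                 params = params, provenance = provenance,
                 excluded = sort(excluded)),
            class = "fp_assembly")
}

#' @export
print.fp_assembly <- function(x, ...) {
  cat(sprintf("<fp_assembly> stage=%s: %d contigs, %d singletons\n",
              x$stage, length(x$contigs), length(x$singletons)))
  invisible(x)
}

## ---- assemble --------------------------------------------------------

#' Assemble clones into contigs from fingerprint overlaps
#'
#' All clone pairs are scored with the Sulston probability; shared
#' hybridization markers relax the pairwise cutoff by the denary ladder
#' (see [effective_cutoff()]), and HICF contig co-membership either counts
#' as one shared marker or — for terminal-clone pairs of distinct
#' preliminary contigs — relaxes the cutoff by exactly two denary steps.
#' Accepted overlaps define a graph whose connected components of two or
#' more clones become contigs; all other clones are singletons. Clones
#' with fewer than 2 bands are never joinable.
#'
#' @param profiles Named list of [band_profile()] objects (uniform
#'   method).
#' @param evidence Optional marker table (`marker_id`, `kind`,
#'   `clone_id`); `PROBE` markers with more than `assembly_max_hits` total
#'   hits are ignored.
#' @param params A [score_params()] object.
#' @param assembly_max_hits Probe hit cap for assembly use (default 50).
#' @param relax_floor Most relaxed pairwise cutoff allowed (default 1e-6).
#' @param hicf_markers Optional HICF pseudo-marker table (kind
#'   `HICF_CONTIG`).
#' @param hicf_terminal_pairs Optional two-column matrix/data.frame of
#'   clone pairs eligible for the exact two-denary HICF relaxation.
#' @param exclude Clone ids forced to remain singletons (QC flags).
#' @param stage Stage label stamped on the assembly.
#' @return An `fp_assembly` object; provenance carries the accepted-edge
#'   audit table (pair, matches, score, effective cutoff).
#' @export
assemble <- function(profiles, evidence = NULL, params,
                     assembly_max_hits = 50L, relax_floor = 1e-6,
                     hicf_markers = NULL, hicf_terminal_pairs = NULL,
                     exclude = character(), stage = "PRELIM_AGAROSE") {
  if (!length(profiles)) stop("empty profile set")
  methods <- unique(vapply(profiles, `[[`, "", "method"))
  if (length(methods) != 1L)
    stop("profiles must share one fingerprinting method")
  ids <- names(profiles)
  active <- setdiff(ids, exclude)
  bands <- .bands_of(profiles[active])
  nb <- lengths(bands)
  joinable <- active[nb >= 2L]
  bl <- bands[joinable]
  n <- lengths(bl)

  max_relax <- effective_cutoff(params$cutoff, 3L, relax_floor)
  cut_max <- max(params$cutoff, max_relax)

  edges <- NULL
  if (length(joinable) >= 2L) {
    m_min <- .global_min_match(n, params, cut_max)
    if (!is.na(m_min)) {
      ap <- cpp_all_pairs(bl, params$tolerance, params$channel_span,
                          max(m_min, 1L))
      if (nrow(ap)) {
        na <- n[ap$i]; nbv <- n[ap$j]
        sc <- .sulston_vec(na, nbv, ap$m, params$tolerance,
                           params$gel_length)
        keep <- sc <= cut_max
        ap <- ap[keep, , drop = FALSE]; sc <- sc[keep]
        if (nrow(ap)) {
          a_id <- joinable[ap$i]; b_id <- joinable[ap$j]
          key <- .pair_key(a_id, b_id)

          probe_sets <- .marker_sets(evidence, assembly_max_hits, "PROBE")
          pc <- .marker_pair_counts(probe_sets, joinable)
          shared <- unname(pc[key]); shared[is.na(shared)] <- 0L

          hicf_co <- rep(FALSE, nrow(ap))
          if (!is.null(hicf_markers) && nrow(hicf_markers)) {
            hsets <- .marker_sets(hicf_markers, Inf, "HICF_CONTIG")
            hc <- .marker_pair_counts(hsets, joinable)
            hicf_co <- !is.na(hc[key]) & hc[key] > 0
          }
          term_pair <- rep(FALSE, nrow(ap))
          if (!is.null(hicf_terminal_pairs) &&
              NROW(hicf_terminal_pairs) > 0) {
            tp <- as.matrix(hicf_terminal_pairs)
            term_pair <- key %in% .pair_key(tp[, 1], tp[, 2])
          }
          shared_eff <- shared + as.integer(hicf_co & !term_pair)
          eff <- effective_cutoff(params$cutoff, shared_eff, relax_floor)
          two_denary <- pmin(params$cutoff * 1e2,
                             pmax(params$cutoff, relax_floor))
          eff <- ifelse(hicf_co & term_pair, pmax(eff, two_denary), eff)
          acc <- sc <= eff
          edges <- data.frame(clone_a = a_id[acc], clone_b = b_id[acc],
                              m = ap$m[acc], score = sc[acc],
                              eff_cutoff = eff[acc],
                              shared = shared_eff[acc])
        }
      }
    }
  }
  if (is.null(edges))
    edges <- data.frame(clone_a = character(0), clone_b = character(0),
                        m = integer(0), score = numeric(0),
                        eff_cutoff = numeric(0), shared = integer(0))

  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$clone_a, edges$clone_b))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  contig_members <- Filter(function(x) length(x) >= 2L, groups)

  .as_assembly(stage, contig_members, ids, profiles, params,
               provenance = list(list(stage = stage,
                                      params = unclass(params),
                                      n_edges = nrow(edges),
                                      edges = edges)),
               excluded = intersect(exclude, ids))
}

## ---- finalization operations ----------------------------------------

## Connected components of members at a given cutoff (fingerprint only).
.split_components <- function(members, profiles, params, cutoff) {
  p2 <- score_params(params$tolerance, params$gel_length,
                     max(cutoff, 1e-300), params$channel_span)
  sub <- assemble(profiles[members], NULL, p2, stage = "SPLIT")
  c(lapply(sub$contigs, `[[`, "members"), as.list(sub$singletons))
}

#' Split contigs with multiple Q clones (DQ)
#'
#' Contigs holding two or more Q clones are reassembled at a tenfold
#' stricter cutoff, recursively, until every resulting contig has at most
#' one Q clone; displaced clones become singletons.
#'
#' @param assembly An `fp_assembly` object.
#' @param profiles Profile list used to build it.
#' @param params [score_params()] in force.
#' @return The updated assembly.
#' @export
dq_split <- function(assembly, profiles, params) {
  stopifnot(inherits(assembly, "fp_assembly"))
  out_members <- list()
  n_split <- 0L
  recurse <- function(members, cutoff) {
    ct <- build_cb_map(members, profiles, params)
    if (length(ct$q_clones) <= 1L) {
      out_members[[length(out_members) + 1L]] <<- members
      return(invisible(NULL))
    }
    if (cutoff < 1e-100) {          # give up: shed everything to singletons
      for (mm in members) out_members[[length(out_members) + 1L]] <<- mm
      return(invisible(NULL))
    }
    n_split <<- n_split + 1L
    parts <- .split_components(members, profiles, params, cutoff / 10)
    if (length(parts) == 1L) {      # did not separate: try stricter still
      recurse(members, cutoff / 10)
    } else {
      for (p in parts) recurse(p, cutoff / 10)
    }
  }
  for (ct in assembly$contigs) recurse(ct$members, params$cutoff)
  keep <- Filter(function(x) length(x) >= 2L, out_members)
  all_ids <- c(unlist(lapply(assembly$contigs, `[[`, "members")),
               assembly$singletons)
  .as_assembly("FINAL", keep, all_ids, profiles, params,
               provenance = c(assembly$provenance,
                              list(list(stage = "DQ_SPLIT",
                                        n_split = n_split))),
               excluded = assembly$excluded)
}

#' End-to-end contig merging
#'
#' Recursively merges contigs whose terminal clones (two per end) overlap,
#' lowering the cutoff one denary step at a time from the assembly cutoff
#' down to `floor`. Only terminal-clone pairs are tested; merged contigs
#' are re-laid out before further rounds.
#'
#' @param assembly An `fp_assembly` object.
#' @param profiles Profile list.
#' @param params [score_params()] in force.
#' @param floor Last (most relaxed) cutoff step (default 1e-6).
#' @return The updated assembly.
#' @export
end_merge <- function(assembly, profiles, params, floor = 1e-6) {
  stopifnot(inherits(assembly, "fp_assembly"))
  contigs <- lapply(assembly$contigs, `[[`, "members")
  buried <- lapply(assembly$contigs, `[[`, "buried")
  all_ids <- c(unlist(contigs), assembly$singletons)
  n_merge <- 0L
  cutoff <- params$cutoff
  while (cutoff <= floor * (1 + 1e-9)) {
    repeat {
      if (length(contigs) < 2L) break
      cts <- lapply(seq_along(contigs), function(k)
        .make_contig(k, contigs[[k]], profiles, params,
                     buried = buried[[k]]))
      term <- lapply(cts, function(ct)
        unique(unlist(ct$terminal)))
      tc <- unlist(term)
      owner <- rep(seq_along(term), lengths(term))
      bl <- .bands_of(profiles[tc])
      ap <- cpp_all_pairs(bl, params$tolerance, params$channel_span, 1L)
      if (!nrow(ap)) break
      cross <- owner[ap$i] != owner[ap$j]
      ap <- ap[cross, , drop = FALSE]
      if (!nrow(ap)) break
      n <- lengths(bl)
      sc <- .sulston_vec(n[ap$i], n[ap$j], ap$m, params$tolerance,
                         params$gel_length)
      hit <- sc <= cutoff
      if (!any(hit)) break
      g <- igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices(as.character(seq_along(contigs)))
      g <- igraph::add_edges(g, rbind(as.character(owner[ap$i[hit]]),
                                      as.character(owner[ap$j[hit]])))
      comp <- igraph::components(g)$membership
      merged <- split(seq_along(contigs), comp)
      n_merge <- n_merge + sum(lengths(merged) > 1L)
      contigs <- lapply(merged, function(ix) unlist(contigs[ix]))
      buried <- lapply(merged, function(ix) do.call(c, buried[ix]))
      if (all(lengths(merged) == 1L)) break
    }
    cutoff <- cutoff * 10
  }
  contigs <- contigs[order(vapply(contigs, min, ""))]
  asm <- .as_assembly(assembly$stage, contigs, all_ids, profiles, params,
                      provenance = c(assembly$provenance,
                                     list(list(stage = "END_MERGE",
                                               n_merge = n_merge,
                                               floor = floor))),
                      excluded = assembly$excluded)
  asm
}

#' Adopt singletons into contigs
#'
#' Each singleton (with at least 2 bands and not QC-excluded) is scored
#' against every contig's CB consensus and terminal clones; singletons
#' reaching the cutoff are adopted into their best-scoring contig, best
#' first, and the process repeats until no more are adopted.
#'
#' @param assembly An `fp_assembly` object.
#' @param profiles Profile list.
#' @param params [score_params()] in force (its cutoff is used).
#' @return The updated assembly.
#' @export
adopt_singletons <- function(assembly, profiles, params) {
  stopifnot(inherits(assembly, "fp_assembly"))
  contigs <- lapply(assembly$contigs, `[[`, "members")
  all_ids <- c(unlist(contigs), assembly$singletons)
  n_adopt <- 0L
  repeat {
    if (!length(contigs)) break
    cts <- lapply(seq_along(contigs), function(k)
      .make_contig(k, contigs[[k]], profiles, params))
    pool <- setdiff(assembly$singletons, c(unlist(contigs),
                                           assembly$excluded))
    pool <- pool[lengths(.bands_of(profiles[pool])) >= 2L]
    if (!length(pool)) break
    best <- data.frame(clone = pool, contig = NA_integer_,
                       score = Inf)
    for (k in seq_along(cts)) {
      ct <- cts[[k]]
      targets <- c(list(ct$consensus),
                   .bands_of(profiles[unique(unlist(ct$terminal))]))
      t_n <- lengths(targets)
      for (si in seq_along(pool)) {
        b <- profiles[[pool[si]]]$bands
        mc <- cpp_match_many(b, targets, params$tolerance,
                             params$channel_span)
        sc <- min(.sulston_vec(rep(length(b), length(targets)), t_n,
                               mc, params$tolerance, params$gel_length))
        if (sc < best$score[si]) {
          best$score[si] <- sc; best$contig[si] <- k
        }
      }
    }
    acc <- best[best$score <= params$cutoff, , drop = FALSE]
    if (!nrow(acc)) break
    acc <- acc[order(acc$score, acc$clone), ]
    for (r in seq_len(nrow(acc)))
      contigs[[acc$contig[r]]] <- c(contigs[[acc$contig[r]]], acc$clone[r])
    assembly$singletons <- setdiff(assembly$singletons, acc$clone)
    n_adopt <- n_adopt + nrow(acc)
  }
  .as_assembly(assembly$stage, contigs, all_ids, profiles, params,
               provenance = c(assembly$provenance,
                              list(list(stage = "ADOPT",
                                        n_adopted = n_adopt))),
               excluded = assembly$excluded)
}

#' Bury near-identical clones
#'
#' A clone is buried into another member of its contig when at least
#' `fraction` of its bands match that member's bands. Burial edges run
#' from fewer-band to more-band clones (ties by id), so the burial graph
#' is acyclic; buried clones keep their membership but are excluded from
#' terminal-clone selection.
#'
#' @param contig An `fp_contig`.
#' @param profiles Profile list.
#' @param params [score_params()] (tolerance/channel span).
#' @param fraction Band-containment threshold (default 0.80).
#' @return The updated contig.
#' @export
bury_clones <- function(contig, profiles, params, fraction = 0.80) {
  stopifnot(inherits(contig, "fp_contig"))
  members <- contig$members
  bands <- .bands_of(profiles[members])
  n <- lengths(bands)
  ord <- order(n, members)        # children first
  buried <- character(0)
  for (ci in ord) {
    child <- members[ci]
    cands <- which(n > n[ci] | (n == n[ci] & members < child))
    if (!length(cands)) next
    mc <- cpp_match_many(bands[[ci]], bands[cands], params$tolerance,
                         params$channel_span)
    frac <- if (n[ci] > 0) mc / n[ci] else 0
    ok <- frac >= fraction
    if (!any(ok)) next
    pick <- cands[ok][order(-frac[ok], -n[cands][ok], members[cands][ok])][1]
    buried[child] <- members[pick]
  }
  # resolve chains to the ultimate unburied parent
  for (child in names(buried)) {
    p <- buried[[child]]
    while (p %in% names(buried)) p <- buried[[p]]
    buried[child] <- p
  }
  contig$buried <- buried
  contig$terminal <- .contig_terminals(contig)
  contig
}

## Apply burying across all contigs of an assembly.
.bury_all <- function(assembly, profiles, params, fraction = 0.80) {
  assembly$contigs <- lapply(assembly$contigs, bury_clones,
                             profiles = profiles, params = params,
                             fraction = fraction)
  n_buried <- sum(vapply(assembly$contigs,
                         function(ct) length(ct$buried), integer(1)))
  assembly$provenance <- c(assembly$provenance,
                           list(list(stage = "BURY", n_buried = n_buried)))
  assembly
}

#' Detect possible cross-well contaminations
#'
#' Clone pairs in rook-adjacent wells of the same plate whose band
#' patterns mutually match at or above `similarity` (fraction of each
#' clone's bands matched) are flagged; flagged clones are rendered
#' singletons by the pipeline.
#'
#' @param profiles Named list of [band_profile()] objects with well
#'   addresses.
#' @param params [score_params()] (tolerance/channel span).
#' @param similarity Mutual match fraction (default 0.90).
#' @return Character vector of flagged clone ids.
#' @export
detect_cross_well <- function(profiles, params, similarity = 0.90) {
  meta <- data.frame(
    clone_id = names(profiles),
    plate = vapply(profiles, `[[`, integer(1), "plate"),
    row = vapply(profiles, `[[`, integer(1), "well_row"),
    col = vapply(profiles, `[[`, integer(1), "well_col"))
  meta <- meta[!is.na(meta$plate), , drop = FALSE]
  flagged <- character(0)
  for (pl in unique(meta$plate)) {
    m <- meta[meta$plate == pl, , drop = FALSE]
    if (nrow(m) < 2L) next
    # rook-adjacent pairs only
    for (i in seq_len(nrow(m) - 1L)) {
      adj <- which(abs(m$row - m$row[i]) + abs(m$col - m$col[i]) == 1L)
      adj <- adj[adj > i]
      for (j in adj) {
        a <- profiles[[m$clone_id[i]]]$bands
        b <- profiles[[m$clone_id[j]]]$bands
        if (length(a) < 2L || length(b) < 2L) next
        mc <- cpp_match_count(a, b, params$tolerance, params$channel_span)
        if (mc / length(a) >= similarity && mc / length(b) >= similarity)
          flagged <- c(flagged, m$clone_id[i], m$clone_id[j])
      }
    }
  }
  sort(unique(flagged))
}

#' Flag clones with outlying band counts
#'
#' Per fingerprinting batch, clones whose band counts fall strictly below
#' the lower or strictly above the upper nearest-rank percentile are
#' flagged (suspected chimeras or failed digests to re-fingerprint).
#'
#' @param profiles Named list of [band_profile()] objects.
#' @param low_pct,high_pct Percentiles (default 5 each).
#' @return Character vector of flagged clone ids.
#' @export
detect_band_outliers <- function(profiles, low_pct = 5, high_pct = 5) {
  counts <- lengths(.bands_of(profiles))
  batch <- vapply(profiles, `[[`, integer(1), "batch")
  batch[is.na(batch)] <- 0L
  flagged <- character(0)
  for (b in unique(batch)) {
    ids <- names(profiles)[batch == b]
    cnt <- counts[ids]
    srt <- sort(cnt)
    nn <- length(srt)
    lo <- srt[max(1L, ceiling(low_pct / 100 * nn))]
    hi <- srt[max(1L, ceiling((100 - high_pct) / 100 * nn))]
    flagged <- c(flagged, ids[cnt < lo | cnt > hi])
  }
  sort(unique(flagged))
}

#' Select terminal clones of the largest contigs
#'
#' Contigs are ranked by clone count (ties by CB length, then id);
#' `per_end` unburied clones with extreme CB offsets are taken from each
#' end of the top `k_contigs`.
#'
#' @param assembly An `fp_assembly` object.
#' @param k_contigs Number of top contigs.
#' @param per_end Clones per contig end (default 2).
#' @return Character vector of selected clone ids (duplicates removed),
#'   with attribute `contig_ids` (the ranked contig selection).
#' @export
select_terminal_clones <- function(assembly, k_contigs, per_end = 2L) {
  stopifnot(inherits(assembly, "fp_assembly"))
  if (!length(assembly$contigs)) return(character(0))
  sz <- vapply(assembly$contigs, function(ct) length(ct$members), integer(1))
  cb <- vapply(assembly$contigs, `[[`, numeric(1), "cb_length")
  id <- vapply(assembly$contigs, `[[`, integer(1), "contig_id")
  ord <- order(-sz, -cb, id)
  top <- assembly$contigs[utils::head(ord, k_contigs)]
  sel <- unlist(lapply(top, function(ct) {
    t <- .contig_terminals(ct, per_end)
    c(t$left, t$right)
  }))
  out <- sort(unique(sel))
  attr(out, "contig_ids") <- vapply(top, `[[`, integer(1), "contig_id")
  out
}

#' HICF contigs as pseudo-markers
#'
#' Each HICF contig becomes one `HICF_CONTIG` marker whose clone set is
#' its membership; HICF singletons yield no marker.
#'
#' @param hicf_assembly An `fp_assembly` from HICF profiles.
#' @return Marker data.frame (`marker_id`, `kind`, `clone_id`).
#' @export
hicf_pseudomarkers <- function(hicf_assembly) {
  stopifnot(inherits(hicf_assembly, "fp_assembly"))
  rows <- lapply(hicf_assembly$contigs, function(ct)
    data.frame(marker_id = sprintf("HICFC%04d", ct$contig_id),
               kind = "HICF_CONTIG", clone_id = ct$members))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(marker_id = character(0), kind = character(0),
                      clone_id = character(0))
  out
}
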