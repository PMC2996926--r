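#' Simulation configuration
#'
#' The stated world of the synthetic genome and BAC library: a desk-scale
#' genome (default 20 Mb) emulating the mapped genome's properties — ~30%
#' repetitive DNA in families of ~120 copies, 0.07%-level organelle
#' contamination, a 10x BAC library with ~100 kb inserts, HindIII-like
#' agarose digests calibrated to ~17.4 scoreable bands per clone on a
#' 5000-unit gel, 5-enzyme HICF digests calibrated to ~178 bands, a
#' 13-group genetic map at ~600 kb/cM, and comparator genomes differing by
#' whole-genome duplications.
#'
#' @param genome_bp Genome size in bp (desk scale 2e7; the mapped genome
#'   was ~8.8e8).
#' @param n_groups Number of linkage groups (default 13).
#' @param repeat_fraction Fraction of the genome in repeat families
#'   (default 0.30).
#' @param repeat_copy_mean Mean copies per repeat family (default 120).
#' @param repeat_unit_bp Repeat unit length (default 500 bp).
#' @param organelle_bp Organelle genome size (default 160 kb,
#'   chloroplast-like).
#' @param organelle_rate Fraction of clones of organelle origin
#'   (default 0.0007).
#' @param coverage Library coverage (default 10).
#' @param insert_mean,insert_sd Clone insert size distribution (bp).
#' @param failed_rate Fraction of clones failing fingerprinting
#'   (default 0.035; such clones emit empty profiles).
#' @param chimera_rate Fraction of chimeric clones (two concatenated
#'   segments; default 0.005).
#' @param cross_well_rate Fraction of clones whose fingerprint is replaced
#'   by an adjacent well's DNA (default 0.006).
#' @param agarose_band_bp Mean restriction fragment size for the agarose
#'   enzyme (default 4096, a 6-cutter).
#' @param agarose_window Scoreable fragment size window in bp; very large
#'   and very small fragments are excluded from band calling (as are the
#'   two vector-junction fragments of every insert). The default
#'   `c(750, 10000)` calibrates the scoreable band mean to ~17.4.
#' @param gel_length Agarose gel length in band units (default 5000).
#' @param hicf_channels Number of HICF enzyme channels (default 5).
#' @param hicf_band_bp Mean fragment size per HICF enzyme (default 2500).
#' @param hicf_window Scoreable HICF fragment window (default
#'   `c(100, 7600)`, calibrating the 5-channel band mean to ~178).
#' @param hicf_channel_span Gel units per HICF channel (default 2000).
#' @param dropout,spurious Per-band probabilities of losing a true band and
#'   of gaining a spurious band (defaults 0.02 each).
#' @param jitter_rate,jitter_max Probability that a band position jitters
#'   and the maximum shift in gel units (defaults 0.5 and 2; shifts stay
#'   below the matching tolerance).
#' @param noise Master switch: `FALSE` zeroes dropout, spurious, jitter,
#'   chimera and cross-well rates (the noise-free stated world used by the
#'   recovery oracles).
#' @param probe_count Number of overgo probes (default 240).
#' @param repetitive_probe_fraction Fraction of probes falling in repeat
#'   families (default 0.10).
#' @param gene_count Number of annotated genes (default scales to ~15 per
#'   200 kb).
#' @param gene_bp Gene length (default 2000).
#' @param cM_per_bp Genetic-to-physical scale (default 1/600000).
#' @param n_wgd Whole-genome duplications in the comparator genome
#'   (0 or 2).
#' @param comparator_chroms Number of comparator chromosomes (default 5).
#' @param block_bp Synteny block size (default 1 Mb).
#' @param retention Per-locus retention probability on duplicated block
#'   copies (default 0.3).
#' @param hit_loss Probability a true comparator hit is not observed
#'   (default 0.1).
#' @param plate_rows,plate_cols Microplate geometry (default 16 x 24).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_bp = 2e7, n_groups = 13L,
                       repeat_fraction = 0.30, repeat_copy_mean = 120,
                       repeat_unit_bp = 500, organelle_bp = 160000,
                       organelle_rate = 0.0007, coverage = 10,
                       insert_mean = 1e5, insert_sd = 5e3,
                       failed_rate = 0.035, chimera_rate = 0.005,
                       cross_well_rate = 0.006, agarose_band_bp = 4096,
                       agarose_window = c(750, 10000), gel_length = 5000L,
                       hicf_channels = 5L, hicf_band_bp = 2500,
                       hicf_window = c(100, 7600),
                       hicf_channel_span = 2000L, dropout = 0.02,
                       spurious = 0.02, jitter_rate = 0.5, jitter_max = 2L,
                       noise = TRUE, probe_count = 240L,
                       repetitive_probe_fraction = 0.10,
                       gene_count = round(genome_bp / 2e5 * 15),
                       gene_bp = 2000, cM_per_bp = 1 / 600000,
                       n_wgd = 0L, comparator_chroms = 5L, block_bp = 1e6,
                       retention = 0.3, hit_loss = 0.1,
                       plate_rows = 16L, plate_cols = 24L) {
  if (!noise) {
    dropout <- 0; spurious <- 0; jitter_rate <- 0
    chimera_rate <- 0; cross_well_rate <- 0
  }
  cfg <- list(genome_bp = genome_bp, n_groups = as.integer(n_groups),
              repeat_fraction = repeat_fraction,
              repeat_copy_mean = repeat_copy_mean,
              repeat_unit_bp = repeat_unit_bp, organelle_bp = organelle_bp,
              organelle_rate = organelle_rate, coverage = coverage,
              insert_mean = insert_mean, insert_sd = insert_sd,
              failed_rate = failed_rate, chimera_rate = chimera_rate,
              cross_well_rate = cross_well_rate,
              agarose_band_bp = agarose_band_bp,
              agarose_window = agarose_window,
              gel_length = as.integer(gel_length),
              hicf_channels = as.integer(hicf_channels),
              hicf_band_bp = hicf_band_bp, hicf_window = hicf_window,
              hicf_channel_span = as.integer(hicf_channel_span),
              dropout = dropout, spurious = spurious,
              jitter_rate = jitter_rate, jitter_max = as.integer(jitter_max),
              noise = noise, probe_count = as.integer(probe_count),
              repetitive_probe_fraction = repetitive_probe_fraction,
              gene_count = as.integer(gene_count), gene_bp = gene_bp,
              cM_per_bp = cM_per_bp, n_wgd = as.integer(n_wgd),
              comparator_chroms = as.integer(comparator_chroms),
              block_bp = block_bp, retention = retention,
              hit_loss = hit_loss, plate_rows = as.integer(plate_rows),
              plate_cols = as.integer(plate_cols))
  rates <- c(cfg$repeat_fraction, cfg$organelle_rate, cfg$failed_rate,
             cfg$chimera_rate, cfg$cross_well_rate, cfg$dropout,
             cfg$spurious, cfg$jitter_rate, cfg$retention, cfg$hit_loss,
             cfg$repetitive_probe_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(c(genome_bp, insert_mean, coverage, agarose_band_bp) <= 0))
    stop("sizes must be positive")
  structure(cfg, class = "sim_config")
}

#' Derive a module seed from a master seed
#'
#' Fixed-offset derivation keeping results below 2^31.
#' @param master Master seed (integer).
#' @param offset Module offset.
#' @return Integer seed.
#' @export
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 48271 + offset * 7919) %% 2147483647)
}

## Run code with a locally seeded RNG, restoring the caller's state.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate a genome with repeats, genes, probes and cut sites
#'
#' Repeat families are placed with Poisson copy numbers; genes and
#' single-copy probe loci are placed preferentially outside repeats;
#' repetitive probes are tied to a repeat family (one locus per copy).
#' Restriction cut sites are homogeneous Poisson processes fixed at the
#' genome level, so overlapping clones share fragments exactly.
#'
#' @param cfg A [sim_config()] object.
#' @param seed Integer seed; identical seeds give identical truth.
#' @return An object of class `genome_truth`.
#' @export
simulate_genome <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(seed, {
    G <- cfg$genome_bp
    group_starts <- floor(seq(0, G, length.out = cfg$n_groups + 1L))

    repeats <- NULL
    # placed copies overlap; -log(1-f) corrects the budget so the union
    # of repeat intervals covers the requested fraction in expectation
    budget <- if (cfg$repeat_fraction > 0)
      -log(1 - cfg$repeat_fraction) * G else 0
    if (budget > 0) {
      fams <- list(); used <- 0; fam <- 0L
      while (used < budget) {
        fam <- fam + 1L
        copies <- max(2L, stats::rpois(1L, cfg$repeat_copy_mean))
        copies <- min(copies, ceiling((budget - used) / cfg$repeat_unit_bp))
        if (copies < 1L) break
        starts <- sort(floor(stats::runif(copies, 0, G - cfg$repeat_unit_bp)))
        fams[[fam]] <- data.frame(family = fam, copy = seq_len(copies),
                                  start = starts,
                                  end = starts + cfg$repeat_unit_bp)
        used <- used + copies * cfg$repeat_unit_bp
      }
      repeats <- do.call(rbind, fams)
    }
    if (is.null(repeats))
      repeats <- data.frame(family = integer(0), copy = integer(0),
                            start = numeric(0), end = numeric(0))
    rep_ir <- IRanges::reduce(IRanges::IRanges(start = repeats$start + 1,
                                               end = pmax(repeats$end, repeats$start + 1)))

    place_biased <- function(n, len, penalty = 0.1) {
      out <- numeric(0)
      while (length(out) < n) {
        cand <- floor(stats::runif(2L * (n - length(out)), 0, G - len))
        in_rep <- IRanges::overlapsAny(
          IRanges::IRanges(start = cand + 1, width = max(len, 1)), rep_ir)
        acc <- !in_rep | stats::runif(length(cand)) < penalty
        out <- c(out, cand[acc])
      }
      sort(out[seq_len(n)])
    }

    gene_start <- place_biased(cfg$gene_count, cfg$gene_bp)
    genes <- data.frame(gene_id = sprintf("G%05d", seq_len(cfg$gene_count)),
                        start = gene_start, end = gene_start + cfg$gene_bp)

    n_rep_probe <- if (nrow(repeats))
      round(cfg$probe_count * cfg$repetitive_probe_fraction) else 0L
    n_low <- cfg$probe_count - n_rep_probe
    low_pos <- place_biased(n_low, 40)
    probes <- data.frame(probe_id = sprintf("OV%04d", seq_len(cfg$probe_count)),
                         repetitive = rep(c(FALSE, TRUE), c(n_low, n_rep_probe)),
                         family = NA_integer_, pos = NA_real_)
    probes$pos[seq_len(n_low)] <- low_pos
    probe_copies <- as.list(low_pos)
    if (n_rep_probe > 0 && nrow(repeats)) {
      fam_ids <- sample(unique(repeats$family), n_rep_probe, replace = TRUE)
      for (k in seq_len(n_rep_probe)) {
        offs <- floor(stats::runif(1, 0, cfg$repeat_unit_bp - 40))
        cp <- repeats$start[repeats$family == fam_ids[k]] + offs
        probes$family[n_low + k] <- fam_ids[k]
        probes$pos[n_low + k] <- cp[1]
        probe_copies[[n_low + k]] <- sort(cp)
      }
    }
    names(probe_copies) <- probes$probe_id

    pois_sites <- function(len, mean_bp)
      sort(stats::runif(stats::rpois(1L, len / mean_bp), 0, len))
    cut_sites <- list(
      agarose = pois_sites(G, cfg$agarose_band_bp),
      hicf = lapply(seq_len(cfg$hicf_channels), function(ch)
        pois_sites(G, cfg$hicf_band_bp)),
      organelle_agarose = pois_sites(cfg$organelle_bp, cfg$agarose_band_bp),
      organelle_hicf = lapply(seq_len(cfg$hicf_channels), function(ch)
        pois_sites(cfg$organelle_bp, cfg$hicf_band_bp)))

    single <- !probes$repetitive
    grp <- findInterval(probes$pos[single], group_starts,
                        rightmost.closed = TRUE)
    grp <- pmin(pmax(grp, 1L), cfg$n_groups)
    map <- data.frame(marker_id = probes$probe_id[single], group = grp,
                      cM = (probes$pos[single] - group_starts[grp]) *
                        cfg$cM_per_bp)

    structure(list(cfg = cfg, genome_bp = G, group_starts = group_starts,
                   repeats = repeats, genes = genes, probes = probes,
                   probe_copies = probe_copies, cut_sites = cut_sites,
                   map = map, seed = seed),
              class = "genome_truth")
  })
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf("<genome_truth> %.3g bp, %d repeat copies, %d genes, %d probes\n",
              x$genome_bp, nrow(x$repeats), nrow(x$genes), nrow(x$probes)))
  invisible(x)
}

#' Measured repeat fraction of a simulated genome
#' @param truth A `genome_truth` object.
#' @return Fraction of the genome covered by repeat copies.
#' @export
repeat_fraction <- function(truth) {
  if (!nrow(truth$repeats)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = truth$repeats$start + 1,
                                         end = truth$repeats$end))
  sum(IRanges::width(ir)) / truth$genome_bp
}

#' Simulate a BAC library over a genome truth
#'
#' Clone count is `coverage * genome / insert_mean`; starts are uniform.
#' Organelle clones, chimeras (two concatenated segments), failed
#' fingerprints and cross-well contaminations occur at the configured
#' rates. Wells are assigned plate-major on the configured plate geometry;
#' the fingerprinting batch is the plate.
#'
#' @param truth A [simulate_genome()] result.
#' @param seed Integer seed.
#' @return Data.frame of clone placements (one row per clone) with well
#'   addresses and truth flags.
#' @export
simulate_library <- function(truth, seed) {
  cfg <- truth$cfg
  .with_seed(seed, {
    G <- truth$genome_bp
    n <- round(cfg$coverage * G / cfg$insert_mean)
    if (n < 1L) stop("empty genome or zero coverage: no clones")
    len <- round(pmin(pmax(stats::rnorm(n, cfg$insert_mean, cfg$insert_sd),
                           cfg$insert_mean / 2), cfg$insert_mean * 2))
    organelle <- stats::runif(n) < cfg$organelle_rate
    chimeric <- !organelle & stats::runif(n) < cfg$chimera_rate
    failed <- stats::runif(n) < cfg$failed_rate
    start <- ifelse(organelle,
                    floor(stats::runif(n, 0, pmax(1, cfg$organelle_bp - pmin(len, cfg$organelle_bp - 1)))),
                    floor(stats::runif(n, 0, G - len)))
    len <- ifelse(organelle, pmin(len, cfg$organelle_bp - 1), len)
    seg2_start <- rep(NA_real_, n); seg2_len <- rep(NA_real_, n)
    if (any(chimeric)) {
      k <- which(chimeric)
      seg2_len[k] <- round(len[k] / 2)
      len[k] <- len[k] - seg2_len[k]
      seg2_start[k] <- floor(stats::runif(length(k), 0, G - seg2_len[k]))
    }
    wells_per_plate <- cfg$plate_rows * cfg$plate_cols
    idx <- seq_len(n) - 1L
    plate <- idx %/% wells_per_plate + 1L
    w <- idx %% wells_per_plate
    row <- w %/% cfg$plate_cols + 1L
    col <- w %% cfg$plate_cols + 1L
    clone_id <- sprintf("GR%05d", seq_len(n))
    contaminated_from <- rep(NA_character_, n)
    n_cw <- stats::rbinom(1L, n, cfg$cross_well_rate)
    if (n_cw > 0) {
      victims <- sample(n, n_cw)
      for (v in victims) {
        # rook-adjacent well on the same plate
        nbr <- which(plate == plate[v] & abs(row - row[v]) + abs(col - col[v]) == 1L)
        if (length(nbr)) contaminated_from[v] <- clone_id[sample(nbr, 1L)]
      }
    }
    data.frame(clone_id = clone_id, start = start, len = len,
               end = start + len, source = ifelse(organelle, "organelle",
                                                  "nuclear"),
               chimeric = chimeric, seg2_start = seg2_start,
               seg2_len = seg2_len, failed = failed,
               contaminated_from = contaminated_from,
               plate = plate, well_row = row, well_col = col, batch = plate)
  })
}

## Map fragment sizes (bp) to gel units via the conditional exponential CDF
## over the scoreable window: scoreable sizes land uniformly on the gel,
## which is exactly the Sulston null for unrelated clones.
.gel_units <- function(sizes, window, mean_bp, units) {
  keep <- sizes >= window[1] & sizes <= window[2]
  s <- sizes[keep]
  lo <- exp(-window[1] / mean_bp); hi <- exp(-window[2] / mean_bp)
  u <- 1L + as.integer(floor((units - 1) * (lo - exp(-s / mean_bp)) / (lo - hi)))
  pmin(pmax(u, 1L), as.integer(units))
}

## Fragment lengths of one interval against sorted genome-level cut sites.
## Only internal fragments (between two cut sites inside the insert) are
## returned: the two insert-boundary fragments carry vector sequence and
## are excluded from band calling, which also makes overlapping clones
## share their common fragments exactly.
.fragments <- function(sites, start, end) {
  inner <- sites[sites > start & sites < end]
  if (length(inner) < 2L) return(numeric(0))
  diff(inner)
}

## True (noise-free) band values of one clone for one method.
.clone_bands <- function(truth, clone, method) {
  cfg <- truth$cfg
  segs <- rbind(c(clone$start, clone$end),
                if (isTRUE(clone$chimeric))
                  c(clone$seg2_start, clone$seg2_start + clone$seg2_len))
  if (method == "AGAROSE") {
    sites <- if (clone$source == "organelle") truth$cut_sites$organelle_agarose
    else truth$cut_sites$agarose
    sizes <- unlist(lapply(seq_len(nrow(segs)), function(i)
      .fragments(sites, segs[i, 1], segs[i, 2])))
    sort(unique(.gel_units(sizes, cfg$agarose_window, cfg$agarose_band_bp,
                           cfg$gel_length)))
  } else {
    chans <- if (clone$source == "organelle") truth$cut_sites$organelle_hicf
    else truth$cut_sites$hicf
    bands <- unlist(lapply(seq_along(chans), function(ch) {
      sizes <- unlist(lapply(seq_len(nrow(segs)), function(i)
        .fragments(chans[[ch]], segs[i, 1], segs[i, 2])))
      u <- .gel_units(sizes, cfg$hicf_window, cfg$hicf_band_bp,
                      cfg$hicf_channel_span)
      (ch - 1L) * cfg$hicf_channel_span + u
    }))
    sort(unique(bands))
  }
}

## Apply band noise (dropout, spurious, jitter) to true band values.
.apply_noise <- function(bands, method, cfg) {
  if (length(bands)) bands <- bands[stats::runif(length(bands)) >= cfg$dropout]
  n_sp <- if (cfg$spurious > 0)
    stats::rbinom(1L, max(length(bands), 1L), cfg$spurious) else 0L
  if (n_sp > 0) {
    if (method == "AGAROSE") {
      extra <- sample.int(cfg$gel_length, n_sp, replace = TRUE)
    } else {
      ch <- sample.int(cfg$hicf_channels, n_sp, replace = TRUE)
      extra <- (ch - 1L) * cfg$hicf_channel_span +
        sample.int(cfg$hicf_channel_span, n_sp, replace = TRUE)
    }
    bands <- c(bands, extra)
  }
  if (cfg$jitter_rate > 0 && length(bands)) {
    hit <- stats::runif(length(bands)) < cfg$jitter_rate
    if (any(hit)) {
      shift <- sample(c(-(cfg$jitter_max:1), 1:cfg$jitter_max), sum(hit),
                      replace = TRUE)
      span <- if (method == "AGAROSE") cfg$gel_length else cfg$hicf_channel_span
      b <- bands[hit]
      off <- (b - 1L) %/% span      # HICF channel is preserved under jitter
      u <- (b - 1L) %% span + 1L
      u <- pmin(pmax(u + shift, 1L), span)
      bands[hit] <- off * span + u
    }
  }
  sort(unique(as.integer(bands)))
}

#' Digest one clone into a band profile
#'
#' Cut sites are genome-level Poisson draws, so overlapping clones share
#' the fragments (hence bands) of their common interval exactly when noise
#' is off. Fragments outside the scoreable size window are excluded; sizes
#' map to gel units through the conditional exponential CDF (scoreable
#' bands are uniform on the gel, matching the Sulston null); comigrating
#' bands merge. Noise (dropout, spurious bands, position jitter below the
#' tolerance) follows the configured rates.
#'
#' @param truth A [simulate_genome()] result.
#' @param clone One row of [simulate_library()].
#' @param method `"AGAROSE"` or `"HICF"`.
#' @param noise Apply the configured noise processes (default from config).
#' @return A [band_profile()].
#' @export
digest_clone <- function(truth, clone, method = c("AGAROSE", "HICF"),
                         noise = truth$cfg$noise) {
  method <- match.arg(method)
  cfg <- truth$cfg
  if (isTRUE(clone$failed)) {
    bands <- integer(0)
  } else {
    bands <- .clone_bands(truth, clone, method)
    if (noise) bands <- .apply_noise(bands, method, cfg)
  }
  band_profile(clone$clone_id, bands, method, plate = clone$plate,
               well_row = clone$well_row, well_col = clone$well_col,
               batch = clone$batch)
}

#' Fingerprint a clone library
#'
#' Vectorised [digest_clone()] over a clone table, honouring cross-well
#' contamination (a contaminated clone reports the bands of its source
#' well, with its own noise draw).
#'
#' @param truth A [simulate_genome()] result.
#' @param clones Clone table from [simulate_library()] (or a subset).
#' @param method `"AGAROSE"` or `"HICF"`.
#' @param seed Integer seed for the noise draws.
#' @param noise Apply noise (default from config).
#' @return Named list of [band_profile()] objects.
#' @export
simulate_fingerprints <- function(truth, clones, method = c("AGAROSE", "HICF"),
                                  seed = 1L, noise = truth$cfg$noise) {
  method <- match.arg(method)
  .with_seed(seed, {
    rows <- seq_len(nrow(clones))
    all_rows <- stats::setNames(rows, clones$clone_id)
    profiles <- vector("list", nrow(clones))
    names(profiles) <- clones$clone_id
    for (i in rows) {
      cl <- clones[i, ]
      src_id <- cl$contaminated_from
      if (!is.na(src_id) && src_id %in% names(all_rows)) {
        src <- clones[all_rows[[src_id]], ]
        src$clone_id <- cl$clone_id
        src[c("plate", "well_row", "well_col", "batch")] <-
          cl[c("plate", "well_row", "well_col", "batch")]
        src$failed <- cl$failed
        profiles[[i]] <- digest_clone(truth, src, method, noise)
      } else {
        profiles[[i]] <- digest_clone(truth, cl, method, noise)
      }
    }
    profiles
  })
}

#' Simulate probe-to-BAC hybridization
#'
#' A BAC is hit when any copy of the probe locus lies fully inside one of
#' its segments. Single-copy probes are expected to hit ~coverage BACs;
#' repetitive probes hit proportionally to family copy number.
#'
#' @param truth A [simulate_genome()] result.
#' @param clones Clone table from [simulate_library()].
#' @return Data.frame with `probe_id`, `bac_id`.
#' @export
simulate_probe_hits <- function(truth, clones) {
  nuc <- clones[clones$source == "nuclear", , drop = FALSE]
  segs <- rbind(
    data.frame(clone_id = nuc$clone_id, start = nuc$start, end = nuc$end),
    {
      ch <- nuc[nuc$chimeric, , drop = FALSE]
      if (nrow(ch)) data.frame(clone_id = ch$clone_id, start = ch$seg2_start,
                               end = ch$seg2_start + ch$seg2_len)
      else NULL
    })
  segs <- segs[order(segs$start), ]
  out <- list()
  max_len <- max(segs$end - segs$start)
  for (pid in names(truth$probe_copies)) {
    for (p in truth$probe_copies[[pid]]) {
      lo <- findInterval(p - max_len, segs$start)
      hi <- findInterval(p, segs$start)
      if (hi < 1L) next
      cand <- segs[max(lo, 1L):hi, , drop = FALSE]
      hit <- cand$clone_id[cand$start <= p & cand$end >= p + 40]
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(probe_id = pid, bac_id = hit)
    }
  }
  res <- unique(do.call(rbind, out))
  if (is.null(res)) res <- data.frame(probe_id = character(0),
                                      bac_id = character(0))
  rownames(res) <- NULL
  res
}

#' Simulate a pooled hybridization experiment
#'
#' A pool scores positive on a BAC when any member probe truly hits it;
#' false-negative and false-positive noise is then applied per
#' (BAC, pool).
#'
#' @param design A [build_pool_design()] object.
#' @param matrix Probe hits (`probe_id`, `bac_id`), e.g. from
#'   [simulate_probe_hits()].
#' @param fn_rate,fp_rate Per-pool false-negative / false-positive rates.
#' @param seed Integer seed.
#' @return Data.frame with `bac_id`, `pool_id`.
#' @export
simulate_pool_experiment <- function(design, matrix, fn_rate = 0,
                                     fp_rate = 0, seed = 1L) {
  .with_seed(seed, {
    matrix <- matrix[matrix$probe_id %in% design$positions$probe_id, ,
                     drop = FALSE]
    all_pools <- names(design$pools)
    out <- list()
    for (bac in sort(unique(matrix$bac_id))) {
      probes <- unique(matrix$probe_id[matrix$bac_id == bac])
      pos <- unique(unlist(lapply(probes, .probe_pools, design = design)))
      if (fn_rate > 0) pos <- pos[stats::runif(length(pos)) >= fn_rate]
      if (fp_rate > 0) {
        neg <- setdiff(all_pools, pos)
        pos <- c(pos, neg[stats::runif(length(neg)) < fp_rate])
      }
      if (length(pos))
        out[[bac]] <- data.frame(bac_id = bac, pool_id = sort(pos))
    }
    res <- do.call(rbind, out)
    if (is.null(res)) res <- data.frame(bac_id = character(0),
                                        pool_id = character(0))
    rownames(res) <- NULL
    res
  })
}

#' Simulate a comparator genome with whole-genome duplications
#'
#' The source genome is partitioned into blocks that are shuffled onto
#' comparator chromosomes; `n_wgd` duplications give `2^n_wgd` copies of
#' every block, with per-locus retention on the non-primary copies.
#' Query sequences (single-copy probe sources, plus BAC-end sequences when
#' a clone table is given) generate hits through the block map with the
#' configured loss rate; gene annotation is carried through for density
#' tracks.
#'
#' @param truth A [simulate_genome()] result.
#' @param seed Integer seed.
#' @param clones Optional clone table; when given, both ends of each
#'   non-failed nuclear clone yield BES queries.
#' @param n_wgd Override the configured number of WGDs.
#' @return List with `chrom_lengths`, `block_map`, `hits`, `genes`,
#'   `queries`, `n_wgd`.
#' @export
simulate_comparator <- function(truth, seed, clones = NULL,
                                n_wgd = truth$cfg$n_wgd) {
  cfg <- truth$cfg
  .with_seed(seed, {
    G <- truth$genome_bp
    n_blocks <- as.integer(ceiling(G / cfg$block_bp))
    n_copies <- 2L^n_wgd
    blocks <- data.frame(block_id = seq_len(n_blocks),
                         src_start = (seq_len(n_blocks) - 1L) * cfg$block_bp,
                         src_end = pmin(seq_len(n_blocks) * cfg$block_bp, G))
    bm <- do.call(rbind, lapply(seq_len(n_copies), function(cp)
      cbind(blocks, copy = cp)))
    bm <- bm[sample(nrow(bm)), ]
    per_chrom <- ceiling(nrow(bm) / cfg$comparator_chroms)
    bm$chrom <- sprintf("chr%d", (seq_len(nrow(bm)) - 1L) %/% per_chrom + 1L)
    width <- bm$src_end - bm$src_start
    bm$tgt_start <- stats::ave(width, bm$chrom,
                               FUN = function(w) cumsum(c(0, w[-length(w)])))
    chrom_lengths <- tapply(width, bm$chrom, sum)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))

    queries <- data.frame(
      query_id = truth$map$marker_id,
      query_kind = "PROBE_SOURCE",
      src_pos = truth$probes$pos[match(truth$map$marker_id,
                                       truth$probes$probe_id)])
    if (!is.null(clones)) {
      nuc <- clones[clones$source == "nuclear" & !clones$failed, ,
                    drop = FALSE]
      queries <- rbind(queries,
                       data.frame(query_id = paste0(nuc$clone_id, "_F"),
                                  query_kind = "BES", src_pos = nuc$start),
                       data.frame(query_id = paste0(nuc$clone_id, "_R"),
                                  query_kind = "BES",
                                  src_pos = pmax(nuc$end - 500, nuc$start)))
    }

    qb <- findInterval(queries$src_pos, blocks$src_start)
    hit_rows <- list()
    for (cp in seq_len(n_copies)) {
      sub <- bm[bm$copy == cp, ]
      mi <- match(qb, sub$block_id)
      retained <- cp == 1L | stats::runif(nrow(queries)) < cfg$retention
      observed <- retained & stats::runif(nrow(queries)) >= cfg$hit_loss
      k <- which(observed & !is.na(mi))
      if (length(k))
        hit_rows[[cp]] <- data.frame(
          query_id = queries$query_id[k], query_kind = queries$query_kind[k],
          target_chrom = sub$chrom[mi[k]],
          target_pos = sub$tgt_start[mi[k]] +
            (queries$src_pos[k] - sub$src_start[mi[k]]),
          src_pos = queries$src_pos[k])
    }
    hits <- do.call(rbind, hit_rows)
    if (is.null(hits))
      hits <- data.frame(query_id = character(0), query_kind = character(0),
                         target_chrom = character(0), target_pos = numeric(0),
                         src_pos = numeric(0))

    gb <- findInterval(truth$genes$start, blocks$src_start)
    gene_rows <- list()
    for (cp in seq_len(n_copies)) {
      sub <- bm[bm$copy == cp, ]
      mi <- match(gb, sub$block_id)
      retained <- cp == 1L | stats::runif(nrow(truth$genes)) < cfg$retention
      k <- which(retained & !is.na(mi))
      if (length(k))
        gene_rows[[cp]] <- data.frame(
          gene_id = truth$genes$gene_id[k], chrom = sub$chrom[mi[k]],
          start = sub$tgt_start[mi[k]] +
            (truth$genes$start[k] - sub$src_start[mi[k]]),
          end = sub$tgt_start[mi[k]] +
            (pmin(truth$genes$end[k], sub$src_end[mi[k]]) - sub$src_start[mi[k]]))
    }
    genes <- do.call(rbind, gene_rows)
    rownames(hits) <- rownames(genes) <- rownames(bm) <- NULL
    list(chrom_lengths = chrom_lengths, block_map = bm, hits = hits,
         genes = genes, queries = queries, n_wgd = n_wgd)
  })
}

#' Invert a comparator hit position back to source coordinates
#'
#' @param comparator A [simulate_comparator()] result.
#' @param chrom,pos Target chromosome and position.
#' @return Source genome position.
#' @export
invert_block_map <- function(comparator, chrom, pos) {
  bm <- comparator$block_map
  out <- rep(NA_real_, length(pos))
  for (i in seq_along(pos)) {
    b <- bm[bm$chrom == chrom[i] & bm$tgt_start <= pos[i] &
              bm$tgt_start + (bm$src_end - bm$src_start) > pos[i], ]
    if (nrow(b)) out[i] <- b$src_start[1] + (pos[i] - b$tgt_start[1])
  }
  out
}

#' Evaluate an assembly against simulation truth
#'
#' True overlap edges are clone pairs (usable fingerprints, same source
#' space, non-chimeric) whose placements overlap by at least `min_overlap`
#' bp and whose noise-free band profiles share at least the pair's Sulston
#' matching-band threshold. Precision is the fraction of co-contiged clone
#' pairs that genuinely overlap or are connected in the true overlap
#' graph; recall is the fraction of true edges co-contiged; purity is the
#' largest truth-component share per contig, averaged over contigs.
#'
#' @param assembly An `fp_assembly` object.
#' @param truth A [simulate_genome()] result.
#' @param clones Clone table from [simulate_library()].
#' @param params [score_params()] in force (tolerance/gel/cutoff).
#' @param min_overlap Minimum genomic overlap (bp) counted as true
#'   (default 1).
#' @return List of metrics (`precision`, `recall`, `purity`, `n_edges`,
#'   `n_pairs`, `precision_defined`).
#' @export
evaluate_assembly <- function(assembly, truth, clones, params,
                              min_overlap = 1) {
  stopifnot(inherits(assembly, "fp_assembly"))
  profiles0 <- simulate_fingerprints(truth, clones, "AGAROSE", seed = 0L,
                                     noise = FALSE)
  nb <- lengths(lapply(profiles0, `[[`, "bands"))
  usable <- clones$clone_id[!clones$failed & !clones$chimeric &
                              is.na(clones$contaminated_from) &
                              nb[clones$clone_id] >= 2L]
  cl <- clones[match(usable, clones$clone_id), ]

  edges <- list()
  for (space in unique(cl$source)) {
    s <- cl[cl$source == space, ]
    s <- s[order(s$start), ]
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1L)) {
      j <- i + 1L
      while (j <= nrow(s) && s$start[j] < s$end[i] - min_overlap + 1) {
        a <- profiles0[[s$clone_id[i]]]$bands
        b <- profiles0[[s$clone_id[j]]]$bands
        m <- cpp_match_count(a, b, params$tolerance, params$channel_span)
        thr <- .min_match_threshold2(length(a), length(b), params)
        if (!is.na(thr) && m >= thr)
          edges[[length(edges) + 1L]] <- c(s$clone_id[i], s$clone_id[j])
        j <- j + 1L
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(usable)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership

  overlap_ok <- function(a, b) {
    ia <- match(a, cl$clone_id); ib <- match(b, cl$clone_id)
    cl$source[ia] == cl$source[ib] &
      pmin(cl$end[ia], cl$end[ib]) - pmax(cl$start[ia], cl$start[ib]) >=
      min_overlap
  }

  pair_rows <- list()
  for (ct in assembly$contigs) {
    mem <- intersect(ct$members, usable)
    if (length(mem) >= 2L) {
      idx <- utils::combn(sort(mem), 2L)
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(a = idx[1, ], b = idx[2, ], contig = ct$contig_id)
    }
  }
  pairs <- do.call(rbind, pair_rows)

  if (is.null(pairs) || !nrow(pairs)) {
    precision <- 1; precision_defined <- FALSE
  } else {
    correct <- overlap_ok(pairs$a, pairs$b) |
      comp[pairs$a] == comp[pairs$b]
    precision <- mean(correct); precision_defined <- TRUE
  }

  cmap <- .clone_contig_map(assembly)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    same <- !is.na(cmap[em[, 1]]) & !is.na(cmap[em[, 2]]) &
      cmap[em[, 1]] == cmap[em[, 2]]
    recall <- mean(same)
  } else recall <- NA_real_

  purity <- if (length(assembly$contigs)) {
    mean(vapply(assembly$contigs, function(ct) {
      mem <- intersect(ct$members, usable)
      if (!length(mem)) return(1)
      max(table(comp[mem])) / length(mem)
    }, numeric(1)))
  } else NA_real_

  list(precision = precision, recall = recall, purity = purity,
       n_edges = length(edges),
       n_pairs = if (is.null(pairs)) 0L else nrow(pairs),
       precision_defined = precision_defined)
}

#' True linkage group of each clone
#'
#' Group of the clone midpoint on the simulated genome (used to score
#' anchoring accuracy).
#' @param truth A `genome_truth`.
#' @param clones Clone table.
#' @return Named integer vector clone -> group.
#' @export
true_clone_groups <- function(truth, clones) {
  mid <- (clones$start + clones$end) / 2
  grp <- findInterval(mid, truth$group_starts, rightmost.closed = TRUE)
  grp <- pmin(pmax(grp, 1L), truth$cfg$n_groups)
  grp[clones$source != "nuclear"] <- NA_integer_
  stats::setNames(as.integer(grp), clones$clone_id)
}
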