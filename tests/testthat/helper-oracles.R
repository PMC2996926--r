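# Independent oracles and deterministic fixtures used across the suite.

# Exhaustive maximum bipartite matching under |a - b| <= tol, by recursion
# over a's bands (each matched to any unused partner or skipped). Only for
# small inputs; independent of the greedy two-pointer implementation.
brute_max_matching <- function(a, b, tol) {
  n <- length(a)
  rec <- function(i, used) {
    if (i > n) return(0L)
    best <- rec(i + 1L, used)               # skip a[i]
    for (j in seq_along(b)) {
      if (!used[j] && abs(a[i] - b[j]) <= tol) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, length(b)))
}

# Brute-force pooled-hybridization deconvolution for a k x k row/col/diag
# design: candidates recomputed from scratch over the whole grid, minimal
# covers enumerated by bitmask.
brute_deconvolve <- function(grid_k, probe_positions, positive) {
  # probe_positions: data.frame(probe_id, row, col)
  pools_of <- function(r, c)
    c(sprintf("ROW_%d", r), sprintf("COL_%d", c),
      sprintf("DIAG_%d", (r + c) %% grid_k))
  cand <- probe_positions[
    vapply(seq_len(nrow(probe_positions)), function(i)
      all(pools_of(probe_positions$row[i], probe_positions$col[i]) %in%
            positive), logical(1)), , drop = FALSE]
  n <- nrow(cand)
  if (n == 0L) return(list(status = "INCONSISTENT", covers = list()))
  covers <- list()
  for (mask in seq_len(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    u <- unique(unlist(lapply(sel, function(i)
      pools_of(cand$row[i], cand$col[i]))))
    if (setequal(u, positive)) covers[[length(covers) + 1L]] <- sel
  }
  if (!length(covers)) return(list(status = "INCONSISTENT", covers = list()))
  minimal <- Filter(function(s)
    !any(vapply(covers, function(t)
      length(t) < length(s) && all(t %in% s), logical(1))), covers)
  status <- if (length(minimal) == 1L) "UNIQUE" else "AMBIGUOUS"
  list(status = status,
       covers = lapply(minimal, function(s) sort(cand$probe_id[s])))
}

# Deterministic, well-separated band blocks: block k holds values
# base + (k-1)*width + gap * 0:(n-1); blocks never tolerance-match each
# other for gap > 2 * tol.
band_block <- function(block, n, gap = 30L, width = 600L, base = 100L) {
  as.integer(base + (block - 1L) * width + gap * (0:(n - 1L)))
}

mk_profile <- function(id, bands, method = "AGAROSE", ...) {
  band_profile(id, bands, method = method, ...)
}

# Two 17-band agarose clones sharing exactly `m` bands (identical values,
# so the share count is tolerance-independent), remaining bands isolated.
shared_pair <- function(m = 11L, n_a = 17L, n_b = 17L) {
  shared <- band_block(1, m)
  ua <- band_block(3, n_a - m)
  ub <- band_block(5, n_b - m)
  list(a = mk_profile("A", c(shared, ua)), b = mk_profile("B", c(shared, ub)))
}

# The HICF-support merge fixture: two 2-clone agarose contigs whose facing
# terminal clones (17 and 18 bands) share exactly 11 bands; the facing
# pair is co-member of one HICF contig. At tolerance 8 / cutoff 1e-10 the
# pair scores 1.55e-10 (no preliminary join); at tolerance 7 it scores
# 3.85e-11 (join only under the two-denary HICF relaxation of 1e-12).
fig1c_fixture <- function() {
  shared11 <- band_block(1, 11)              # A2/B1 overlap
  u6 <- band_block(3, 6)                     # A-side private bands
  v7 <- band_block(5, 7)                     # B-side private bands
  a1_extra <- band_block(7, 4)
  b2_extra <- band_block(8, 4)
  profiles <- list(
    A1 = mk_profile("A1", c(shared11[1:7], u6, a1_extra)),       # 17 bands
    A2 = mk_profile("A2", c(shared11, u6)),                      # 17 bands
    B1 = mk_profile("B1", c(shared11, v7)),                      # 18 bands
    B2 = mk_profile("B2", c(shared11[1:6], v7, b2_extra)))       # 17 bands
  hicf_shared <- as.integer(seq(11, 1990, by = 13))              # channel 1
  hicf <- list(
    A1 = mk_profile("A1", band_block(1, 150, gap = 11, width = 2000,
                                     base = 2001), "HICF"),
    A2 = mk_profile("A2", hicf_shared, "HICF"),
    B1 = mk_profile("B1", hicf_shared, "HICF"),
    B2 = mk_profile("B2", band_block(1, 150, gap = 11, width = 2000,
                                     base = 6001), "HICF"))
  list(profiles = profiles, hicf = hicf)
}

# A staircase contig: clones sliding along a consensus of `n_cons` spaced
# bands, each clone `n_clone` bands wide, stepping by `step` bands.
staircase_profiles <- function(n_clones = 5L, n_clone = 20L, step = 8L,
                               gap = 40L) {
  cons <- as.integer(100L + gap * (0:(n_clone + step * (n_clones - 1L))))
  profs <- lapply(seq_len(n_clones), function(i) {
    ix <- (1L + step * (i - 1L)):(n_clone + step * (i - 1L))
    mk_profile(sprintf("S%d", i), cons[ix])
  })
  names(profs) <- vapply(profs, `[[`, "", "clone_id")
  attr(profs, "consensus_size") <- length(cons)
  profs
}

# Small noise-free simulated world shared by several tests.
sim_world <- function(genome_bp = 3e6, seed = 42, noise = FALSE,
                      probe_count = 60, ...) {
  cfg <- sim_config(genome_bp = genome_bp, noise = noise,
                    probe_count = probe_count, ...)
  truth <- simulate_genome(cfg, seed)
  clones <- simulate_library(truth, derive_seed(seed, 1))
  profiles <- simulate_fingerprints(truth, clones, "AGAROSE",
                                    derive_seed(seed, 2))
  list(cfg = cfg, truth = truth, clones = clones, profiles = profiles)
}
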