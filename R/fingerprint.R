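#' Band profile of a fingerprinted clone
#'
#' Holds the scoreable restriction-fragment bands of one BAC clone, either
#' from a single-enzyme agarose gel (band positions are migration units in
#' `[1, gel_length]`) or from a multi-enzyme HICF run (composite
#' channel-offset units, `band = channel_index * channel_span + size_unit`).
#' Bands are sorted ascending and comigrating duplicates are merged.
#'
#' @param clone_id Clone name.
#' @param bands Integer vector of band positions (any order; duplicates are
#'   merged as comigrating fragments).
#' @param method `"AGAROSE"` or `"HICF"`.
#' @param plate,well_row,well_col Microplate address (used by cross-well
#'   contamination screening); `NA` when unknown.
#' @param batch Fingerprinting batch (used by band-count outlier screening).
#' @return An object of class `band_profile`.
#' @export
band_profile <- function(clone_id, bands, method = c("AGAROSE", "HICF"),
                         plate = NA_integer_, well_row = NA_integer_,
                         well_col = NA_integer_, batch = NA_integer_) {
  method <- match.arg(method)
  stopifnot(is.character(clone_id), length(clone_id) == 1L, nzchar(clone_id))
  bands <- as.integer(bands)
  if (anyNA(bands)) stop("bands must be integer and non-missing")
  if (any(bands < 1L)) stop("band positions must be >= 1")
  bands <- sort(unique(bands))
  structure(
    list(clone_id = clone_id, method = method, bands = bands,
         plate = as.integer(plate), well_row = as.integer(well_row),
         well_col = as.integer(well_col), batch = as.integer(batch)),
    class = "band_profile")
}

#' @export
print.band_profile <- function(x, ...) {
  cat(sprintf("<band_profile> %s [%s] %d bands\n", x$clone_id, x$method,
              length(x$bands)))
  invisible(x)
}

#' Scoring parameters for Sulston overlap calling
#'
#' @param tolerance Maximum band-position difference (gel units) for two
#'   bands to be called matching. FPC-style defaults: 8 for preliminary
#'   agarose, 7 for integrated agarose, 3 for HICF.
#' @param gel_length Length of the gel in band units (5000 for agarose).
#'   For HICF with composite band encoding this is
#'   `channels * channel_span`.
#' @param cutoff Sulston probability at or below which an overlap is called.
#' @param channel_span For HICF composite encoding, the per-channel unit
#'   span (bands only match within the same channel); 0 disables channels.
#' @return An object of class `score_params`.
#' @export
score_params <- function(tolerance = 7L, gel_length = 5000L, cutoff = 1e-12,
                         channel_span = 0L) {
  tolerance <- as.integer(tolerance); gel_length <- as.integer(gel_length)
  channel_span <- as.integer(channel_span)
  if (!(tolerance > 0L && tolerance < gel_length))
    stop("need 0 < tolerance < gel_length")
  if (!(is.numeric(cutoff) && cutoff > 0 && cutoff <= 1))
    stop("cutoff must lie in (0, 1]")
  structure(list(tolerance = tolerance, gel_length = gel_length,
                 cutoff = cutoff, channel_span = channel_span),
            class = "score_params")
}

#' HICF scoring defaults
#'
#' Convenience constructor for the 5-channel HICF scheme: tolerance 3,
#' per-channel span 2000 units, cutoff 1e-50.
#' @param cutoff Sulston cutoff (default 1e-50).
#' @param channels Number of enzyme channels.
#' @param channel_span Units per channel.
#' @return A `score_params` object.
#' @export
hicf_params <- function(cutoff = 1e-50, channels = 5L, channel_span = 2000L) {
  score_params(tolerance = 3L, gel_length = channels * channel_span,
               cutoff = cutoff, channel_span = channel_span)
}

#' Lander-Waterman parameters
#'
#' @param genome_bp Genome size in bp.
#' @param avg_band_bp Average restriction band size in bp (the genome length
#'   used by the formula is `genome_bp / avg_band_bp` in band units).
#' @param n_clones Number of fingerprinted clones.
#' @param avg_bands Average scoreable bands per clone (clone "length" L).
#' @param min_match Matching bands needed to call an overlap (T).
#' @return An object of class `lw_params`.
#' @export
lw_params <- function(genome_bp, avg_band_bp, n_clones, avg_bands, min_match) {
  vals <- c(genome_bp, avg_band_bp, n_clones, avg_bands, min_match)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Lander-Waterman parameters must be positive")
  if (min_match > avg_bands) stop("min_match must be <= avg_bands")
  structure(list(genome_bp = genome_bp, avg_band_bp = avg_band_bp,
                 n_clones = n_clones, avg_bands = avg_bands,
                 min_match = min_match), class = "lw_params")
}

#' Match bands of two fingerprints
#'
#' Greedy two-pointer matching of two ascending band lists under a position
#' tolerance; each band is used at most once and the earliest available
#' partner is taken. On sorted inputs this attains the maximum bipartite
#' matching under the threshold criterion.
#'
#' @param a,b Ascending integer band vectors.
#' @param tolerance Maximum position difference for a match.
#' @param channel_span Optional HICF channel span (0 = none); bands only
#'   match within the same channel.
#' @return A list with `count` (matched band pairs) and `pairs`
#'   (two-column matrix of 1-based indices into `a` and `b`).
#' @export
match_bands <- function(a, b, tolerance, channel_span = 0L) {
  a <- as.integer(a); b <- as.integer(b)
  if (is.unsorted(a) || is.unsorted(b))
    stop("band lists must be sorted ascending")
  p <- cpp_match_pairs(a, b, as.integer(tolerance), as.integer(channel_span))
  list(count = nrow(p), pairs = p)
}

## Log-space binomial upper tail: P(X >= m), X ~ Binomial(n, lambda),
## computed with exact log binomial coefficients (no normal approximation).
.binom_tail <- function(n, lambda, m) {
  if (m <= 0) return(1)
  if (m > n) return(0)
  if (lambda <= 0) return(0)
  if (lambda >= 1) return(1)
  k <- m:n
  lt <- lchoose(n, k) + k * log(lambda) + (n - k) * log1p(-lambda)
  mx <- max(lt)
  exp(mx + log(sum(exp(lt - mx))))
}

#' Sulston overlap score
#'
#' Probability that two unrelated clones with `n_a` and `n_b` uniformly
#' placed bands share at least `m` matching bands by chance. With
#' `n_lo = min(n_a, n_b)`, `n_hi = max(n_a, n_b)`, single-band match
#' probability `p = 2 * tolerance / gel_length` and
#' `lambda = 1 - (1 - p)^n_hi`, the score is the exact binomial upper tail
#' `sum_{k=m}^{n_lo} C(n_lo, k) lambda^k (1-lambda)^(n_lo-k)`, evaluated in
#' log space.
#'
#' @param n_a,n_b Band counts of the two clones.
#' @param m Number of matching bands observed.
#' @param params A [score_params()] object (tolerance, gel length).
#' @return The overlap probability in `[0, 1]`.
#' @export
sulston_score <- function(n_a, n_b, m, params) {
  stopifnot(inherits(params, "score_params"))
  if (m < 0 || m > min(n_a, n_b))
    stop("m must satisfy 0 <= m <= min(n_a, n_b)")
  .sulston(n_a, n_b, m, params$tolerance, params$gel_length)
}

.sulston <- function(n_a, n_b, m, tolerance, gel_length) {
  n_lo <- min(n_a, n_b); n_hi <- max(n_a, n_b)
  p <- 2 * tolerance / gel_length
  lambda <- -expm1(n_hi * log1p(-p))
  .binom_tail(n_lo, lambda, m)
}

## Vectorised over pairs (n_a, n_b, m equal-length vectors).
.sulston_vec <- function(n_a, n_b, m, tolerance, gel_length) {
  vapply(seq_along(m), function(i)
    .sulston(n_a[i], n_b[i], m[i], tolerance, gel_length), numeric(1))
}

#' Call an overlap between two fingerprints
#'
#' @param pa,pb [band_profile()] objects of the same method.
#' @param params A [score_params()] object.
#' @param effective_cutoff Cutoff to compare against (defaults to
#'   `params$cutoff`); see [effective_cutoff()] for marker-based relaxation.
#' @return List with `accepted`, `score` and `match_count`. Degenerate
#'   clones (< 2 bands) are never accepted.
#' @export
call_overlap <- function(pa, pb, params, effective_cutoff = params$cutoff) {
  stopifnot(inherits(pa, "band_profile"), inherits(pb, "band_profile"),
            inherits(params, "score_params"))
  if (pa$method != pb$method)
    stop("cannot compare AGAROSE and HICF fingerprints directly")
  n_a <- length(pa$bands); n_b <- length(pb$bands)
  if (n_a < 2L || n_b < 2L)
    return(list(accepted = FALSE, score = 1, match_count = 0L))
  m <- cpp_match_count(pa$bands, pb$bands, params$tolerance,
                       params$channel_span)
  s <- sulston_score(n_a, n_b, m, params)
  list(accepted = s <= effective_cutoff, score = s, match_count = m)
}

## Smallest j with S(n_a, n_b, j) <= cutoff, or NA when unreachable.
.min_match_threshold2 <- function(n_a, n_b, params, cutoff = params$cutoff) {
  n_lo <- min(n_a, n_b)
  for (j in 0:n_lo) {
    if (.sulston(n_a, n_b, j, params$tolerance, params$gel_length) <= cutoff)
      return(j)
  }
  NA_integer_
}

#' Minimum matching bands needed to call an overlap
#'
#' Smallest integer `j` such that `sulston_score(n, n, j) <= cutoff`, found
#' by upward scan of the exact binomial tail.
#'
#' @param n Band count of both clones.
#' @param params A [score_params()] object (its `cutoff` is used).
#' @return Integer threshold, or `NA` when even `j = n` fails (too few
#'   bands to ever support an overlap at this cutoff).
#' @export
min_match_threshold <- function(n, params) {
  stopifnot(inherits(params, "score_params"), n >= 1)
  .min_match_threshold2(n, n, params)
}

#' Minimum informative band count
#'
#' Smallest band count `n` at which two clones sharing all `n` bands reach
#' the cutoff, i.e. `sulston_score(n, n, n) <= cutoff`. Clones with fewer
#' bands cannot form statistically supported joins even with identical band
#' patterns. Exact log-space arithmetic matters here: near the default
#' cutoff the preceding `n` misses by under 5%.
#'
#' @param params A [score_params()] object with `cutoff < 1`.
#' @return Integer band count.
#' @export
min_informative_band_count <- function(params) {
  stopifnot(inherits(params, "score_params"))
  if (params$cutoff >= 1) stop("cutoff must be < 1")
  n <- 1L
  repeat {
    if (.sulston(n, n, n, params$tolerance, params$gel_length) <=
        params$cutoff) return(n)
    n <- n + 1L
    if (n > 10000L) stop("no informative band count below 10000")
  }
}

#' Expected contig count (Lander-Waterman)
#'
#' `E = N * exp(-(L * N / G) * (1 - T / L))` with `G = genome_bp /
#' avg_band_bp` the genome length in band units, `L` the average bands per
#' clone, `N` the clone count and `T` the matching bands needed to call an
#' overlap.
#'
#' @param lw An [lw_params()] object.
#' @return Expected number of contigs (islands of two or more clones plus
#'   apparent singleton islands, per the classic island formula).
#' @export
expected_contigs <- function(lw) {
  stopifnot(inherits(lw, "lw_params"))
  G <- lw$genome_bp / lw$avg_band_bp
  lw$n_clones * exp(-(lw$avg_bands * lw$n_clones / G) *
                      (1 - lw$min_match / lw$avg_bands))
}

#' Monte-Carlo tally of chance band matches
#'
#' Simulates the Sulston null directly: two clones of `n` bands each at
#' independent continuous-uniform positions on `(0, gel_length)`. Per
#' trial, counts the bands of the first clone with at least one band of
#' the second within the tolerance (neighbour reuse allowed — the event
#' whose count the score's binomial model describes; maximum matching
#' without reuse is a strictly smaller count and is not the modelled
#' quantity). Uses R's RNG: call `set.seed()` first for reproducibility.
#'
#' @param n Bands per clone.
#' @param params A [score_params()] object (tolerance, gel length).
#' @param trials Number of Monte-Carlo trials.
#' @return Integer vector of length `n + 1`: entry `k + 1` counts trials
#'   with exactly `k` matched bands. `rev(cumsum(rev(tally)))/trials`
#'   gives the empirical `P(>= m)` curve comparable to [sulston_score()].
#' @export
sulston_mc_tally <- function(n, params, trials = 1e6) {
  stopifnot(inherits(params, "score_params"), n >= 1, trials >= 1)
  cpp_sulston_mc(as.integer(n), params$tolerance, params$gel_length,
                 as.integer(trials))
}

#' Marker-based cutoff relaxation
#'
#' Shared hybridization markers (or shared HICF contig membership) between
#' two clones relax the Sulston cutoff by 2, 3 or 4 denary intervals for 1,
#' 2 and 3+ shared markers respectively, capped at a relaxation floor.
#'
#' @param base Base cutoff probability.
#' @param shared_evidence Number of shared markers (>= 0).
#' @param floor Most relaxed cutoff ever allowed (default 1e-6).
#' @return The effective cutoff.
#' @export
effective_cutoff <- function(base, shared_evidence, floor = 1e-6) {
  stopifnot(all(shared_evidence >= 0))
  steps <- c(0, 2, 3, 4)[pmin(shared_evidence, 3) + 1]
  pmin(base * 10^steps, pmax(base, floor))
}
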