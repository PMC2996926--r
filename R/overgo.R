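#' Build a pooled-overgo hybridization design
#'
#' Probes fill a `grid_k` x `grid_k` array row-major; pools are the rows,
#' columns and (wrapped) diagonals of the grid, so every probe lies in
#' exactly three pools and any two distinct probes share at most one pool.
#'
#' @param probe_ids Ordered probe names (at most `grid_k^2`).
#' @param grid_k Grid dimension (default 24, i.e. 576 probes in 72 pools).
#' @param diagonal Diagonal convention, `(row + col) %% k` (`"plus"`,
#'   default) or `(row - col) %% k` (`"minus"`).
#' @return An object of class `pool_design` with `positions` (probe, row,
#'   col, the three pool ids) and `pools` (pool id -> probe ids).
#' @export
build_pool_design <- function(probe_ids, grid_k = 24L,
                              diagonal = c("plus", "minus")) {
  diagonal <- match.arg(diagonal)
  grid_k <- as.integer(grid_k)
  n <- length(probe_ids)
  if (n > grid_k^2) stop("more probes than grid positions")
  if (anyDuplicated(probe_ids)) stop("probe ids must be unique")
  idx <- seq_len(n) - 1L
  row <- idx %/% grid_k
  col <- idx %% grid_k
  d <- if (diagonal == "plus") (row + col) %% grid_k else (row - col) %% grid_k
  positions <- data.frame(probe_id = probe_ids, row = row, col = col,
                          pool_row = sprintf("ROW_%d", row),
                          pool_col = sprintf("COL_%d", col),
                          pool_diag = sprintf("DIAG_%d", d),
                          stringsAsFactors = FALSE)
  pool_ids <- c(sprintf("ROW_%d", 0:(grid_k - 1L)),
                sprintf("COL_%d", 0:(grid_k - 1L)),
                sprintf("DIAG_%d", 0:(grid_k - 1L)))
  pools <- lapply(stats::setNames(pool_ids, pool_ids), function(p)
    positions$probe_id[positions$pool_row == p | positions$pool_col == p |
                         positions$pool_diag == p])
  structure(list(grid_k = grid_k, diagonal = diagonal,
                 positions = positions, pools = pools),
            class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("<pool_design> %dx%d grid, %d probes, %d pools\n", x$grid_k,
              x$grid_k, nrow(x$positions), length(x$pools)))
  invisible(x)
}

## Pools of one probe, as a character vector.
.probe_pools <- function(design, probe_id) {
  p <- design$positions[design$positions$probe_id == probe_id, ]
  c(p$pool_row, p$pool_col, p$pool_diag)
}

## All inclusion-minimal subsets of candidate probes whose pooled signature
## equals the positive pool set. Exact enumeration; candidate sets are small
## by construction of the grid.
.minimal_covers <- function(pool_sets, positive, max_candidates = 16L) {
  n <- length(pool_sets)
  if (n == 0L || n > max_candidates) return(list())
  covers <- list()
  for (mask in seq_len(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    u <- unique(unlist(pool_sets[sel], use.names = FALSE))
    if (length(u) == length(positive) && all(positive %in% u))
      covers[[length(covers) + 1L]] <- sel
  }
  if (!length(covers)) return(list())
  minimal <- vapply(covers, function(s)
    !any(vapply(covers, function(t)
      length(t) < length(s) && all(t %in% s), logical(1))), logical(1))
  covers[minimal]
}

#' Deconvolve pooled hybridization hits into probe assignments
#'
#' For each BAC, candidate probes are the grid positions whose row, column
#' and diagonal pools are all positive; the retained probe sets are the
#' inclusion-minimal covers of the positive pool set. Exactly one minimal
#' cover gives status `UNIQUE`, several give `AMBIGUOUS`, none gives
#' `INCONSISTENT`.
#'
#' @param design A [build_pool_design()] object.
#' @param hits Data.frame with `bac_id`, `pool_id` (positive pools per BAC).
#' @return Data.frame with `bac_id`, `probe_id` (comma-joined for
#'   non-unique statuses the union over minimal covers), `status`; one row
#'   per (bac, probe) for UNIQUE assignments.
#' @export
deconvolve <- function(design, hits) {
  stopifnot(inherits(design, "pool_design"))
  unknown <- setdiff(unique(hits$pool_id), names(design$pools))
  if (length(unknown))
    stop("unknown pool id(s): ", paste(unknown, collapse = ", "))
  out <- list()
  pos <- design$positions
  for (bac in sort(unique(hits$bac_id))) {
    positive <- unique(hits$pool_id[hits$bac_id == bac])
    cand <- pos[pos$pool_row %in% positive & pos$pool_col %in% positive &
                  pos$pool_diag %in% positive, ]
    pool_sets <- lapply(seq_len(nrow(cand)), function(i)
      c(cand$pool_row[i], cand$pool_col[i], cand$pool_diag[i]))
    covers <- .minimal_covers(pool_sets, positive)
    if (length(covers) == 0L) {
      out[[bac]] <- data.frame(bac_id = bac, probe_id = NA_character_,
                               status = "INCONSISTENT")
    } else if (length(covers) == 1L) {
      out[[bac]] <- data.frame(bac_id = bac,
                               probe_id = cand$probe_id[covers[[1L]]],
                               status = "UNIQUE")
    } else {
      union_probes <- sort(unique(cand$probe_id[unlist(covers)]))
      out[[bac]] <- data.frame(bac_id = bac,
                               probe_id = paste(union_probes, collapse = ","),
                               status = "AMBIGUOUS")
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(bac_id = character(0), probe_id = character(0),
                      status = character(0))
  rownames(res) <- NULL
  res
}

#' Classify a probe by its total library hit count
#'
#' Low copy is 29 hits or fewer, highly repetitive is 100 or more, the rest
#' are moderately repetitive. Probes with 30+ hits are excluded from contig
#' anchoring; probes with more than 50 hits are excluded from contig
#' assembly. Flags compose with the class.
#'
#' @param total_hits Integer vector of per-probe total BAC hits.
#' @return Data.frame with `total_hits`, `class` (`LOW`/`MODERATE`/`HIGH`),
#'   `assembly_excluded`, `anchoring_excluded`.
#' @export
classify_probe <- function(total_hits) {
  stopifnot(all(total_hits >= 0))
  cls <- ifelse(total_hits <= 29L, "LOW",
                ifelse(total_hits >= 100L, "HIGH", "MODERATE"))
  data.frame(total_hits = total_hits, class = cls,
             assembly_excluded = total_hits > 50L,
             anchoring_excluded = total_hits >= 30L)
}

#' Design overgo candidate windows from a source sequence
#'
#' The sequence is chopped into consecutive non-overlapping windows of the
#' probe length; windows containing `N` are rejected and the rest are
#' screened for GC content (computed over ACGT only).
#'
#' @param sequence Nucleotide string over `A/C/G/T/N` (case-insensitive).
#' @param length Window length in bp (default 40).
#' @param gc_min,gc_max GC-content bounds (default 0.40-0.60).
#' @return Data.frame with `start` (1-based), `end`, `seq`, `gc` for the
#'   accepted windows.
#' @export
design_overgos <- function(sequence, length = 40L, gc_min = 0.40,
                           gc_max = 0.60) {
  sequence <- toupper(as.character(sequence)[1])
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over A/C/G/T/N")
  n_win <- nchar(sequence) %/% length
  if (n_win == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), gc = numeric(0)))
  starts <- (seq_len(n_win) - 1L) * length + 1L
  seqs <- substring(sequence, starts, starts + length - 1L)
  gc <- vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    acgt <- sum(chars %in% c("A", "C", "G", "T"))
    if (acgt == 0L) return(NA_real_)
    sum(chars %in% c("G", "C")) / acgt
  }, numeric(1), USE.NAMES = FALSE)
  keep <- !grepl("N", seqs, fixed = TRUE) & !is.na(gc) &
    gc >= gc_min & gc <= gc_max
  data.frame(start = starts[keep], end = starts[keep] + length - 1L,
             seq = seqs[keep], gc = gc[keep])
}

#' Design overgo candidates from a FASTA file
#'
#' Applies [design_overgos()] to every sequence in a FASTA file.
#'
#' @param path FASTA file of probe source sequences.
#' @param ... Passed to [design_overgos()].
#' @return Data.frame with `source_id` plus the [design_overgos()]
#'   columns.
#' @export
design_overgos_fasta <- function(path, ...) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    w <- design_overgos(as.character(seqs[[i]]), ...)
    if (nrow(w)) cbind(source_id = names(seqs)[i], w) else NULL
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(source_id = character(0), start = integer(0),
                      end = integer(0), seq = character(0),
                      gc = numeric(0))
  res
}

#' Read/write pooled-hybridization tables
#'
#' Pool designs are stored as TSV (`probe_id`, `row`, `col`); pool hits as
#' TSV (`bac_id`, `pool_id`).
#' @param design A `pool_design`.
#' @param path File path.
#' @return See each function.
#' @export
write_pool_design <- function(design, path) {
  write_tsv(design$positions[c("probe_id", "row", "col")], path)
  invisible(path)
}

#' @rdname write_pool_design
#' @param grid_k,diagonal Passed to [build_pool_design()].
#' @export
read_pool_design <- function(path, grid_k = 24L, diagonal = "plus") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  build_pool_design(df$probe_id, grid_k = grid_k, diagonal = diagonal)
}
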