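#' Read an FPC "sizes" file
#'
#' The sizes dialect stores one record per clone: a line with the clone
#' name and band count separated by whitespace, one band value per line,
#' and a `-1` terminator line.
#'
#' @param path File path.
#' @param method Fingerprinting method to stamp on the profiles.
#' @return Named list of [band_profile()] objects (names = clone ids).
#' @export
read_sizes <- function(path, method = c("AGAROSE", "HICF")) {
  method <- match.arg(method)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  profiles <- list()
  i <- 1L
  while (i <= length(lines)) {
    head <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(head) != 2L || is.na(suppressWarnings(as.integer(head[2]))))
      stop(sprintf("sizes parse error at line %d: expected '<clone> <nbands>'", i))
    clone <- head[1]
    nb <- as.integer(head[2])
    if (i + nb + 1L > length(lines))
      stop(sprintf("sizes parse error: record '%s' at line %d truncated",
                   clone, i))
    bands <- suppressWarnings(as.integer(lines[(i + 1L):(i + nb)]))
    if (nb > 0L && anyNA(bands))
      stop(sprintf("sizes parse error: non-integer band in record '%s' (line %d)",
                   clone, i))
    if (nb == 0L) bands <- integer(0)
    term <- lines[i + nb + 1L]
    if (term != "-1")
      stop(sprintf("sizes parse error: missing -1 terminator for '%s' at line %d",
                   clone, i + nb + 1L))
    profiles[[clone]] <- band_profile(clone, bands, method)
    i <- i + nb + 2L
  }
  profiles
}

#' Write an FPC "sizes" file
#'
#' @param profiles Named list of [band_profile()] objects.
#' @param path Output path.
#' @return `path`, invisibly. `read_sizes(write_sizes(x))` restores the
#'   band content exactly.
#' @export
write_sizes <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    writeLines(sprintf("%s %d", p$clone_id, length(p$bands)), con)
    if (length(p$bands)) writeLines(format(p$bands, scientific = FALSE,
                                           trim = TRUE), con)
    writeLines("-1", con)
  }
  invisible(path)
}

#' Read a BLAST-tabular hit table
#'
#' Parses the outfmt-6-like subset used for contig-to-genome anchoring:
#' whitespace/tab-separated columns with `qseqid` (1), `sseqid` (2) and
#' `sstart` (9). Positions are converted to 0-based.
#'
#' @param path File path.
#' @return A data.frame with `query_id`, `target_chrom`, `target_pos`
#'   (0-based bp).
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(query_id = character(0), target_chrom = character(0),
                      target_pos = numeric(0)))
  fields <- strsplit(lines, "\t")
  ncol <- lengths(fields)
  if (any(ncol < 9L))
    stop(sprintf("hit table parse error at line %d: fewer than 9 columns",
                 which(ncol < 9L)[1]))
  sstart <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 9L)))
  if (anyNA(sstart))
    stop(sprintf("hit table parse error at line %d: malformed sstart",
                 which(is.na(sstart))[1]))
  data.frame(query_id = vapply(fields, `[[`, "", 1L),
             target_chrom = vapply(fields, `[[`, "", 2L),
             target_pos = sstart - 1)
}

#' Write a BLAST-tabular hit table (outfmt-6-like subset)
#'
#' @param hits Data.frame with `query_id`, `target_chrom`, `target_pos`
#'   (0-based; written 1-based). Unavailable columns are written as
#'   placeholder values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  n <- nrow(hits)
  lines <- sprintf("%s\t%s\t100.00\t40\t0\t0\t1\t40\t%d\t%d\t1e-20\t80.0",
                   hits$query_id, hits$target_chrom,
                   as.integer(hits$target_pos + 1),
                   as.integer(hits$target_pos + 40))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write evidence marker tables
#'
#' Markers are stored long-format as TSV with columns `marker_id`, `kind`
#' (`PROBE` or `HICF_CONTIG`) and `clone_id`.
#'
#' @param path File path.
#' @return Data.frame with `marker_id`, `kind`, `clone_id`.
#' @export
read_markers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "kind", "clone_id")
  if (!all(need %in% names(df)))
    stop("marker table must have columns marker_id, kind, clone_id")
  if (!all(df$kind %in% c("PROBE", "HICF_CONTIG")))
    stop("marker kind must be PROBE or HICF_CONTIG")
  df[need]
}

#' @rdname read_markers
#' @param markers Data.frame with `marker_id`, `kind`, `clone_id`.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a genetic map
#'
#' TSV with columns `marker_id`, `group` (integer linkage group) and `cM`.
#'
#' @param path File path.
#' @param n_groups Number of linkage groups allowed (default 13).
#' @return Data.frame of map loci.
#' @export
read_genetic_map <- function(path, n_groups = 13L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "group", "cM")
  if (!all(need %in% names(df)))
    stop("genetic map must have columns marker_id, group, cM")
  if (any(df$cM < 0)) stop("cM positions must be non-negative")
  if (any(!(df$group %in% seq_len(n_groups))))
    stop(sprintf("groups must lie in 1..%d", n_groups))
  df[need]
}

#' @rdname read_genetic_map
#' @param map Data.frame with `marker_id`, `group`, `cM`.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generic TSV helpers used by the CLI
#'
#' Thin wrappers with stable ordering and no quoting.
#' @param df Data.frame.
#' @param path File path.
#' @return The data.frame (read) or `path` invisibly (write).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write gene intervals as BED (0-based half-open)
#'
#' @param genes Data.frame with `chrom`, `start` (0-based), `end`
#'   (exclusive) and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path) {
  name <- if ("name" %in% names(genes)) genes$name else
    if ("gene_id" %in% names(genes)) genes$gene_id else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", genes$chrom, as.integer(genes$start),
                     as.integer(genes$end), name), path)
  invisible(path)
}

#' Read gene intervals from BED or GFF3
#'
#' BED is parsed directly (0-based half-open kept); GFF3 is read via
#' rtracklayer when available and 1-based inclusive coordinates are
#' converted to 0-based half-open.
#'
#' @param path File path ending in `.bed`, `.gff3` or `.gff`.
#' @return Data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_genes <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    f <- strsplit(lines, "\t")
    if (any(lengths(f) < 3L)) stop("BED parse error: need >= 3 columns")
    return(data.frame(
      chrom = vapply(f, `[[`, "", 1L),
      start = as.numeric(vapply(f, `[[`, "", 2L)),
      end = as.numeric(vapply(f, `[[`, "", 3L)),
      name = vapply(f, function(x) if (length(x) >= 4L) x[[4L]] else ".", "")))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$ID)) as.character(gr$ID) else ".")
}

#' Export an assembly as tables
#'
#' Writes a simplified FPC-style text export (one block per contig with CB
#' extents and member clones) plus TSV contig/singleton tables.
#'
#' @param assembly An `fp_assembly` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assembly <- function(assembly, dir) {
  stopifnot(inherits(assembly, "fp_assembly"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  members <- do.call(rbind, lapply(assembly$contigs, function(ct) {
    data.frame(contig_id = ct$contig_id, clone_id = ct$members,
               cb_offset = unname(ct$offsets[ct$members]),
               q_clone = ct$members %in% ct$q_clones,
               buried_into = ifelse(ct$members %in% names(ct$buried),
                                    ct$buried[ct$members], ""))
  }))
  if (is.null(members))
    members <- data.frame(contig_id = integer(0), clone_id = character(0),
                          cb_offset = numeric(0), q_clone = logical(0),
                          buried_into = character(0))
  contigs <- do.call(rbind, lapply(assembly$contigs, function(ct)
    data.frame(contig_id = ct$contig_id, n_clones = length(ct$members),
               cb_length = ct$cb_length, n_q = length(ct$q_clones))))
  if (is.null(contigs))
    contigs <- data.frame(contig_id = integer(0), n_clones = integer(0),
                          cb_length = integer(0), n_q = integer(0))
  write_tsv(members, file.path(dir, "members.tsv"))
  write_tsv(contigs, file.path(dir, "contigs.tsv"))
  writeLines(assembly$singletons, file.path(dir, "singletons.txt"))
  con <- file(file.path(dir, "assembly.fpc.txt"), "w")
  on.exit(close(con))
  writeLines(sprintf("// fpmap assembly stage=%s contigs=%d singletons=%d",
                     assembly$stage, length(assembly$contigs),
                     length(assembly$singletons)), con)
  for (ct in assembly$contigs) {
    writeLines(sprintf("Ctg%d  CB 0..%d", ct$contig_id, ct$cb_length), con)
    for (cl in ct$members)
      writeLines(sprintf("  %s %g %s", cl, ct$offsets[[cl]],
                         if (cl %in% ct$q_clones) "Q" else ""), con)
  }
  invisible(dir)
}
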