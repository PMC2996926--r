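test_that("repetitive queries are removed at 10 hits", {
  hits <- rbind(
    data.frame(query_id = "rep10", target_chrom = "chr1",
               target_pos = seq(0, 9e6, by = 1e6)),       # 10 hits
    data.frame(query_id = "ok9", target_chrom = "chr1",
               target_pos = seq(0, 8e6, by = 1e6)),       # 9 hits
    data.frame(query_id = "solo", target_chrom = "chr2", target_pos = 5))
  f <- filter_repetitive_queries(hits)
  expect_false("rep10" %in% f$query_id)
  expect_equal(sum(f$query_id == "ok9"), 9L)
  expect_true("solo" %in% f$query_id)
  empty <- hits[0, ]
  expect_equal(nrow(filter_repetitive_queries(empty)), 0L)
})

test_that("window chaining produces maximal >= 2-query anchors", {
  qc <- data.frame(query_id = c("q1", "q2", "q3"),
                   contig_id = c(1L, 1L, 1L))
  h <- data.frame(query_id = c("q1", "q2"), target_chrom = "chr1",
                  target_pos = c(100000, 250000))
  a <- anchor_to_genome(h, qc, 200000)
  expect_equal(nrow(a), 1L)
  expect_equal(a$start, 100000)
  expect_equal(a$end, 250000)

  # gap equal to the window breaks the chain (strict inequality)
  h2 <- data.frame(query_id = c("q1", "q2"), target_chrom = "chr1",
                   target_pos = c(100000, 300000))
  expect_equal(nrow(anchor_to_genome(h2, qc, 200000)), 0L)

  # single-query chains never anchor, even with repeated hits
  h3 <- data.frame(query_id = c("q1", "q1"), target_chrom = "chr1",
                   target_pos = c(100000, 150000))
  expect_equal(nrow(anchor_to_genome(h3, qc, 200000)), 0L)
  expect_error(anchor_to_genome(h, qc, -5), "window")

  # property: anchors are maximal — no unused in-window hit adjoins one
  set.seed(31)
  qc2 <- data.frame(query_id = sprintf("q%02d", 1:40),
                    contig_id = rep(1:8, each = 5))
  hh <- data.frame(query_id = sample(qc2$query_id, 120, replace = TRUE),
                   target_chrom = sample(c("c1", "c2"), 120, replace = TRUE),
                   target_pos = sample.int(3e6, 120))
  win <- 150000
  aa <- anchor_to_genome(hh, qc2, win)
  hm <- merge(hh, qc2, by = "query_id")
  for (i in seq_len(nrow(aa))) {
    others <- hm[hm$contig_id == aa$contig_id[i] &
                   hm$target_chrom == aa$target_chrom[i] &
                   (hm$target_pos < aa$start[i] | hm$target_pos > aa$end[i]), ]
    if (nrow(others))
      expect_true(min(abs(c(others$target_pos - aa$start[i],
                            others$target_pos - aa$end[i]))) >= win)
  }
})

test_that("anchor coverage uses interval union", {
  lens <- c(chr1 = 1e7)
  a1 <- data.frame(contig_id = 1L, target_chrom = "chr1",
                   start = 2e6, end = 3e6, n_queries = 2L, queries = "a,b")
  expect_equal(anchor_coverage(a1, lens), 0.10)
  # full overlap counted once; order independent
  a2 <- rbind(a1, a1)
  expect_equal(anchor_coverage(a2, lens), 0.10)
  a3 <- rbind(a1, transform(a1, start = 2.5e6, end = 3.5e6))
  expect_equal(anchor_coverage(a3, lens), 0.15)
  expect_equal(anchor_coverage(a3[c(2, 1), ], lens), 0.15)
  expect_equal(anchor_coverage(a1[0, ], lens), 0)
})

test_that("gene density counts are conserved and bin by start", {
  lens <- c(c1 = 1e6, c2 = 6e5)
  g <- data.frame(chrom = c("c1", "c1", "c1", "c2"),
                  start = c(0, 100, 199999, 250000),
                  end = c(2000, 2100, 201999, 252000))
  tr <- gene_density(g, lens, bin = 200000)
  expect_equal(sum(tr$count), nrow(g))
  expect_equal(tr$count[tr$chrom == "c1" & tr$bin_index == 0], 3L)
  expect_equal(tr$count[tr$chrom == "c2" & tr$bin_index == 1], 1L)
  expect_equal(nrow(tr), 5 + 3)
  empty <- gene_density(g[0, ], lens)
  expect_true(all(empty$count == 0L))
  # random placement conserves counts
  set.seed(8)
  gr <- data.frame(chrom = sample(names(lens), 200, replace = TRUE),
                   start = sample.int(5e5, 200), end = 0)
  expect_equal(sum(gene_density(gr, lens)$count), 200L)
})

test_that("density enrichment separates covered and uncovered bins", {
  lens <- c(c1 = 2e6)
  track <- gene_density(data.frame(chrom = "c1",
                                   start = c(rep(10, 30), rep(200010, 3)),
                                   end = 0), lens, bin = 200000)
  # anchor covering only the densest bin
  a <- data.frame(contig_id = 1L, target_chrom = "c1", start = 1000,
                  end = 150000, n_queries = 2L, queries = "x,y")
  enr <- density_enrichment(a, track, bin = 200000, top_fraction = 0.30)
  expect_gt(enr$top_covered_fraction, enr$overall_covered_fraction)
  expect_gt(enr$mean_density_covered, enr$mean_density_uncovered)
  zero <- density_enrichment(a[0, ], track)
  expect_equal(zero$top_covered_fraction, 0)
  expect_equal(zero$overall_covered_fraction, 0)
})

test_that("cb_coverage converts CB units to genome fraction", {
  ct <- list(list(contig_id = 1L, cb_length = 100))
  expect_equal(cb_coverage(ct, genome_bp = 4.097e6, avg_band_bp = 4097),
               0.10)
  expect_equal(cb_coverage(list(), genome_bp = 1e6), 0)
  # simulated contigs approximate the truly spanned fraction
  w <- sim_world(3e6)
  asm <- assemble(w$profiles, NULL, score_params(7, 5000, 1e-12))
  cl <- w$clones[match(unlist(lapply(asm$contigs, `[[`, "members")),
                       w$clones$clone_id), ]
  cl <- cl[cl$source == "nuclear", ]
  ir <- IRanges::reduce(IRanges::IRanges(start = cl$start + 1, end = cl$end))
  truth_frac <- sum(IRanges::width(ir)) / w$truth$genome_bp
  # with the per-scoreable-band genomic spacing (insert / mean band
  # count) the CB estimate tracks the truly spanned fraction
  spacing <- w$cfg$insert_mean /
    mean(lengths(lapply(w$profiles, `[[`, "bands"))[!w$clones$failed])
  est <- cb_coverage(asm, genome_bp = w$truth$genome_bp,
                     avg_band_bp = spacing)
  expect_lte(abs(est - truth_frac) / truth_frac, 0.30)
  # at the average *band size* the estimate underestimates span, because
  # very large and very small fragments are excluded from band calling
  expect_lt(cb_coverage(asm, genome_bp = w$truth$genome_bp,
                        avg_band_bp = 4097), truth_frac)
})

test_that("WGD duplications raise the multi-region anchor rate", {
  w <- sim_world(4e6, seed = 21)
  asm <- assemble(w$profiles, NULL, score_params(7, 5000, 1e-12))
  cmap <- data.frame(clone_id = unlist(lapply(asm$contigs, `[[`, "members")),
                     contig_id = rep(vapply(asm$contigs, `[[`, integer(1),
                                            "contig_id"),
                                     vapply(asm$contigs,
                                            function(ct) length(ct$members),
                                            integer(1))))
  rate <- sapply(c(0L, 2L), function(nw) {
    comp <- simulate_comparator(w$truth, derive_seed(21, 5 + nw), w$clones,
                                n_wgd = nw)
    hits <- filter_repetitive_queries(comp$hits)
    qc <- data.frame(query_id = paste0(cmap$clone_id, "_F"),
                     contig_id = cmap$contig_id)
    qc <- rbind(qc, data.frame(query_id = paste0(cmap$clone_id, "_R"),
                               contig_id = cmap$contig_id))
    a <- anchor_to_genome(hits, qc, 200000)
    if (!nrow(a)) return(NA_real_)
    per <- table(a$contig_id)
    mean(per >= 2)
  })
  expect_gt(rate[2], rate[1])
})
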