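test_that("sizes files round-trip and validate", {
  w <- sim_world(2e6, seed = 29)
  path <- withr::local_tempfile(fileext = ".sizes")
  write_sizes(w$profiles, path)
  back <- read_sizes(path)
  expect_identical(names(back), names(w$profiles))
  expect_identical(lapply(back, `[[`, "bands"),
                   lapply(w$profiles, `[[`, "bands"))
  # zero-band clones are legal
  empties <- names(back)[lengths(lapply(back, `[[`, "bands")) == 0]
  expect_gt(length(empties), 0L)

  bad <- withr::local_tempfile()
  writeLines(c("clone1 2", "100", "200"), bad)       # missing terminator
  expect_error(read_sizes(bad), "line 1.*truncated|truncated")
  writeLines(c("clone1 2", "100", "200", "0"), bad)  # wrong terminator
  expect_error(read_sizes(bad), "terminator.*line 4")
  writeLines(c("clone1 2", "100", "x", "-1"), bad)
  expect_error(read_sizes(bad), "non-integer")
})

test_that("hit tables parse the tabular subset and reject junk", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hits <- data.frame(query_id = c("q1", "q2", "q3"),
                     target_chrom = c("c1", "c1", "c2"),
                     target_pos = c(0, 150000, 99))
  write_hit_table(hits, path)
  back <- read_hit_table(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$target_pos, hits$target_pos)

  writeLines("q1\tc1\tonly-three-cols", path)
  expect_error(read_hit_table(path), "9 columns")
  writeLines("q1\tc1\t100\t40\t0\t0\t1\t40\tNOPE\t140\t1e-5\t80", path)
  expect_error(read_hit_table(path), "malformed")
  writeLines(character(0), path)
  expect_equal(nrow(read_hit_table(path)), 0L)
})

test_that("marker and map tables validate their schemas", {
  path <- withr::local_tempfile(fileext = ".tsv")
  mk <- data.frame(marker_id = "m", kind = "PROBE", clone_id = "c")
  write_markers(mk, path)
  expect_equal(read_markers(path), mk)
  write_tsv(data.frame(marker_id = "m", kind = "WRONG", clone_id = "c"),
            path)
  expect_error(read_markers(path), "kind")

  map <- data.frame(marker_id = c("a", "b"), group = c(1L, 13L),
                    cM = c(0, 5.5))
  write_genetic_map(map, path)
  expect_equal(read_genetic_map(path), map)
  write_tsv(data.frame(marker_id = "a", group = 14L, cM = 1), path)
  expect_error(read_genetic_map(path), "1..13")
  write_tsv(data.frame(marker_id = "a", group = 1L, cM = -2), path)
  expect_error(read_genetic_map(path), "non-negative")
})

test_that("BED writing and reading preserve intervals", {
  path <- withr::local_tempfile(fileext = ".bed")
  g <- data.frame(chrom = c("c1", "c2"), start = c(0, 100),
                  end = c(50, 400), name = c("g1", "g2"))
  write_bed(g, path)
  back <- read_genes(path)
  expect_equal(back$start, g$start)
  expect_equal(back$end, g$end)
  expect_equal(back$name, g$name)
})

test_that("assembly exports are complete and consistent", {
  w <- sim_world(2e6, seed = 31)
  asm <- assemble(w$profiles, NULL, score_params(7, 5000, 1e-12))
  dir <- withr::local_tempdir()
  write_assembly(asm, dir)
  members <- read_tsv(file.path(dir, "members.tsv"))
  contigs <- read_tsv(file.path(dir, "contigs.tsv"))
  singles <- readLines(file.path(dir, "singletons.txt"))
  expect_equal(nrow(contigs), length(asm$contigs))
  expect_setequal(c(members$clone_id, singles), names(w$profiles))
  expect_equal(unname(table(members$contig_id)[as.character(contigs$contig_id)]),
               unname(as.table(contigs$n_clones)),
               ignore_attr = TRUE)
})

test_that("analytics and usage subcommands behave", {
  out <- capture.output(status <- fpmap_cli(
    c("analytics", "--bands", "17", "--tol", "7", "--gel", "5000",
      "--cutoff", "1e-12")))
  expect_equal(status, 0L)
  expect_true(any(grepl("min_match_threshold.* = 12$", out)))
  expect_true(any(grepl("min_informative_band_count.* = 8$", out)))

  expect_equal(suppressMessages(fpmap_cli("frobnicate")), 2L)
  expect_equal(capture.output(s0 <- fpmap_cli(character(0)))[1],
               "usage: fpmap <command> [options]")
  expect_equal(s0, 1L)
  # validation failures exit non-zero instead of aborting
  expect_equal(suppressMessages(fpmap_cli(c("assemble", "--sizes",
                                            "/nonexistent"))), 1L)
})

test_that("the CLI chains a full demo pipeline", {
  dir <- withr::local_tempdir()
  ds <- file.path(dir, "ds")
  expect_equal(suppressMessages(
    fpmap_cli(c("simulate", "--out", ds, "--genome", "4e6", "--seed", "2",
                "--probes", "80", "--wgd", "2"))), 0L)
  expect_true(all(file.exists(file.path(ds,
    c("agarose.sizes", "hicf.sizes", "clones.tsv", "markers.tsv",
      "pool_design.tsv", "pool_hits.tsv", "genetic_map.tsv",
      "comparator_hits.tsv", "comparator_chroms.tsv",
      "comparator_genes.bed", "config.json")))))

  asmdir <- file.path(dir, "asm")
  expect_equal(suppressMessages(
    fpmap_cli(c("assemble", "--sizes", file.path(ds, "agarose.sizes"),
                "--clones", file.path(ds, "clones.tsv"),
                "--markers", file.path(ds, "markers.tsv"),
                "--out", asmdir))), 0L)
  members <- read_tsv(file.path(asmdir, "members.tsv"))
  expect_gt(nrow(members), 50L)

  anchors_out <- file.path(dir, "anchors.tsv")
  expect_equal(suppressMessages(
    fpmap_cli(c("anchor", "--members", file.path(asmdir, "members.tsv"),
                "--pairs", file.path(ds, "probe_hits.tsv"),
                "--map", file.path(ds, "genetic_map.tsv"),
                "--out", anchors_out))), 0L)
  expect_true(file.exists(anchors_out))

  # query -> contig table from BES naming
  qc <- rbind(data.frame(query_id = paste0(members$clone_id, "_F"),
                         contig_id = members$contig_id),
              data.frame(query_id = paste0(members$clone_id, "_R"),
                         contig_id = members$contig_id))
  qc_path <- file.path(dir, "qc.tsv")
  write_tsv(qc, qc_path)
  syn_out <- file.path(dir, "synteny.tsv")
  expect_equal(suppressMessages(
    fpmap_cli(c("synteny", "--hits", file.path(ds, "comparator_hits.tsv"),
                "--query-contig", qc_path, "--window", "200000",
                "--chroms", file.path(ds, "comparator_chroms.tsv"),
                "--genes", file.path(ds, "comparator_genes.bed"),
                "--out", syn_out))), 0L)
  expect_gt(nrow(read_tsv(syn_out)), 0L)

  expect_equal(suppressMessages(
    fpmap_cli(c("evaluate", "--dataset", ds,
                "--members", file.path(asmdir, "members.tsv")))), 0L)
})

test_that("probe hits parse through the evidence path in assemble", {
  # markers written by simulate must load and relax cutoffs end to end
  pair <- shared_pair(11)
  profs <- list(A = pair$a, B = pair$b)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_markers(data.frame(marker_id = "M1", kind = "PROBE",
                           clone_id = c("A", "B")), path)
  asm <- assemble(profs, read_markers(path), score_params(7, 5000, 1e-12))
  expect_length(asm$contigs, 1L)
})
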