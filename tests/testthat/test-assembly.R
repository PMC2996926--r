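params12 <- score_params(7, 5000, 1e-12)

test_that("assemble joins transitive chains and respects marker relaxation", {
  # chain a-b-c with strong consecutive overlaps -> one contig of 3
  cons <- band_block(1, 27)
  profs <- list(a = mk_profile("a", cons[1:17]),   # a/b and b/c share 12,
                b = mk_profile("b", cons[6:22]),   # a/c only 7: joined by
                c = mk_profile("c", cons[11:27]))  # transitivity
  asm <- assemble(profs, NULL, params12)
  expect_length(asm$contigs, 1L)
  expect_setequal(asm$contigs[[1]]$members, c("a", "b", "c"))
  expect_length(asm$singletons, 0L)
  expect_error(assemble(list(), NULL, params12), "empty")

  # 11/17 shared bands: no markers -> two singletons
  pair <- shared_pair(11)
  profs2 <- list(A = pair$a, B = pair$b)
  asm2 <- assemble(profs2, NULL, params12)
  expect_length(asm2$contigs, 0L)
  expect_setequal(asm2$singletons, c("A", "B"))

  # one shared marker relaxes 1e-12 to 1e-10 and joins the pair
  ev <- data.frame(marker_id = "M1", kind = "PROBE",
                   clone_id = c("A", "B"))
  asm3 <- assemble(profs2, ev, params12)
  expect_length(asm3$contigs, 1L)
  # audit: the accepted edge records score <= effective cutoff
  ed <- asm3$provenance[[1]]$edges
  expect_true(all(ed$score <= ed$eff_cutoff))

  # a probe over the assembly hit cap is ignored
  ev_big <- data.frame(marker_id = "M2", kind = "PROBE",
                       clone_id = sprintf("Z%02d", 1:60))
  ev_big$clone_id[1:2] <- c("A", "B")
  expect_length(assemble(profs2, ev_big, params12)$contigs, 0L)
})

test_that("noise-free simulation is recovered perfectly", {
  w <- sim_world()
  asm <- assemble(w$profiles, NULL, params12)
  met <- evaluate_assembly(asm, w$truth, w$clones, params12)
  expect_equal(met$precision, 1)
  expect_equal(met$recall, 1)
  expect_equal(met$purity, 1)
  # partition invariant: every clone in exactly one contig or singleton
  in_ct <- unlist(lapply(asm$contigs, `[[`, "members"))
  expect_false(any(duplicated(in_ct)))
  expect_setequal(c(in_ct, asm$singletons), names(w$profiles))
})

test_that("build_cb_map obeys its layout contract", {
  p1 <- mk_profile("x", band_block(1, 12))
  cb1 <- build_cb_map("x", list(x = p1), params12)
  expect_equal(cb1$cb_length, 12L)
  expect_length(cb1$q_clones, 0L)

  # two identical clones: cb_length = n, equal offsets
  twins <- list(t1 = mk_profile("t1", band_block(1, 15)),
                t2 = mk_profile("t2", band_block(1, 15)))
  cb2 <- build_cb_map(c("t1", "t2"), twins, params12)
  expect_equal(cb2$cb_length, 15L)
  expect_equal(unname(cb2$offsets["t1"]), unname(cb2$offsets["t2"]))

  # staircase of 5: bounds, 25% accuracy, monotone offsets
  st <- staircase_profiles()
  cb <- build_cb_map(names(st), st, params12)
  nb <- lengths(lapply(st, `[[`, "bands"))
  expect_gte(cb$cb_length, max(nb))
  expect_lte(cb$cb_length, sum(nb))
  truth_span <- attr(st, "consensus_size")
  expect_lte(abs(cb$cb_length - truth_span) / truth_span, 0.25)
  expect_true(all(diff(cb$offsets[names(st)]) > 0) ||
                all(diff(cb$offsets[names(st)]) < 0))
})

test_that("dq_split separates a falsely bridged contig", {
  # two tight 3-clone groups (consecutive clones share 15/17 bands,
  # S=1.4e-18) plus two 29-band bridging clones joining both groups via
  # 14-band partial matches (S=1.7e-13: accepted at 1e-12, dropped at
  # 1e-13). The bridges align < 50% of their bands anywhere -> 2 Q clones.
  consP <- band_block(1, 21, gap = 25)
  consQ <- band_block(4, 21, gap = 25)
  junk1 <- band_block(7, 1)
  junk2 <- band_block(8, 1)
  profs <- list(
    p1 = mk_profile("p1", consP[1:17]), p2 = mk_profile("p2", consP[3:19]),
    p3 = mk_profile("p3", consP[5:21]),
    q1 = mk_profile("q1", consQ[1:17]), q2 = mk_profile("q2", consQ[3:19]),
    q3 = mk_profile("q3", consQ[5:21]),
    x1 = mk_profile("x1", c(consP[8:21], consQ[1:14], junk1)),
    x2 = mk_profile("x2", c(consP[1:14], consQ[8:21], junk2)))
  asm <- assemble(profs, NULL, params12)
  expect_length(asm$contigs, 1L)          # falsely bridged into one
  expect_gte(length(asm$contigs[[1]]$q_clones), 2L)
  split <- dq_split(asm, profs, params12)
  expect_true(all(vapply(split$contigs,
                         function(ct) length(ct$q_clones), integer(1)) <= 1L))
  mem <- lapply(split$contigs, `[[`, "members")
  expect_true(any(vapply(mem, setequal, logical(1), c("p1", "p2", "p3"))))
  expect_true(any(vapply(mem, setequal, logical(1), c("q1", "q2", "q3"))))

  # a contig without Q clones is untouched
  clean <- assemble(profs[1:3], NULL, params12)
  expect_equal(lapply(dq_split(clean, profs[1:3], params12)$contigs,
                      `[[`, "members"),
               lapply(clean$contigs, `[[`, "members"))
})

test_that("end_merge joins contigs end-to-end only", {
  # terminal pair shares 11/17 bands: S = 2.1e-11 merges at the 1e-10 step
  pair <- shared_pair(11)
  consA <- sort(c(pair$a$bands, band_block(7, 8)))
  profs <- list(a1 = mk_profile("a1", consA[!consA %in% pair$a$bands[1:3]]),
                a2 = pair$a,
                b1 = pair$b,
                b2 = mk_profile("b2", sort(c(pair$b$bands[4:18],
                                             band_block(8, 5)))))
  asm <- assemble(profs, NULL, params12)
  expect_length(asm$contigs, 2L)
  merged <- end_merge(asm, profs, params12, floor = 1e-6)
  expect_length(merged$contigs, 1L)
  expect_setequal(merged$contigs[[1]]$members, names(profs))

  # interior-only overlap between two 5-clone contigs: never merged
  stA <- staircase_profiles(5, 20, 8, gap = 40)
  stB <- staircase_profiles(5, 20, 8, gap = 40)
  names(stB) <- sub("S", "T", names(stB))
  stB <- lapply(names(stB), function(nm)
    mk_profile(nm, stB[[sub("T", "S", nm)]]$bands + 3000L))
  names(stB) <- vapply(stB, `[[`, "", "clone_id")
  # make the middles near-identical (interior overlap only)
  stB$T3 <- mk_profile("T3", sort(c(stA$S3$bands[1:16],
                                    stB$T3$bands[17:20])))
  profs2 <- c(stA, stB)
  asm2 <- assemble(profs2, NULL, score_params(7, 5000, 1e-8))
  if (length(asm2$contigs) == 2L) {
    m2 <- end_merge(asm2, profs2, score_params(7, 5000, 1e-8),
                    floor = 1e-6)
    expect_length(m2$contigs, 2L)        # end-to-end restriction holds
  }
})

test_that("end_merge never joins disjoint genomic regions", {
  for (seed in c(7, 19)) {
    w <- sim_world(2e6, seed = seed)
    asm <- assemble(w$profiles, NULL, params12)
    merged <- end_merge(asm, w$profiles, params12, floor = 1e-6)
    expect_lte(length(merged$contigs), length(asm$contigs))
    # every merged contig spans one contiguous region of its source space
    cl <- w$clones
    for (ct in merged$contigs) {
      m <- cl[match(ct$members, cl$clone_id), ]
      for (space in unique(m$source)) {
        s <- m[m$source == space, ]
        s <- s[order(s$start), ]
        if (nrow(s) > 1L)
          expect_true(all(s$start[-1] <= cummax(s$end)[-nrow(s)]))
      }
    }
  }
})

test_that("adopt_singletons recovers a removable clone", {
  st <- staircase_profiles(4, 20, 5)
  s <- mk_profile("adoptme", st$S2$bands[3:18])   # 16 of S2's bands
  profs <- c(st, list(adoptme = s))
  asm <- assemble(profs[names(profs) != "adoptme"], NULL, params12)
  asm$singletons <- c(asm$singletons, "adoptme")
  out <- adopt_singletons(asm, profs, params12)
  expect_true("adoptme" %in% out$contigs[[1]]$members)

  # degenerate singletons are never adopted
  tiny <- mk_profile("tiny", 100L)
  profs2 <- c(st, list(tiny = tiny))
  asm2 <- assemble(profs2, NULL, params12)
  out2 <- adopt_singletons(asm2, profs2, params12)
  expect_true("tiny" %in% out2$singletons)
})

test_that("bury_clones buries contained patterns acyclically", {
  parent <- band_block(1, 20)
  profs <- list(P = mk_profile("P", parent),
                C = mk_profile("C", parent[1:18]),   # 90% of P's bands
                D = mk_profile("D", parent))         # identical to P
  asm <- assemble(profs, NULL, params12)
  ct <- bury_clones(asm$contigs[[1]], profs, params12, fraction = 0.80)
  # the sub-clone is buried, and exactly one of the identical pair
  expect_true("C" %in% names(ct$buried))
  expect_length(setdiff(c("P", "D"), names(ct$buried)), 1L)
  # burial targets are unburied; buried clones keep membership but
  # leave the terminals
  expect_false(any(ct$buried %in% names(ct$buried)))
  expect_setequal(ct$members, c("P", "C", "D"))
  expect_false(any(names(ct$buried) %in% unlist(ct$terminal)))

  # property: burial targets are always unburied (no cycles) on random sets
  set.seed(5)
  for (rep in 1:20) {
    base <- sort(sample.int(5000, 25))
    profs_r <- lapply(1:6, function(i)
      mk_profile(sprintf("r%d", i), sort(sample(base, sample(15:25, 1)))))
    names(profs_r) <- vapply(profs_r, `[[`, "", "clone_id")
    ct_r <- structure(list(contig_id = 1L, members = names(profs_r),
                           offsets = stats::setNames(rep(0, 6), names(profs_r)),
                           cb_length = 25L, q_clones = character(0),
                           consensus = base, buried = character(0),
                           terminal = list()), class = "fp_contig")
    ct_r <- bury_clones(ct_r, profs_r, params12)
    expect_false(any(ct_r$buried %in% names(ct_r$buried)))
  }
})

test_that("cross-well detection needs adjacency and high similarity", {
  b <- band_block(1, 17)
  mk <- function(id, bands, plate, r, c)
    band_profile(id, bands, plate = plate, well_row = r, well_col = c)
  profs <- list(
    v = mk("v", b, 1, 3, 4), w = mk("w", b, 1, 3, 5),          # adjacent copy
    x = mk("x", b, 1, 10, 10), y = mk("y", b, 2, 3, 4),        # distant copies
    z = mk("z", band_block(5, 17), 1, 3, 3))                   # adjacent, unrelated
  flagged <- detect_cross_well(profs, params12)
  expect_setequal(flagged, c("v", "w"))
  expect_length(detect_cross_well(profs["x"], params12), 0L)
})

test_that("simulated cross-well contaminations are detected", {
  w <- sim_world(2e6, seed = 9, noise = TRUE, cross_well_rate = 0.05,
                 dropout = 0, spurious = 0, jitter_rate = 0,
                 failed_rate = 0)
  planted <- w$clones$clone_id[!is.na(w$clones$contaminated_from)]
  expect_gt(length(planted), 0L)
  flagged <- detect_cross_well(w$profiles, params12)
  expect_gte(mean(planted %in% flagged), 0.9)
})

test_that("band-count outliers are flagged per batch by nearest rank", {
  uni <- lapply(1:40, function(i)
    band_profile(sprintf("u%d", i), band_block(1, 17), batch = 1L))
  names(uni) <- vapply(uni, `[[`, "", "clone_id")
  expect_length(detect_band_outliers(uni), 0L)

  chim <- band_profile("chim", band_block(1, 34, gap = 20), batch = 1L)
  profs <- c(uni, list(chim = chim))
  expect_identical(detect_band_outliers(profs), "chim")
})

test_that("terminal clone selection ranks and dedupes", {
  st <- staircase_profiles(10, 20, 8, gap = 25)
  small <- list(m1 = mk_profile("m1", band_block(7, 17)),
                m2 = mk_profile("m2", band_block(7, 17)))
  profs <- c(st, small)
  asm <- assemble(profs, NULL, score_params(7, 5000, 1e-8))
  sel <- select_terminal_clones(asm, 1L, 2L)
  expect_length(sel, 4L)                       # four BACs per contig
  expect_true(all(startsWith(sel, "S")))       # largest contig wins
  sel2 <- select_terminal_clones(asm, 2L, 2L)
  expect_lte(length(sel2), 8L)
  expect_true(all(c("m1", "m2") %in% sel2))    # 2-clone contig dedupes
})

test_that("HICF pseudo-markers partition contiged clones", {
  f <- fig1c_fixture()
  hp <- hicf_params(1e-50)
  hasm <- assemble(f$hicf, NULL, hp, stage = "HICF_ONLY")
  mk <- hicf_pseudomarkers(hasm)
  expect_setequal(unique(mk$kind), "HICF_CONTIG")
  in_ct <- unlist(lapply(hasm$contigs, `[[`, "members"))
  expect_setequal(mk$clone_id, in_ct)
  expect_false(any(duplicated(mk$clone_id)))
  expect_false(any(hasm$singletons %in% mk$clone_id))
})
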