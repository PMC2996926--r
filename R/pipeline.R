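#' Pipeline configuration
#'
#' Stage parameters of the integrated assembly pipeline, defaulting to the
#' published protocol: preliminary agarose assembly at cutoff 1e-10 /
#' tolerance 8 with probe relaxation to 1e-8/1e-7/1e-6; HICF assembly of
#' terminal clones of the largest contigs at 1e-50 / tolerance 3 (no
#' markers); integrated agarose reassembly at 1e-12 / tolerance 7 with
#' probe+HICF relaxation to 1e-10/1e-9/1e-8 and the exact two-denary rule
#' for HICF-supported terminal-clone joins; then DQ splitting, end merges
#' from 1e-12 through 1e-6, singleton adoption and burying.
#'
#' @param prelim_cutoff,prelim_tolerance Preliminary agarose settings.
#' @param prelim_floor Relaxation floor of the preliminary stage (1e-6).
#' @param hicf_cutoff HICF assembly cutoff (1e-50).
#' @param hicf_top_fraction Fraction of (largest) contigs whose terminal
#'   clones get HICF fingerprints (default 0.5, as in the mapped library).
#' @param per_end Terminal clones per contig end (default 2).
#' @param final_cutoff,final_tolerance Integrated assembly settings.
#' @param final_floor Relaxation floor of the integrated stage (1e-8).
#' @param merge_floor Last end-merge step (1e-6).
#' @param assembly_max_hits Probe hit cap for assembly use (50).
#' @param bury_fraction Band-containment threshold for burying (0.80).
#' @param outlier_low_pct,outlier_high_pct Band-count QC percentiles (5/5).
#' @param cross_well_similarity Cross-well mutual match fraction (0.90).
#' @param gel_length Agarose gel length (5000).
#' @param run_qc Run the QC stage (outliers + cross-well; default TRUE).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(prelim_cutoff = 1e-10, prelim_tolerance = 8L,
                            prelim_floor = 1e-6, hicf_cutoff = 1e-50,
                            hicf_top_fraction = 0.5, per_end = 2L,
                            final_cutoff = 1e-12, final_tolerance = 7L,
                            final_floor = 1e-8, merge_floor = 1e-6,
                            assembly_max_hits = 50L, bury_fraction = 0.80,
                            outlier_low_pct = 5, outlier_high_pct = 5,
                            cross_well_similarity = 0.90,
                            gel_length = 5000L, run_qc = TRUE) {
  cfg <- as.list(environment())
  needed <- vapply(cfg, is.null, logical(1))
  if (any(needed)) stop("missing stage parameter(s): ",
                        paste(names(cfg)[needed], collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Run the integrated physical-map pipeline
#'
#' Stages: (0) QC — band-count outliers and cross-well contaminations are
#' excluded (rendered singletons); (1) preliminary agarose assembly with
#' probe relaxation; (2) terminal-clone selection from the largest contigs
#' and HICF-only assembly of those clones; (3) integrated agarose
#' reassembly with probe and HICF pseudo-marker relaxation, where HICF
#' contig co-membership relaxes terminal-clone joins of distinct
#' preliminary contigs by exactly two denary steps; (4) DQ splitting;
#' (5) recursive end-to-end merging; (6) singleton adoption; (7) burying.
#' Provenance records each stage's parameters and counts.
#'
#' @param profiles Named list of agarose [band_profile()] objects.
#' @param evidence Optional probe marker table (`marker_id`, `kind`,
#'   `clone_id`).
#' @param config A [pipeline_config()].
#' @param hicf_profiles Optional named list of HICF [band_profile()]s for
#'   (at least) the clones that will be selected in stage 2; when `NULL`
#'   the HICF stages are skipped and the pipeline reduces to the
#'   marker-relaxed agarose assembly plus finalization.
#' @return The final `fp_assembly` (stage `FINAL`) with full provenance;
#'   attribute `prelim` holds the preliminary assembly and attribute
#'   `hicf` the HICF-only assembly (or `NULL`).
#' @export
run_integrated_pipeline <- function(profiles, evidence = NULL,
                                    config = pipeline_config(),
                                    hicf_profiles = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  prelim_params <- score_params(config$prelim_tolerance, config$gel_length,
                                config$prelim_cutoff)
  final_params <- score_params(config$final_tolerance, config$gel_length,
                               config$final_cutoff)

  # stage 0: QC
  excluded <- character(0)
  qc <- list(outliers = character(0), cross_well = character(0))
  if (config$run_qc) {
    qc$outliers <- detect_band_outliers(profiles, config$outlier_low_pct,
                                        config$outlier_high_pct)
    qc$cross_well <- detect_cross_well(profiles, final_params,
                                       config$cross_well_similarity)
    excluded <- union(qc$outliers, qc$cross_well)
  }

  # stage 1: preliminary agarose assembly
  prelim <- assemble(profiles, evidence, prelim_params,
                     assembly_max_hits = config$assembly_max_hits,
                     relax_floor = config$prelim_floor,
                     exclude = excluded, stage = "PRELIM_AGAROSE")

  # stage 2: HICF of terminal clones of the largest contigs
  hicf_asm <- NULL
  hicf_markers <- NULL
  hicf_terminal_pairs <- NULL
  if (!is.null(hicf_profiles) && length(prelim$contigs)) {
    k <- max(1L, floor(length(prelim$contigs) * config$hicf_top_fraction))
    sel <- select_terminal_clones(prelim, k, config$per_end)
    sel <- intersect(sel, names(hicf_profiles))
    if (length(sel) >= 2L) {
      hicf_asm <- assemble(hicf_profiles[sel], NULL,
                           hicf_params(config$hicf_cutoff),
                           stage = "HICF_ONLY")
      hicf_markers <- hicf_pseudomarkers(hicf_asm)
      # pairs of terminal clones belonging to distinct preliminary contigs
      owner <- .clone_contig_map(prelim)[sel]
      if (length(sel) >= 2L) {
        cmb <- utils::combn(sort(sel), 2L)
        distinct <- owner[cmb[1, ]] != owner[cmb[2, ]]
        hicf_terminal_pairs <- cbind(cmb[1, distinct], cmb[2, distinct])
      }
    }
  }

  # stage 3: integrated reassembly
  integrated <- assemble(profiles, evidence, final_params,
                         assembly_max_hits = config$assembly_max_hits,
                         relax_floor = config$final_floor,
                         hicf_markers = hicf_markers,
                         hicf_terminal_pairs = hicf_terminal_pairs,
                         exclude = excluded, stage = "INTEGRATED")

  # stages 4-7: finalization
  asm <- dq_split(integrated, profiles, final_params)
  asm <- end_merge(asm, profiles, final_params, floor = config$merge_floor)
  asm <- adopt_singletons(asm, profiles, final_params)
  asm <- .bury_all(asm, profiles, final_params, config$bury_fraction)
  asm$stage <- "FINAL"
  asm$provenance <- c(list(list(stage = "QC", flagged = qc,
                                n_excluded = length(excluded)),
                           list(stage = "PRELIM",
                                n_contigs = length(prelim$contigs),
                                n_singletons = length(prelim$singletons)),
                           list(stage = "HICF",
                                n_contigs = if (is.null(hicf_asm)) 0L
                                else length(hicf_asm$contigs))),
                      asm$provenance)
  attr(asm, "prelim") <- prelim
  attr(asm, "hicf") <- hicf_asm
  asm
}
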