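# End-to-end orchestration: inputs (files or a synthetic cohort) ->
# mismatch -> dnDSA -> cPRA/mcPRA -> IS classification -> association report.

#' Pipeline configuration
#'
#' Single source of truth for every analysis threshold, with the published
#' defaults: bead MFI > 1000 defines an unacceptable antigen, 12+ mismatched
#' eplets defines a high DR/DQ load, cPRA >= 94.50 defines a highly
#' sensitized patient, an average CNI trough < 5 ng/mL counts as reduced
#' immunosuppression, and a >= 50% donor-pool reduction defines a meaningful
#' cPRA change. The baseline serum window extends 31 days past graft failure.
#'
#' @param mfi_threshold MFI cut for antibody positivity (default 1000,
#'   strict).
#' @param eplet_threshold Low/high eplet mismatch cut (default 12).
#' @param hsp_cutoff Highly-sensitized cPRA cut (default 94.50, inclusive).
#' @param trough_cutoff CNI trough cut in ng/mL (default 5; at-cutoff is
#'   maintained).
#' @param mcpra_cutoff Pool-reduction percent defining a meaningful change
#'   (default 50, inclusive).
#' @param baseline_window_days Days after failure still counted as baseline
#'   (default 31).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mfi_threshold = 1000, eplet_threshold = 12L,
                            hsp_cutoff = 94.50, trough_cutoff = 5,
                            mcpra_cutoff = 50, baseline_window_days = 31L) {
  structure(list(mfi_threshold = mfi_threshold,
                 eplet_threshold = as.integer(eplet_threshold),
                 hsp_cutoff = hsp_cutoff, trough_cutoff = trough_cutoff,
                 mcpra_cutoff = mcpra_cutoff,
                 baseline_window_days = as.integer(baseline_window_days)),
            class = "pipeline_config")
}

#' Read all pipeline inputs from a directory
#'
#' Expects the file set written by [write_cohort()]: `genotypes.tsv`,
#' `pairs.tsv`, `registry.tsv`, `donor_panel.tsv`, `beads.csv`,
#' `is_timeline.csv`, `troughs.csv`, `patients.csv`.
#'
#' @param dir Input directory.
#' @return List of parsed inputs.
#' @export
read_pipeline_inputs <- function(dir) {
  need <- c("genotypes.tsv", "pairs.tsv", "registry.tsv", "donor_panel.tsv",
            "beads.csv", "is_timeline.csv", "troughs.csv", "patients.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) {
    stop("input directory '", dir, "' missing file(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dates <- data.table::fread(file.path(dir, "patients.csv"), header = TRUE)
  dates[, `:=`(patient_id = as.character(patient_id),
               transplant_date = as.Date(transplant_date),
               failure_date = as.Date(failure_date),
               last_date = as.Date(last_date))]
  list(genotypes = read_genotypes(file.path(dir, "genotypes.tsv")),
       pairs = as.data.frame(data.table::fread(file.path(dir, "pairs.tsv"),
                                               colClasses = "character")),
       registry = load_eplet_registry(file.path(dir, "registry.tsv")),
       donor_panel = read_donor_panel(file.path(dir, "donor_panel.tsv")),
       beads = read_bead_panels(file.path(dir, "beads.csv")),
       is_timeline = read_is_timeline(file.path(dir, "is_timeline.csv")),
       troughs = read_troughs(file.path(dir, "troughs.csv")),
       dates = as.data.frame(dates))
}

cohort_inputs <- function(cohort) {
  list(genotypes = cohort$genotypes, pairs = cohort$pairs,
       registry = cohort$registry, donor_panel = cohort$donor_panel,
       beads = cohort$beads, is_timeline = cohort$is_timeline,
       troughs = cohort$troughs, dates = cohort$dates)
}

#' Assemble the per-patient cohort table
#'
#' One row per transplant pair: eplet mismatch counts and LOW/HIGH categories
#' for all four locus groups, de novo DSA flags and timing for DR and DQ,
#' baseline and last cPRA with the donor-pool-reduction outcome, highly
#' sensitized flags, immunosuppression classification and follow-up time.
#' Baseline cPRA uses cumulative above-threshold antibodies up to
#' `failure_date + baseline_window_days`; the last cPRA uses all samples up
#' to the last follow-up date. Beads matching the recipient's own antigen
#' keys are excluded throughout (self-reactivity artefacts at antigen-level
#' resolution).
#'
#' @param inputs List as returned by [read_pipeline_inputs()] (or internal
#'   equivalent from a `synthetic_cohort`).
#' @param config A [pipeline_config()].
#' @return data.frame, one row per patient.
#' @export
assemble_cohort_table <- function(inputs, config = pipeline_config()) {
  mm <- mismatch_table(inputs$pairs, inputs$genotypes, inputs$registry,
                       threshold = config$eplet_threshold)
  beads <- data.table::as.data.table(inputs$beads)
  rows <- lapply(seq_len(nrow(inputs$pairs)), function(i) {
    pid <- inputs$pairs$recipient_id[i]
    don <- inputs$genotypes[[inputs$pairs$donor_id[i]]]
    rec <- inputs$genotypes[[pid]]
    drow <- inputs$dates[inputs$dates$patient_id == pid, ]
    if (nrow(drow) != 1L) {
      stop("patient '", pid, "' missing from the dates table", call. = FALSE)
    }
    self_keys <- unique(antigen_key(genotype_alleles(rec, HLA_LOCI)))
    pb <- beads[patient_id == pid]
    pb <- pb[!(antigen_key(bead_allele) %in% self_keys)]

    mmp <- mm[mm$pair_id == inputs$pairs$pair_id[i], ]
    mget_ <- function(grp, col) mmp[[col]][mmp$group == grp]

    targets <- unlist(lapply(names(LOCUS_GROUPS), function(g)
      donor_mismatched_antigens(don, rec, g)))
    dsa <- detect_dndsa(pb, targets, drow$transplant_date, drow$failure_date,
                        mfi_threshold = config$mfi_threshold,
                        baseline_window_days = config$baseline_window_days)
    dsa_flag <- function(grp) any(dsa$locus_group == grp)
    dsa_timing <- function(grp) {
      tm <- dsa$timing[dsa$locus_group == grp]
      if (!length(tm)) return(NA_character_)
      if (length(unique(tm)) > 1L || any(tm == "BOTH")) "BOTH" else tm[1]
    }

    base_cut <- drow$failure_date + config$baseline_window_days
    ua_base <- unacceptable_antigens(pb[sample_date <= base_cut],
                                     config$mfi_threshold)
    ua_last <- unacceptable_antigens(pb[sample_date <= drow$last_date],
                                     config$mfi_threshold)
    sr <- sensitization_record(pid,
                               compute_cpra(ua_base, inputs$donor_panel),
                               compute_cpra(ua_last, inputs$donor_panel),
                               baseline_date = drow$failure_date,
                               last_date = drow$last_date,
                               reduction_cutoff = config$mcpra_cutoff,
                               hsp_cutoff = config$hsp_cutoff)

    iv <- inputs$is_timeline[inputs$is_timeline$patient_id == pid, ,
                             drop = FALSE]
    tr <- inputs$troughs[inputs$troughs$patient_id == pid, , drop = FALSE]
    data.frame(
      patient_id = pid, pair_id = inputs$pairs$pair_id[i],
      mm_class_i = mget_("CLASS_I", "count"),
      mm_dr = mget_("DR", "count"), dr_category = mget_("DR", "category"),
      mm_dq = mget_("DQ", "count"), dq_category = mget_("DQ", "category"),
      mm_dp = mget_("DP", "count"),
      dndsa_dq = dsa_flag("DQ"), dndsa_dq_timing = dsa_timing("DQ"),
      dndsa_dr = dsa_flag("DR"), dndsa_dr_timing = dsa_timing("DR"),
      baseline_cpra = sr$baseline_cpra, last_cpra = sr$last_cpra,
      delta_cpra = sr$delta_cpra, pool_reduction = sr$pool_reduction,
      mcpra = sr$mcpra, hsp_baseline = sr$hsp_baseline,
      hsp_last = sr$hsp_last,
      avg_trough = average_trough(iv, tr),
      is_reduced = classify_reduced(iv, tr, config$trough_cutoff),
      followup_months = round(as.numeric(drow$last_date - drow$failure_date) /
                                30.44, 1),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Accepts either an input directory (see [read_pipeline_inputs()]) or a
#' `synthetic_cohort` object, assembles the cohort table, builds the four
#' exposure-by-outcome 2x2 tables with Fisher exact p-values, compares the
#' cPRA change between low and high mismatch groups by t-test, and computes
#' median/IQR descriptive summaries. With `out_dir` set, writes
#' `cohort.tsv`, `association.tsv`, `report.txt` and `manifest.json`;
#' outputs are deterministic functions of the inputs and configuration, so a
#' rerun reproduces them byte for byte.
#'
#' @param input Directory path or `synthetic_cohort`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List: `cohort` (data.frame), `tables` (2x2 matrices),
#'   `association` (data.frame with p-values), `summaries` (list of
#'   `summary_stat`), `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  inputs <- if (inherits(input, "synthetic_cohort")) cohort_inputs(input)
            else read_pipeline_inputs(input)
  n_self_dropped <- 0L
  cohort <- withCallingHandlers(
    assemble_cohort_table(inputs, config),
    warning = function(w) {
      if (grepl("self-reactive", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })

  tables <- build_tables(cohort)
  association <- do.call(rbind, lapply(names(tables), function(lb) {
    t2 <- tables[[lb]]
    p <- withCallingHandlers(fisher_exact(t2),
                             warning = function(w) invokeRestart("muffleWarning"))
    data.frame(comparison = lb, low_no = t2[1, 1], low_yes = t2[1, 2],
               high_no = t2[2, 1], high_yes = t2[2, 2],
               fisher_p = p, stringsAsFactors = FALSE)
  }))

  ttests <- lapply(c(DQ = "dq_category", DR = "dr_category"), function(col) {
    lo <- cohort$delta_cpra[cohort[[col]] == "LOW"]
    hi <- cohort$delta_cpra[cohort[[col]] == "HIGH"]
    tryCatch(two_sample_t(hi, lo)$p_value, error = function(e) NA_real_)
  })

  summaries <- list(
    baseline_cpra = median_iqr(cohort$baseline_cpra),
    last_cpra = median_iqr(cohort$last_cpra),
    delta_cpra = median_iqr(cohort$delta_cpra),
    followup_months = median_iqr(cohort$followup_months)
  )

  res <- list(cohort = cohort, tables = tables, association = association,
              ttests = ttests, summaries = summaries, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, inputs, out_dir)
  res
}

write_pipeline_outputs <- function(res, inputs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(res$cohort, file.path(out_dir, "cohort.tsv"), sep = "\t")
  data.table::fwrite(res$association, file.path(out_dir, "association.tsv"),
                     sep = "\t")

  rpt <- c("Allosensitization analysis report",
           "=================================",
           sprintf("Patients: %d", nrow(res$cohort)),
           sprintf("Baseline cPRA:  %s", format(res$summaries$baseline_cpra)),
           sprintf("Last cPRA:      %s", format(res$summaries$last_cpra)),
           sprintf("cPRA change:    %s", format(res$summaries$delta_cpra)),
           sprintf("Follow-up (mo): %s", format(res$summaries$followup_months)),
           sprintf("Meaningful cPRA change (>= %g%% pool reduction): %d/%d",
                   res$config$mcpra_cutoff,
                   sum(res$cohort$mcpra, na.rm = TRUE),
                   sum(!is.na(res$cohort$mcpra))),
           "",
           "Association tables (rows LOW/HIGH mismatch, cols outcome no/yes):")
  for (i in seq_len(nrow(res$association))) {
    a <- res$association[i, ]
    rpt <- c(rpt, sprintf("  %-12s [[%d,%d],[%d,%d]]  Fisher p = %.4g",
                          a$comparison, a$low_no, a$low_yes, a$high_no,
                          a$high_yes, a$fisher_p))
  }
  rpt <- c(rpt, "",
           sprintf("t-test, cPRA change high vs low DQ: p = %.4g",
                   res$ttests$DQ),
           sprintf("t-test, cPRA change high vs low DR: p = %.4g",
                   res$ttests$DR))
  writeLines(rpt, file.path(out_dir, "report.txt"))

  manifest <- list(
    package = "epletrisk",
    version = as.character(utils::packageVersion("epletrisk")),
    config = unclass(res$config),
    n_patients = nrow(res$cohort),
    n_panel_donors = length(inputs$donor_panel$phenotypes),
    registry_version = inputs$registry$version,
    n_bead_results = nrow(inputs$beads)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
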