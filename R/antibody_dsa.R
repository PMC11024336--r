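# Single-antigen-bead antibody calls and de novo DSA classification.

#' Read single-antigen-bead panels from CSV
#'
#' Expects columns `patient_id`, `sample_date` (ISO-8601), `bead_allele`,
#' `mfi`. Each row is one bead on one sample date.
#'
#' @param path Path to the CSV file.
#' @return data.table with `sample_date` as `Date` and numeric `mfi`.
#' @export
read_bead_panels <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("patient_id", "sample_date", "bead_allele", "mfi")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("bead panel file '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt[, `:=`(patient_id = as.character(patient_id),
            sample_date = as.Date(sample_date),
            bead_allele = as.character(bead_allele),
            mfi = as.numeric(mfi))]
  if (any(is.na(dt$sample_date))) {
    stop("unparseable sample_date in '", path, "'", call. = FALSE)
  }
  if (any(is.na(dt$mfi)) || any(dt$mfi < 0)) {
    stop("MFI values must be non-negative numbers in '", path, "'",
         call. = FALSE)
  }
  dt[]
}

#' Unacceptable antigens from bead results
#'
#' A bead defines an unacceptable antigen when its MFI is strictly greater
#' than the threshold (beads at exactly the threshold are excluded, per the
#' ">1,000" laboratory convention). Beads are collapsed to antigen keys; an
#' empty or all-negative panel yields an empty set, not an error.
#'
#' @param beads data.frame with columns `bead_allele` and `mfi` (any number of
#'   sample dates; antibodies are cumulative across the rows given).
#' @param mfi_threshold MFI cut, default 1000.
#' @return Character vector of antigen keys (sorted, unique).
#' @examples
#' b <- data.frame(bead_allele = c("A*02:01", "B*07:02"), mfi = c(1000, 1001))
#' unacceptable_antigens(b)  # only "B*07"
#' @export
unacceptable_antigens <- function(beads, mfi_threshold = 1000) {
  if (is.null(beads) || nrow(beads) == 0L) return(character(0))
  pos <- beads$mfi > mfi_threshold
  sort(unique(antigen_key(beads$bead_allele[pos])))
}

#' Donor antigens mismatched against the recipient
#'
#' Antigen keys of donor alleles at the group's loci whose key is not among
#' the recipient's keys at those loci. This is the set of legitimate DSA
#' targets for the pair; a pair matched at antigen level has none.
#'
#' @param donor,recipient `hla_genotype` objects.
#' @param group Group name or locus vector.
#' @return Character vector of antigen keys (sorted, unique).
#' @export
donor_mismatched_antigens <- function(donor, recipient, group) {
  dk <- unique(antigen_key(genotype_alleles(donor, group)))
  rk <- unique(antigen_key(genotype_alleles(recipient, group)))
  sort(setdiff(dk, rk))
}

#' Detect de novo donor-specific antibodies for one patient
#'
#' A donor target (antigen key from [donor_mismatched_antigens()]) becomes a
#' dnDSA event when at least one bead matching the target is above threshold
#' on a sample date after the transplant, and the target is negative on every
#' pre-transplant panel (de novo means absent before transplant, not merely
#' before the latest sample). Timing relative to graft failure uses a
#' baseline window: samples up to `failure_date + baseline_window_days` count
#' as pre-failure, matching a baseline serum drawn prior to or within one
#' month of failure.
#'
#' Beads whose antigen key equals one of the recipient's own keys are
#' self-reactivity artefacts at this resolution and are dropped with a
#' warning before calling.
#'
#' @param panel data.frame of one patient's bead results (`sample_date`,
#'   `bead_allele`, `mfi`; a `patient_id` column is carried through if
#'   present).
#' @param donor_targets Character vector of antigen keys.
#' @param transplant_date,failure_date `Date`s with
#'   `transplant_date < failure_date`.
#' @param mfi_threshold MFI cut, default 1000.
#' @param baseline_window_days Days after failure still counted as the
#'   pre-failure window (default 31).
#' @param recipient_keys Optional character vector of the recipient's own
#'   antigen keys, used to drop self-reactive beads.
#' @param strict If `TRUE`, a missing pre-transplant baseline panel is an
#'   error; otherwise a warning is raised and the patient is assumed naive
#'   (no preformed DSA).
#' @return data.frame of events: `patient_id`, `target`, `locus_group`,
#'   `first_detected`, `timing` (`PRE_FAILURE`, `POST_FAILURE` or `BOTH`).
#'   Zero rows when no dnDSA.
#' @export
detect_dndsa <- function(panel, donor_targets, transplant_date, failure_date,
                         mfi_threshold = 1000, baseline_window_days = 31,
                         recipient_keys = NULL, strict = FALSE) {
  transplant_date <- as.Date(transplant_date)
  failure_date <- as.Date(failure_date)
  stopifnot(transplant_date < failure_date)
  empty <- data.frame(patient_id = character(0), target = character(0),
                      locus_group = character(0),
                      first_detected = as.Date(character(0)),
                      timing = character(0), stringsAsFactors = FALSE)
  if (length(donor_targets) == 0L) return(empty)
  if (is.null(panel) || nrow(panel) == 0L) return(empty)

  pid <- if ("patient_id" %in% names(panel)) as.character(panel$patient_id[1]) else NA_character_
  panel <- data.frame(sample_date = as.Date(panel$sample_date),
                      key = antigen_key(panel$bead_allele),
                      mfi = as.numeric(panel$mfi), stringsAsFactors = FALSE)
  if (!is.null(recipient_keys)) {
    self <- panel$key %in% recipient_keys
    if (any(self)) {
      warning("dropping ", sum(self), " self-reactive bead result(s) ",
              "(bead antigen key matches recipient typing)", call. = FALSE)
      panel <- panel[!self, , drop = FALSE]
    }
  }
  if (!any(panel$sample_date <= transplant_date)) {
    if (strict) {
      stop("no pre-transplant baseline panel available", call. = FALSE)
    }
    warning("no pre-transplant baseline panel; assuming no preformed DSA",
            call. = FALSE)
  }

  pre_cut <- failure_date + baseline_window_days
  key_to_group <- function(k) {
    loc <- sub("\\*.*$", "", k)
    names(LOCUS_GROUPS)[vapply(LOCUS_GROUPS, function(l) loc %in% l, logical(1))][1]
  }
  rows <- lapply(sort(unique(donor_targets)), function(tg) {
    hits <- panel[panel$key == tg & panel$mfi > mfi_threshold, , drop = FALSE]
    preformed <- any(hits$sample_date <= transplant_date)
    post_tx <- hits$sample_date[hits$sample_date > transplant_date]
    if (preformed || length(post_tx) == 0L) return(NULL)
    in_pre <- any(post_tx <= pre_cut)
    in_post <- any(post_tx > pre_cut)
    data.frame(patient_id = pid, target = tg, locus_group = key_to_group(tg),
               first_detected = min(post_tx),
               timing = if (in_pre && in_post) "BOTH"
                        else if (in_pre) "PRE_FAILURE" else "POST_FAILURE",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}
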