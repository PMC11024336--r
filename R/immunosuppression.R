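# Post-failure maintenance immunosuppression timelines and the
# maintained-vs-reduced exposure classification.

IS_CATEGORIES <- c("CNI_MMF", "CNI_MONO", "MMF_MONO", "WITHDRAWN")
CNI_DRUGS <- c("TACROLIMUS", "CYCLOSPORIN", "NONE")

#' Read an immunosuppression timeline CSV
#'
#' Expects columns `patient_id`, `start`, `end` (ISO dates), `category` (one
#' of CNI_MMF, CNI_MONO, MMF_MONO, WITHDRAWN) and `cni_drug` (TACROLIMUS,
#' CYCLOSPORIN or NONE). Intervals are validated per patient: start < end,
#' non-overlapping in date order, and category consistent with the CNI drug
#' (MMF_MONO and WITHDRAWN imply NONE; CNI categories require a drug).
#'
#' @param path Path to the CSV file.
#' @return data.table of validated intervals.
#' @export
read_is_timeline <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("patient_id", "start", "end", "category", "cni_drug")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("IS timeline '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt[, `:=`(patient_id = as.character(patient_id),
            start = as.Date(start), end = as.Date(end),
            category = as.character(category),
            cni_drug = as.character(cni_drug))]
  validate_is_intervals(dt)
  dt[]
}

validate_is_intervals <- function(dt) {
  bad_cat <- setdiff(unique(dt$category), IS_CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown IS category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  bad_drug <- setdiff(unique(dt$cni_drug), CNI_DRUGS)
  if (length(bad_drug)) {
    stop("unknown CNI drug: ", paste(bad_drug, collapse = ", "), call. = FALSE)
  }
  if (any(dt$start >= dt$end)) {
    stop("IS interval with start >= end", call. = FALSE)
  }
  no_cni <- dt$category %in% c("MMF_MONO", "WITHDRAWN")
  if (any(no_cni & dt$cni_drug != "NONE")) {
    stop("MMF_MONO/WITHDRAWN intervals must have cni_drug = NONE",
         call. = FALSE)
  }
  if (any(!no_cni & dt$cni_drug == "NONE")) {
    stop("CNI_MMF/CNI_MONO intervals require a CNI drug", call. = FALSE)
  }
  for (pid in unique(dt$patient_id)) {
    iv <- dt[dt$patient_id == pid, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)])) {
      stop("overlapping IS intervals for patient '", pid, "'", call. = FALSE)
    }
  }
  invisible(dt)
}

#' Read CNI trough levels from CSV
#'
#' Expects columns `patient_id`, `date`, `ng_per_ml`.
#'
#' @param path Path to the CSV file.
#' @return data.table of trough measurements.
#' @export
read_troughs <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("patient_id", "date", "ng_per_ml")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("trough file '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt[, `:=`(patient_id = as.character(patient_id), date = as.Date(date),
            ng_per_ml = as.numeric(ng_per_ml))]
  if (any(is.na(dt$ng_per_ml)) || any(dt$ng_per_ml < 0)) {
    stop("trough levels must be non-negative numbers", call. = FALSE)
  }
  dt[]
}

#' Average CNI trough level over a timeline
#'
#' Arithmetic mean (unweighted by interval length) of all trough measurements
#' falling inside CNI-containing intervals. A CNI interval with no
#' measurement raises a warning and contributes nothing; with no CNI exposure
#' at all the result is `NA`. Optionally a time-weighted mean (per-interval
#' means weighted by interval length in days) is available.
#'
#' @param intervals data.frame of one patient's IS intervals (`start`, `end`,
#'   `category`, `cni_drug`).
#' @param troughs data.frame of the same patient's measurements (`date`,
#'   `ng_per_ml`).
#' @param time_weighted If `TRUE`, weight per-interval means by interval
#'   duration.
#' @return Mean trough in ng/mL, or `NA_real_` with no usable CNI exposure.
#' @export
average_trough <- function(intervals, troughs, time_weighted = FALSE) {
  cni <- intervals[intervals$category %in% c("CNI_MMF", "CNI_MONO"), ,
                   drop = FALSE]
  if (nrow(cni) == 0L) return(NA_real_)
  per <- lapply(seq_len(nrow(cni)), function(i) {
    sel <- troughs$date >= cni$start[i] & troughs$date <= cni$end[i]
    vals <- troughs$ng_per_ml[sel]
    if (length(vals) == 0L) {
      warning("CNI interval ", format(cni$start[i]), "..", format(cni$end[i]),
              " has no trough measurement; excluded from average",
              call. = FALSE)
      return(NULL)
    }
    list(vals = vals,
         weight = as.numeric(cni$end[i] - cni$start[i]))
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0L) return(NA_real_)
  if (time_weighted) {
    m <- vapply(per, function(p) mean(p$vals), numeric(1))
    w <- vapply(per, function(p) p$weight, numeric(1))
    sum(m * w) / sum(w)
  } else {
    mean(unlist(lapply(per, `[[`, "vals")))
  }
}

#' Classify immunosuppression exposure as reduced or maintained
#'
#' A patient's post-failure exposure counts as *reduced* when any of three
#' criteria holds: (1) complete withdrawal (a WITHDRAWN interval exists);
#' (2) CNI cessation — a CNI-containing interval is followed later in the
#' timeline by an interval without CNI; (3) the average CNI trough level is
#' below `trough_cutoff`. An average trough exactly at the cutoff is
#' *maintained* (the maintained reference group is defined by troughs >= 5
#' ng/mL). Everything else is maintained.
#'
#' @param intervals data.frame of one patient's IS intervals.
#' @param troughs data.frame of the patient's trough measurements.
#' @param trough_cutoff ng/mL cut, default 5.
#' @param time_weighted Passed to [average_trough()].
#' @return Logical: `TRUE` = reduced, `FALSE` = maintained.
#' @export
classify_reduced <- function(intervals, troughs, trough_cutoff = 5,
                             time_weighted = FALSE) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    stop("empty immunosuppression timeline", call. = FALSE)
  }
  iv <- intervals[order(intervals$start), , drop = FALSE]
  if ("WITHDRAWN" %in% iv$category) return(TRUE)
  has_cni <- iv$category %in% c("CNI_MMF", "CNI_MONO")
  if (any(has_cni)) {
    last_cni <- max(which(has_cni))
    if (last_cni < nrow(iv)) return(TRUE)  # CNI ceased during follow-up
    avg <- average_trough(iv, troughs, time_weighted)
    if (!is.na(avg) && avg < trough_cutoff) return(TRUE)
  }
  FALSE
}

#' Per-patient immunosuppression exposure table
#'
#' @param timeline data.frame of intervals for many patients (see
#'   [read_is_timeline()]).
#' @param troughs data.frame of trough measurements for many patients.
#' @param trough_cutoff,time_weighted Passed to [classify_reduced()].
#' @return data.frame: `patient_id`, `avg_trough`, `reduced`.
#' @export
is_exposure_table <- function(timeline, troughs, trough_cutoff = 5,
                              time_weighted = FALSE) {
  ids <- unique(timeline$patient_id)
  out <- lapply(ids, function(pid) {
    iv <- timeline[timeline$patient_id == pid, , drop = FALSE]
    tr <- troughs[troughs$patient_id == pid, , drop = FALSE]
    data.frame(patient_id = pid,
               avg_trough = average_trough(iv, tr, time_weighted),
               reduced = classify_reduced(iv, tr, trough_cutoff,
                                          time_weighted),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
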