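# cPRA against an explicit donor reference panel, and the meaningful-cPRA
# (mcPRA) donor-pool-reduction statistic.

#' Construct a donor reference panel
#'
#' @param phenotypes Named list: donor id -> character vector of antigen keys
#'   (the donor's HLA phenotype across the eleven loci).
#' @param source Provenance label.
#' @return Object of class `donor_panel`.
#' @export
donor_panel <- function(phenotypes, source = "unspecified") {
  stopifnot(is.list(phenotypes), length(phenotypes) > 0L)
  n_ag <- vapply(phenotypes, length, integer(1))
  if (any(n_ag == 0L)) {
    stop("donor panel phenotypes must carry at least one antigen key",
         call. = FALSE)
  }
  structure(list(phenotypes = lapply(phenotypes, unique),
                 source = as.character(source)),
            class = "donor_panel")
}

#' @export
print.donor_panel <- function(x, ...) {
  cat("<donor_panel> ", length(x$phenotypes), " donors (source: ", x$source,
      ")\n", sep = "")
  invisible(x)
}

#' Read a donor reference panel from TSV
#'
#' Expects columns `donor_id` and `antigens` (semicolon-separated antigen
#' keys).
#'
#' @param path Path to the TSV file.
#' @param source Provenance label; defaults to the file name.
#' @return A `donor_panel`.
#' @export
read_donor_panel <- function(path, source = basename(path)) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          header = TRUE)
  miss <- setdiff(c("donor_id", "antigens"), names(dt))
  if (length(miss)) {
    stop("donor panel '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ph <- strsplit(dt$antigens, ";", fixed = TRUE)
  names(ph) <- dt$donor_id
  donor_panel(ph, source = source)
}

#' Calculated panel reactive antibody (cPRA)
#'
#' The percentage of reference-panel donors carrying at least one antigen on
#' the patient's unacceptable list. This panel-based formulation is used in
#' place of a registry haplotype-frequency calculator: it is reproducible
#' from an explicit donor file and coincides with the frequency computation
#' when the panel enumerates the donor population. Reported to two decimal
#' places, the convention of national calculators (e.g. the 94.50% highly
#' sensitized cut).
#'
#' @param unacceptable Character vector of antigen keys (may be empty).
#' @param panel A `donor_panel`.
#' @return cPRA percent in \[0, 100\], rounded to 2 decimals.
#' @examples
#' p <- donor_panel(list(d1 = "A*02", d2 = c("A*01", "B*07"), d3 = "A*03"))
#' compute_cpra("A*02", p)  # 33.33
#' @export
compute_cpra <- function(unacceptable, panel) {
  stopifnot(inherits(panel, "donor_panel"))
  if (length(unacceptable) == 0L) return(0)
  hit <- vapply(panel$phenotypes, function(ph) any(ph %in% unacceptable),
                logical(1))
  round(100 * mean(hit), 2)
}

#' Compatible donor pool size
#'
#' @param cpra cPRA percent in \[0, 100\] (vectorized).
#' @return Pool percent, `100 - cpra`.
#' @export
donor_pool <- function(cpra) {
  if (any(is.na(cpra)) || any(cpra < 0) || any(cpra > 100)) {
    stop("cPRA must lie in [0, 100]", call. = FALSE)
  }
  100 - cpra
}

#' Relative reduction of the compatible donor pool
#'
#' `100 * (pool(baseline) - pool(last)) / pool(baseline)` with
#' `pool(c) = 100 - c`. The same absolute cPRA rise shrinks the pool far more
#' for an already-sensitized patient: 0% -> 2% is a 2% pool reduction, while
#' 96% -> 98% halves the remaining pool (50%). Negative values (a cPRA fall)
#' are returned as-is.
#'
#' @param baseline_cpra,last_cpra cPRA percents (vectorized); baseline must be
#'   < 100 (a patient already at zero pool has no defined relative reduction).
#' @return Pool reduction percent.
#' @export
pool_reduction <- function(baseline_cpra, last_cpra) {
  pb <- donor_pool(baseline_cpra)
  pl <- donor_pool(last_cpra)
  if (any(pb == 0)) {
    stop("pool reduction undefined at baseline cPRA = 100 (empty pool)",
         call. = FALSE)
  }
  100 * (pb - pl) / pb
}

#' Meaningful cPRA change (mcPRA) flag
#'
#' A cPRA rise is meaningful when it reduces the compatible donor pool by 50%
#' or more relative to baseline (inclusive boundary). This puts each
#' patient's change on the same scale regardless of baseline sensitization.
#'
#' @param baseline_cpra,last_cpra cPRA percents (vectorized).
#' @param reduction_cutoff Pool-reduction percent defining "meaningful"
#'   (default 50).
#' @return Logical vector.
#' @export
mcpra_flag <- function(baseline_cpra, last_cpra, reduction_cutoff = 50) {
  pool_reduction(baseline_cpra, last_cpra) >= reduction_cutoff
}

#' Smallest last cPRA that triggers the mcPRA flag
#'
#' Closed form `100 - (1 - cutoff/100) * (100 - baseline)`: with the default
#' 50% cutoff, a baseline of 0% must reach 50% and a baseline of 96% must
#' reach 98%.
#'
#' @param baseline_cpra Baseline cPRA percent (vectorized), < 100.
#' @param reduction_cutoff Pool-reduction percent (default 50).
#' @return The threshold last cPRA percent.
#' @export
mcpra_threshold <- function(baseline_cpra, reduction_cutoff = 50) {
  pb <- donor_pool(baseline_cpra)
  if (any(pb == 0)) {
    stop("mcPRA threshold undefined at baseline cPRA = 100", call. = FALSE)
  }
  100 - (1 - reduction_cutoff / 100) * pb
}

#' Highly sensitized patient flag
#'
#' @param cpra cPRA percent (vectorized).
#' @param cutoff Highly-sensitized cut, default 94.50 (the Canadian registry
#'   definition; inclusive).
#' @return Logical vector.
#' @export
hsp_flag <- function(cpra, cutoff = 94.50) {
  donor_pool(cpra)  # range check
  cpra >= cutoff
}

#' Assemble a per-patient sensitization record
#'
#' @param patient_id Identifier.
#' @param baseline_cpra,last_cpra cPRA percents.
#' @param baseline_date,last_date Sample dates.
#' @param reduction_cutoff mcPRA pool-reduction cut (default 50).
#' @param hsp_cutoff Highly-sensitized cut (default 94.50).
#' @return One-row data.frame with `delta_cpra`, `pool_reduction`, `mcpra`,
#'   `hsp_baseline`, `hsp_last`. `pool_reduction` and `mcpra` are `NA` when
#'   baseline cPRA is 100 (undefined relative change).
#' @export
sensitization_record <- function(patient_id, baseline_cpra, last_cpra,
                                 baseline_date = NA, last_date = NA,
                                 reduction_cutoff = 50, hsp_cutoff = 94.50) {
  pr <- if (baseline_cpra < 100) {
    pool_reduction(baseline_cpra, last_cpra)
  } else NA_real_
  data.frame(
    patient_id = as.character(patient_id),
    baseline_cpra = baseline_cpra, last_cpra = last_cpra,
    baseline_date = as.Date(baseline_date), last_date = as.Date(last_date),
    delta_cpra = last_cpra - baseline_cpra,
    pool_reduction = pr,
    mcpra = if (is.na(pr)) NA else pr >= reduction_cutoff,
    hsp_baseline = hsp_flag(baseline_cpra, hsp_cutoff),
    hsp_last = hsp_flag(last_cpra, hsp_cutoff),
    stringsAsFactors = FALSE
  )
}
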