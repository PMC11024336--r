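# Eplet registry and donor-against-recipient eplet mismatch.

#' Construct an eplet registry
#'
#' @param entries Named list: canonical allele string -> character vector of
#'   eplet names.
#' @param version Free-text provenance label recorded in outputs.
#' @return Object of class `eplet_registry`.
#' @export
eplet_registry <- function(entries, version = "unversioned") {
  stopifnot(is.list(entries), length(entries) > 0L)
  entries <- lapply(entries, function(e) {
    e <- unique(as.character(e))
    if (any(!nzchar(e))) stop("empty eplet name in registry", call. = FALSE)
    e
  })
  structure(list(entries = entries, version = as.character(version)),
            class = "eplet_registry")
}

#' @export
print.eplet_registry <- function(x, ...) {
  cat("<eplet_registry> ", length(x$entries), " alleles, ",
      length(unique(unlist(x$entries))), " distinct eplets (version: ",
      x$version, ")\n", sep = "")
  invisible(x)
}

#' Load an eplet registry from a TSV file
#'
#' Expects header columns `allele` and `eplet`, one row per (allele, eplet)
#' assignment. Duplicate rows collapse; the per-allele eplet set is the union
#' over its rows.
#'
#' @param path Path to the TSV file.
#' @param version Provenance label; defaults to the file name.
#' @return An `eplet_registry`.
#' @export
load_eplet_registry <- function(path, version = basename(path)) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          header = TRUE)
  miss <- setdiff(c("allele", "eplet"), names(dt))
  if (length(miss)) {
    stop("eplet registry '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(dt) == 0L) stop("eplet registry '", path, "' is empty", call. = FALSE)
  eplet_registry(lapply(split(dt$eplet, dt$allele), unique), version = version)
}

#' Look up the eplet set of one allele
#'
#' Lookup is by exact canonical allele string first, then by two-field
#' truncation (so `"A*02:01:01"` falls back to `"A*02:01"`). Unresolved
#' alleles are a hard error by default: silently treating them as eplet-free
#' would bias mismatch counts low.
#'
#' @param registry An `eplet_registry`.
#' @param allele Allele string or `hla_allele`.
#' @param on_missing `"error"` (default) or `"skip"` (return `NULL` with a
#'   warning).
#' @return Character vector of eplet names, or `NULL` when skipped.
#' @export
eplet_lookup <- function(registry, allele, on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(registry, "eplet_registry"))
  key <- format(as_allele(allele))
  hit <- registry$entries[[key]]
  if (is.null(hit)) hit <- registry$entries[[truncate_two_field(key)]]
  if (is.null(hit)) {
    msg <- paste0("allele '", key, "' not found in eplet registry (version: ",
                  registry$version, ")")
    if (on_missing == "error") stop(msg, call. = FALSE)
    warning(msg, "; skipping", call. = FALSE)
    return(NULL)
  }
  hit
}

#' Eplet repertoire of a subject over a locus group
#'
#' Union of the eplet sets of all alleles the subject carries at the group's
#' loci. Absent DRB3/4/5 loci contribute nothing; homozygosity contributes the
#' allele's set once (set semantics throughout).
#'
#' @param g An `hla_genotype`.
#' @param group Group name or locus vector.
#' @param registry An `eplet_registry`.
#' @param on_missing Passed to [eplet_lookup()].
#' @return Character vector of eplet names (unique, possibly empty).
#' @export
subject_eplets <- function(g, group, registry,
                           on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  alleles <- genotype_alleles(g, group)
  sets <- lapply(alleles, eplet_lookup, registry = registry,
                 on_missing = on_missing)
  unique(unlist(sets, use.names = FALSE)) %||% character(0)
}

#' Donor-against-recipient eplet mismatch for one locus group
#'
#' Mismatched eplets are those present on at least one donor allele at the
#' group's loci but absent from the recipient's whole repertoire at those
#' loci (host-versus-graft antibody direction). Each eplet is counted once
#' regardless of how many donor alleles carry it, matching the convention of
#' a single per-group count.
#'
#' @param donor,recipient `hla_genotype` objects.
#' @param group Group name (`"CLASS_I"`, `"DR"`, `"DQ"`, `"DP"`) or loci.
#' @param registry An `eplet_registry`.
#' @param threshold Eplet count at and above which the category is `HIGH`
#'   (default 12, i.e. low = 0-11). Only DR and DQ have an established
#'   categorical threshold; it is applied uniformly but class I / DP
#'   categories should be read as descriptive.
#' @param on_missing Passed to [eplet_lookup()].
#' @return Object of class `mismatch_result`: list with `pair_id`, `group`,
#'   `mismatched_eplets`, `count`, `category`.
#' @examples
#' reg <- eplet_registry(list("DQB1*03:01" = c("e1", "e2"),
#'                            "DQB1*05:01" = c("e2", "e3")))
#' d <- genotype("D", list(DQB1 = "DQB1*03:01"))
#' r <- genotype("R", list(DQB1 = "DQB1*05:01"))
#' eplet_mismatch(d, r, "DQ", reg)$count  # e1 only -> 1
#' @export
eplet_mismatch <- function(donor, recipient, group, registry, threshold = 12L,
                           on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  de <- subject_eplets(donor, group, registry, on_missing)
  re <- subject_eplets(recipient, group, registry, on_missing)
  mm <- setdiff(de, re)
  structure(list(
    pair_id = paste0(donor$subject_id, "->", recipient$subject_id),
    group = if (length(group) == 1L && group %in% names(LOCUS_GROUPS))
      group else paste(group, collapse = "+"),
    mismatched_eplets = mm,
    count = length(mm),
    category = categorize_mismatch(length(mm), threshold)
  ), class = "mismatch_result")
}

#' @export
print.mismatch_result <- function(x, ...) {
  cat("<mismatch_result> ", x$pair_id, " [", x$group, "]: ", x$count,
      " mismatched eplets (", x$category, ")\n", sep = "")
  invisible(x)
}

#' Categorize an eplet mismatch count as LOW or HIGH
#'
#' Low is 0 to `threshold - 1` mismatched eplets; high is `threshold` or
#' more. The default threshold of 12 is the published low/high cut for both
#' DR and DQ (low = 0-11, high = 12+).
#'
#' @param count Non-negative integer vector of eplet mismatch counts.
#' @param threshold Cut point (default 12).
#' @return Character vector, `"LOW"` or `"HIGH"`.
#' @export
categorize_mismatch <- function(count, threshold = 12L) {
  if (any(is.na(count)) || any(count < 0)) {
    stop("mismatch count must be non-negative", call. = FALSE)
  }
  ifelse(count >= threshold, "HIGH", "LOW")
}

#' Per-pair, per-group mismatch table
#'
#' @param pairs data.frame with columns `pair_id`, `donor_id`, `recipient_id`.
#' @param genotypes Named list of `hla_genotype` (donors and recipients).
#' @param registry An `eplet_registry`.
#' @param groups Group names to evaluate (default all four).
#' @param threshold Low/high cut passed to [eplet_mismatch()].
#' @param on_missing Passed to [eplet_lookup()].
#' @return data.frame: `pair_id`, `donor_id`, `recipient_id`, `group`,
#'   `count`, `category`, `registry_version`.
#' @export
mismatch_table <- function(pairs, genotypes, registry,
                           groups = names(LOCUS_GROUPS), threshold = 12L,
                           on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- genotypes[[pairs$donor_id[i]]]
    r <- genotypes[[pairs$recipient_id[i]]]
    if (is.null(d) || is.null(r)) {
      stop("pair '", pairs$pair_id[i], "': missing genotype for ",
           if (is.null(d)) pairs$donor_id[i] else pairs$recipient_id[i],
           call. = FALSE)
    }
    do.call(rbind, lapply(groups, function(gr) {
      m <- eplet_mismatch(d, r, gr, registry, threshold, on_missing)
      data.frame(pair_id = pairs$pair_id[i], donor_id = pairs$donor_id[i],
                 recipient_id = pairs$recipient_id[i], group = gr,
                 count = m$count, category = m$category,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$registry_version <- registry$version
  out
}
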