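# HLA allele / genotype data model and parsing.

#' Recognized HLA loci
#'
#' The eleven loci handled by the package: the class I loci A, B and C, the
#' DR-beta loci DRB1 and the secondary DRB3/4/5 loci (absent on some
#' haplotypes), the DQ loci DQA1/DQB1 and the DP loci DPA1/DPB1.
#'
#' @format Character vector of locus names.
#' @export
HLA_LOCI <- c("A", "B", "C",
              "DRB1", "DRB3", "DRB4", "DRB5",
              "DQA1", "DQB1", "DPA1", "DPB1")

#' HLA locus groups
#'
#' Fixed, disjoint grouping of loci used for per-group eplet mismatch counts
#' and antibody calls: `CLASS_I` = A/B/C, `DR` = DRB1/DRB3/DRB4/DRB5,
#' `DQ` = DQA1/DQB1, `DP` = DPA1/DPB1.
#'
#' @format Named list of character vectors.
#' @export
LOCUS_GROUPS <- list(
  CLASS_I = c("A", "B", "C"),
  DR      = c("DRB1", "DRB3", "DRB4", "DRB5"),
  DQ      = c("DQA1", "DQB1"),
  DP      = c("DPA1", "DPB1")
)

# Loci that may legitimately carry zero alleles (null haplotypes).
NULLABLE_LOCI <- c("DRB3", "DRB4", "DRB5")

#' Resolve a locus-group name to its loci
#'
#' @param group Either a group name (`"CLASS_I"`, `"DR"`, `"DQ"`, `"DP"`) or a
#'   character vector of locus names.
#' @return Character vector of locus names.
#' @export
locus_group <- function(group) {
  if (length(group) == 1L && group %in% names(LOCUS_GROUPS)) {
    return(LOCUS_GROUPS[[group]])
  }
  bad <- setdiff(group, HLA_LOCI)
  if (length(bad)) {
    stop("unknown locus group or loci: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  group
}

#' Parse an HLA allele string
#'
#' Accepts the standard colon-delimited nomenclature `LOCUS*F1:F2[:F3...]`
#' with an optional trailing expression suffix letter (N, L, S, C, A or Q).
#' The locus is matched case-insensitively; the suffix is retained on the
#' object but ignored for all matching (antigen keys, registry lookup).
#'
#' @param text Single allele string, e.g. `"DQB1*03:01"`.
#' @return An object of class `hla_allele`: a list with elements `locus`
#'   (locus name), `fields` (character vector of numeric field strings) and
#'   `suffix` (expression suffix, `""` if none).
#' @examples
#' parse_allele("DQB1*03:01")
#' parse_allele("A*02:01:01")
#' @export
parse_allele <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("allele must be a single character string", call. = FALSE)
  }
  m <- regmatches(text, regexec(
    "^([A-Za-z][A-Za-z0-9]*)\\*([0-9]+(?::[0-9]+)*)([NLSCAQ]?)$", text))[[1]]
  if (length(m) == 0L) {
    stop("malformed allele string: '", text, "'", call. = FALSE)
  }
  locus <- toupper(m[2])
  if (!locus %in% HLA_LOCI) {
    stop("unknown locus '", m[2], "' in allele '", text, "'", call. = FALSE)
  }
  structure(list(locus = locus,
                 fields = strsplit(m[3], ":", fixed = TRUE)[[1]],
                 suffix = m[4]),
            class = "hla_allele")
}

#' @export
format.hla_allele <- function(x, ...) {
  paste0(x$locus, "*", paste(x$fields, collapse = ":"), x$suffix)
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.hla_allele <- function(x, ...) format(x)

as_allele <- function(x) {
  if (inherits(x, "hla_allele")) x else parse_allele(x)
}

#' Antigen-level key of an allele
#'
#' Truncates an allele to its locus and first field (`"DQB1*03:01"` ->
#' `"DQB1*03"`), the package's antigen-level equivalence class. True serologic
#' split/broad tables need external data, and allelic antibodies are out of
#' scope, so the first field is used as a deterministic stand-in and all
#' antigen-level matching (DSA specificity, cPRA) operates on these keys.
#'
#' @param x An `hla_allele`, an allele string, or a character vector of allele
#'   strings (vectorized).
#' @return Character vector of antigen keys.
#' @examples
#' antigen_key("DQB1*03:01")  # "DQB1*03"
#' antigen_key(c("A*02:01:01", "DQB1*03:02"))
#' @export
antigen_key <- function(x) {
  if (inherits(x, "hla_allele")) {
    return(paste0(x$locus, "*", x$fields[1]))
  }
  # parse each distinct allele string once; bead tables repeat few alleles
  ux <- unique(x)
  uk <- vapply(ux, function(a) {
    al <- as_allele(a)
    paste0(al$locus, "*", al$fields[1])
  }, character(1), USE.NAMES = FALSE)
  uk[match(x, ux)]
}

#' Locus of an allele
#'
#' @param x An `hla_allele`, an allele string, or a character vector of allele
#'   strings (vectorized).
#' @return Character vector of locus names.
#' @export
allele_locus <- function(x) {
  if (inherits(x, "hla_allele")) return(x$locus)
  ux <- unique(x)
  ul <- vapply(ux, function(a) as_allele(a)$locus, character(1),
               USE.NAMES = FALSE)
  ul[match(x, ux)]
}

# Canonical two-field truncation of an allele string ("A*02:01:01" -> "A*02:01").
truncate_two_field <- function(x) {
  vapply(x, function(a) {
    al <- as_allele(a)
    paste0(al$locus, "*", paste(al$fields[seq_len(min(2L, length(al$fields)))],
                                collapse = ":"))
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a genotype
#'
#' A genotype holds 0-2 alleles per locus for one subject. DRB3/DRB4/DRB5 may
#' carry zero alleles (null haplotypes); a single allele at a locus encodes
#' reported homozygosity (copy number never matters downstream: eplet sets and
#' antigen reactivity are set-valued).
#'
#' @param subject_id Subject identifier.
#' @param alleles Named list, locus -> character vector of allele strings
#'   (0-2 per locus). Loci not named are treated as untyped/absent.
#' @return Object of class `hla_genotype`.
#' @export
genotype <- function(subject_id, alleles) {
  stopifnot(is.list(alleles))
  bad <- setdiff(names(alleles), HLA_LOCI)
  if (length(bad)) {
    stop("unknown loci in genotype for subject '", subject_id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(vector("list", length(HLA_LOCI)), HLA_LOCI)
  for (loc in HLA_LOCI) {
    a <- unique(as.character(alleles[[loc]] %||% character(0)))
    if (length(a) > 2L) {
      stop("subject '", subject_id, "' has ", length(a),
           " distinct alleles at locus ", loc, " (max 2)", call. = FALSE)
    }
    if (length(a)) {
      wrong <- allele_locus(a) != loc
      if (any(wrong)) {
        stop("allele '", a[wrong][1], "' listed under locus ", loc,
             " for subject '", subject_id, "'", call. = FALSE)
      }
    }
    full[[loc]] <- a
  }
  structure(list(subject_id = as.character(subject_id), alleles = full),
            class = "hla_genotype")
}

#' @export
print.hla_genotype <- function(x, ...) {
  cat("<hla_genotype> subject ", x$subject_id, "\n", sep = "")
  for (loc in HLA_LOCI) {
    a <- x$alleles[[loc]]
    if (length(a)) cat("  ", loc, ": ", paste(a, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Alleles of a genotype at a set of loci
#'
#' @param g An `hla_genotype`.
#' @param group Group name or locus vector (see [locus_group()]).
#' @return Character vector of allele strings (possibly empty).
#' @export
genotype_alleles <- function(g, group) {
  stopifnot(inherits(g, "hla_genotype"))
  unlist(g$alleles[locus_group(group)], use.names = FALSE)
}

#' Read genotypes from a TSV file
#'
#' Expects a tab-delimited UTF-8 file with header columns `subject_id`,
#' `locus`, `allele`; one row per allele copy. Duplicate identical rows
#' collapse to a single (homozygous) entry; more than two distinct alleles at
#' one locus for one subject is a validation error.
#'
#' @param path Path to the TSV file.
#' @return Named list of `hla_genotype`, keyed by subject id.
#' @export
read_genotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          header = TRUE)
  need <- c("subject_id", "locus", "allele")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("genotype file '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  genotypes_from_table(dt[, need, with = FALSE])
}

#' Assemble genotypes from a long table
#'
#' @param tab data.frame with columns `subject_id`, `locus`, `allele`.
#' @return Named list of `hla_genotype`.
#' @export
genotypes_from_table <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$subject_id), function(d) {
    genotype(d$subject_id[1], split(d$allele, d$locus))
  })
  out[unique(tab$subject_id)]
}

#' Validate a genotype file and report problems
#'
#' @param path Path to a genotype TSV.
#' @return Invisibly, the parsed genotype list; errors describe the offending
#'   subject/locus/allele.
#' @export
validate_genotypes <- function(path) {
  g <- read_genotypes(path)
  invisible(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
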