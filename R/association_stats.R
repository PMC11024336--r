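# Self-contained association tests and descriptive summaries:
# two-sided Fisher exact test by the point-probability method, two-sample t
# test (Welch or pooled), and median/IQR by the linear-interpolation quantile
# convention.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Implemented from first principles: with both margins fixed, the upper-left
#' cell follows a hypergeometric distribution; the two-sided p-value is the
#' sum of probabilities of all tables whose probability does not exceed that
#' of the observed table (point-probability / minimum-likelihood method, the
#' convention of mainstream statistics environments). Probabilities are
#' compared with a relative tolerance of 1e-7 to absorb floating-point ties.
#'
#' @param x A 2x2 matrix of non-negative integer counts (rows = exposure,
#'   columns = outcome), or the cell `a` with `b`, `c`, `d` given separately
#'   (row-major: `a b / c d`).
#' @param b,c,d Remaining cells when `x` is scalar.
#' @return The two-sided p-value in (0, 1]. A zero row or column margin
#'   returns 1 with a warning (no information against independence).
#' @examples
#' fisher_exact(matrix(c(9, 1, 4, 7), 2, 2, byrow = TRUE))  # ~0.024
#' @export
fisher_exact <- function(x, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2L, 2L)))
    a <- x[1, 1]; b <- x[1, 2]; c <- x[2, 1]; d <- x[2, 2]
  } else {
    a <- x
    stopifnot(!is.null(b), !is.null(c), !is.null(d))
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("2x2 cells must be non-negative integers", call. = FALSE)
  }
  n <- sum(cells)
  if (n < 1) stop("table total must be >= 1", call. = FALSE)
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("a zero margin carries no information; p = 1 by convention",
            call. = FALSE)
    return(1)
  }
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  # log hypergeometric pmf over the support, built from binomial coefficients
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
  p_obs <- logp[support == a]
  keep <- logp <= p_obs + log(1 + 1e-7)
  min(1, sum(exp(logp[keep])))
}

#' Two-sample t test
#'
#' Two-sided p-value for a difference in means, with Welch's unequal-variance
#' degrees of freedom (default) or the pooled-variance Student form.
#'
#' @param x,y Numeric samples, each of size >= 2; at least one must have
#'   nonzero variance.
#' @param welch Use the Welch-Satterthwaite approximation (default `TRUE`).
#' @return List with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y, welch = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    stop("both samples are constant; t statistic undefined", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df),
       mean_x = mean(x), mean_y = mean(y))
}

#' Median with interquartile range
#'
#' Quantiles use the linear-interpolation convention (the default "type 7" of
#' most statistics environments): for probability p on a sorted sample of
#' size n, position h = (n - 1) p + 1 and the value is interpolated between
#' the floor(h)-th and ceiling(h)-th order statistics.
#'
#' @param values Numeric vector, length >= 1, no NAs.
#' @return Object of class `summary_stat`: list with `median`, `iqr_low`
#'   (25th), `iqr_high` (75th) and `n`.
#' @examples
#' median_iqr(c(1, 2, 3))  # median 2, IQR (1.5, 2.5)
#' @export
median_iqr <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(is.na(values))) {
    stop("values must be a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  s <- sort(values)
  n <- length(s)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  structure(list(median = q(0.5), iqr_low = q(0.25), iqr_high = q(0.75),
                 n = n),
            class = "summary_stat")
}

#' @export
format.summary_stat <- function(x, digits = 2, ...) {
  sprintf("%s (IQR = %s, %s), n = %d",
          formatC(x$median, format = "f", digits = digits),
          formatC(x$iqr_low, format = "f", digits = digits),
          formatC(x$iqr_high, format = "f", digits = digits), x$n)
}

#' @export
print.summary_stat <- function(x, ...) {
  cat("<summary_stat> ", format(x, ...), "\n", sep = "")
  invisible(x)
}

#' Build the standard 2x2 association tables from a cohort table
#'
#' Emits the four exposure-by-outcome tables driving the association
#' analysis: DQ mismatch category vs mcPRA, DR vs mcPRA, DQ vs DQ dnDSA, and
#' DR vs DR dnDSA. Rows are LOW/HIGH mismatch, columns outcome no/yes.
#' Patients with an undefined mcPRA (baseline cPRA 100) are excluded from the
#' mcPRA tables and listed in the `exclusions` attribute.
#'
#' @param cohort data.frame with columns `dq_category`, `dr_category`
#'   (LOW/HIGH), `mcpra` (logical, may be NA), `dndsa_dq`, `dndsa_dr`
#'   (logical).
#' @return Named list of 2x2 matrices (`DQ_x_mcPRA`, `DR_x_mcPRA`,
#'   `DQ_x_dnDSA`, `DR_x_dnDSA`) with an `exclusions` attribute.
#' @export
build_tables <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0L) {
    stop("empty cohort table", call. = FALSE)
  }
  need <- c("dq_category", "dr_category", "mcpra", "dndsa_dq", "dndsa_dr")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab2x2 <- function(category, outcome) {
    keep <- !is.na(outcome)
    category <- factor(category[keep], levels = c("LOW", "HIGH"))
    outcome <- factor(outcome[keep], levels = c(FALSE, TRUE),
                      labels = c("no", "yes"))
    tab <- table(category, outcome)
    matrix(as.integer(tab), 2L, 2L, dimnames = dimnames(tab))
  }
  out <- list(
    DQ_x_mcPRA = tab2x2(cohort$dq_category, cohort$mcpra),
    DR_x_mcPRA = tab2x2(cohort$dr_category, cohort$mcpra),
    DQ_x_dnDSA = tab2x2(cohort$dq_category, cohort$dndsa_dq),
    DR_x_dnDSA = tab2x2(cohort$dr_category, cohort$dndsa_dr)
  )
  excl <- which(is.na(cohort$mcpra))
  attr(out, "exclusions") <-
    if ("patient_id" %in% names(cohort)) cohort$patient_id[excl] else excl
  out
}
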