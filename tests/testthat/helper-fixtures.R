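# Shared fixtures: everything is built in code at test time.

# Small hand-written registry used by the worked examples.
toy_registry <- function() {
  eplet_registry(list(
    "DQA1*01:01" = c("qa1", "qa2"),
    "DQA1*05:01" = c("qa3", "qshared"),
    "DQB1*03:01" = c("e1", "e2", "e3", "e4", "e5"),
    "DQB1*03:02" = c("e3", "e4", "e5", "e6"),
    "DQB1*05:01" = c("e4", "e5", "qshared"),
    "DRB1*03:01" = c("r1", "r2"),
    "DRB1*15:01" = c("r2", "r3"),
    "DRB3*01:01" = c("r4"),
    "A*01:01" = c("a1", "a2"),
    "A*02:01" = c("a2", "a3")
  ), version = "toy")
}

write_genotype_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(rows, path, sep = "\t")
  path
}

# Brute-force eplet mismatch oracle: enumerate (donor allele, eplet) pairs
# and filter against the recipient's eplet union. Deliberately ignores the
# set machinery of the implementation.
oracle_mismatch_count <- function(donor, recipient, group, registry) {
  d_alleles <- genotype_alleles(donor, group)
  r_alleles <- genotype_alleles(recipient, group)
  r_union <- character(0)
  for (a in r_alleles) r_union <- c(r_union, eplet_lookup(registry, a))
  seen <- character(0)
  for (a in d_alleles) {
    for (e in eplet_lookup(registry, a)) {
      if (!(e %in% r_union) && !(e %in% seen)) seen <- c(seen, e)
    }
  }
  length(seen)
}

# Random toy world for property tests: random registry over the default
# allele universe plus random genotypes.
random_world <- function(n_eplet_pool = 40) {
  freqs <- default_allele_freqs()
  alleles <- unlist(lapply(freqs, function(d) setdiff(d$allele, "NULL")),
                    use.names = FALSE)
  pool <- paste0("ep", seq_len(n_eplet_pool))
  entries <- lapply(stats::setNames(alleles, alleles), function(a) {
    sample(pool, sample(2:8, 1))
  })
  registry <- eplet_registry(entries, version = "random")
  draw_genotype <- function(id) {
    al <- lapply(freqs, function(d) {
      a <- sample(d$allele, 2, replace = TRUE, prob = d$freq)
      setdiff(a, "NULL")
    })
    genotype(id, al)
  }
  list(registry = registry, draw_genotype = draw_genotype)
}

# Brute-force two-sided Fisher oracle via factorial-ratio probabilities over
# every table with the observed margins (independent of the lchoose route).
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  prob_of <- function(x) {
    bb <- r1 - x; cc <- c1 - x; dd <- n - r1 - c1 + x
    if (bb < 0 || cc < 0 || dd < 0) return(0)
    exp(lfactorial(r1) + lfactorial(n - r1) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(x) -
          lfactorial(bb) - lfactorial(cc) - lfactorial(dd))
  }
  probs <- vapply(0:min(r1, c1), prob_of, numeric(1))
  p_obs <- prob_of(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-patient bead panel builder.
make_panel <- function(dates, positives, all_beads, pos_mfi = 8000,
                       neg_mfi = 100) {
  rows <- lapply(seq_along(dates), function(i) {
    data.frame(patient_id = "P1", sample_date = as.Date(dates[i]),
               bead_allele = all_beads,
               mfi = ifelse(all_beads %in% positives[[i]], pos_mfi, neg_mfi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
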