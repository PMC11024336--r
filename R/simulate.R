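# Synthetic-cohort generator: eplet registry, genotypes, donor reference
# panel, bead panels, immunosuppression timelines and latent ground truth,
# so the full pipeline is exercisable without confidential patient data.

#' Default per-locus allele frequency tables
#'
#' A compact set of common alleles per locus with plausible population
#' frequencies (each locus sums to 1). The nullable DRB3/4/5 loci include a
#' `"NULL"` pseudo-allele whose draw means the haplotype carries no gene
#' copy. Several loci deliberately contain multiple alleles of the same
#' first-field class (e.g. DQB1*03:01 / DQB1*03:02) so that antigen-level
#' grouping and intra-class eplet sharing are exercised.
#'
#' @return Named list: locus -> data.frame(`allele`, `freq`).
#' @export
default_allele_freqs <- function() {
  f <- function(alleles, freqs) data.frame(allele = alleles, freq = freqs,
                                           stringsAsFactors = FALSE)
  list(
    A = f(c("A*01:01", "A*02:01", "A*03:01", "A*11:01", "A*24:02"),
          c(.20, .30, .15, .15, .20)),
    B = f(c("B*07:02", "B*08:01", "B*15:01", "B*35:01", "B*44:02", "B*51:01"),
          c(.20, .15, .15, .15, .20, .15)),
    C = f(c("C*03:04", "C*04:01", "C*05:01", "C*07:01", "C*07:02"),
          c(.15, .25, .10, .25, .25)),
    DRB1 = f(c("DRB1*03:01", "DRB1*04:01", "DRB1*07:01", "DRB1*11:01",
               "DRB1*13:01", "DRB1*15:01"),
             c(.15, .15, .15, .15, .20, .20)),
    DRB3 = f(c("NULL", "DRB3*01:01", "DRB3*02:02", "DRB3*03:01"),
             c(.35, .25, .25, .15)),
    DRB4 = f(c("NULL", "DRB4*01:03"), c(.55, .45)),
    DRB5 = f(c("NULL", "DRB5*01:01"), c(.70, .30)),
    DQA1 = f(c("DQA1*01:01", "DQA1*01:02", "DQA1*02:01", "DQA1*03:01",
               "DQA1*05:01"),
             c(.15, .25, .15, .20, .25)),
    DQB1 = f(c("DQB1*02:01", "DQB1*03:01", "DQB1*03:02", "DQB1*05:01",
               "DQB1*06:02"),
             c(.20, .25, .15, .20, .20)),
    DPA1 = f(c("DPA1*01:03", "DPA1*02:01"), c(.60, .40)),
    DPB1 = f(c("DPB1*02:01", "DPB1*03:01", "DPB1*04:01", "DPB1*04:02"),
             c(.25, .15, .40, .20))
  )
}

#' Simulation configuration
#'
#' Defaults mirror the scale and structure of a small single-centre
#' transplant-failure cohort: 21 patients, graft failure a few years after
#' transplant, a median post-failure antibody follow-up around 27 months,
#' and a latent logistic de novo DSA model driven by the eplet mismatch load
#' and by reduced maintenance immunosuppression. Positive/negative bead MFI
#' ranges sit far from the 1000 calling threshold so antibody calls are
#' deterministic given the latent events.
#'
#' @param seed Integer seed governing every random draw.
#' @param n_patients Number of recipient/donor pairs (default 21).
#' @param n_panel_donors Reference-panel size for cPRA (default 500).
#' @param allele_freqs Per-locus frequency tables
#'   (default [default_allele_freqs()]).
#' @param eplets_per_allele Integer range: eplets carried per allele
#'   (default 5-10, which places per-group DR/DQ mismatch loads on both
#'   sides of the published low/high threshold of 12).
#' @param shared_eplet_fraction Fraction of an allele's eplets shared by all
#'   alleles of its first-field class (default 0.5); drives cross-reactive
#'   epitope spreading.
#' @param dndsa_model List `alpha` (intercept), `beta_mm` (log-odds per
#'   mismatched eplet), `gamma_is` (log-odds for reduced immunosuppression).
#' @param spreading If `TRUE` (default), beads sharing at least one eplet
#'   with a DSA target also turn positive, driving the cPRA rise.
#' @param followup_months Range of post-failure follow-up in months
#'   (default 12-42, median 27).
#' @param months_to_failure Range of transplant-to-failure intervals in
#'   months (default 50-123).
#' @param p_reduced Probability a patient's immunosuppression is reduced
#'   post-failure (default 0.5).
#' @param mfi_positive,mfi_negative Uniform MFI ranges for positive
#'   (default 3000-15000) and negative (default 0-500) beads.
#' @param p_event_prefailure Probability that a latent dnDSA event arises
#'   before graft failure rather than during post-failure follow-up
#'   (default 0.35).
#' @param p_transient_prefailure Probability that a pre-failure antibody
#'   wanes below threshold after the baseline sample (default 0.5); cPRA is
#'   cumulative so waning never lowers it, but it produces the
#'   pre-failure-only timing class.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_patients = 21L, n_panel_donors = 500L,
                       allele_freqs = default_allele_freqs(),
                       eplets_per_allele = c(5L, 10L),
                       shared_eplet_fraction = 0.5,
                       dndsa_model = list(alpha = -3.5, beta_mm = 0.1,
                                          gamma_is = 1.5),
                       spreading = TRUE,
                       followup_months = c(12, 42),
                       months_to_failure = c(50, 123),
                       p_reduced = 0.5,
                       mfi_positive = c(3000, 15000),
                       mfi_negative = c(0, 500),
                       p_event_prefailure = 0.35,
                       p_transient_prefailure = 0.5) {
  stopifnot(n_patients >= 1, n_panel_donors >= 1,
            shared_eplet_fraction >= 0, shared_eplet_fraction <= 1,
            p_reduced >= 0, p_reduced <= 1,
            length(eplets_per_allele) == 2L,
            eplets_per_allele[1] >= 1,
            eplets_per_allele[1] <= eplets_per_allele[2],
            all(c("alpha", "beta_mm", "gamma_is") %in% names(dndsa_model)))
  for (loc in names(allele_freqs)) {
    tot <- sum(allele_freqs[[loc]]$freq)
    if (abs(tot - 1) > 1e-9) {
      stop("allele frequencies at locus ", loc, " sum to ", tot, ", not 1",
           call. = FALSE)
    }
    if (any(allele_freqs[[loc]]$freq < 0)) {
      stop("negative allele frequency at locus ", loc, call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_panel_donors = as.integer(n_panel_donors),
                 allele_freqs = allele_freqs,
                 eplets_per_allele = as.integer(eplets_per_allele),
                 shared_eplet_fraction = shared_eplet_fraction,
                 dndsa_model = dndsa_model, spreading = isTRUE(spreading),
                 followup_months = followup_months,
                 months_to_failure = months_to_failure,
                 p_reduced = p_reduced,
                 mfi_positive = mfi_positive, mfi_negative = mfi_negative,
                 p_event_prefailure = p_event_prefailure,
                 p_transient_prefailure = p_transient_prefailure),
            class = "sim_config")
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

sim_alleles <- function(cfg) {
  unlist(lapply(cfg$allele_freqs, function(d) setdiff(d$allele, "NULL")),
         use.names = FALSE)
}

#' Generate a synthetic eplet registry
#'
#' Every allele of a first-field class carries the same total number of
#' eplets (drawn once per class from `eplets_per_allele`); a
#' `shared_eplet_fraction` share of them is common to the whole class and the
#' remainder is private to the allele. Sharing within a class creates the
#' cross-reactivity that lets antibody spreading inflate cPRA; classes never
#' share eplets with each other.
#'
#' @param cfg A `sim_config`.
#' @return An `eplet_registry` covering every non-null allele in
#'   `cfg$allele_freqs`.
#' @export
make_registry <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  alleles <- sim_alleles(cfg)
  classes <- split(alleles, antigen_key(alleles))
  lo <- cfg$eplets_per_allele[1]; hi <- cfg$eplets_per_allele[2]
  entries <- list()
  for (cls in names(classes)) {
    m <- if (lo == hi) lo else sample(lo:hi, 1L)
    n_shared <- round(cfg$shared_eplet_fraction * m)
    shared <- if (n_shared > 0) paste0(cls, ":s", seq_len(n_shared))
              else character(0)
    for (al in classes[[cls]]) {
      n_priv <- m - n_shared
      priv <- if (n_priv > 0) paste0(al, ":p", seq_len(n_priv))
              else character(0)
      entries[[al]] <- c(shared, priv)
    }
  }
  eplet_registry(entries, version = paste0("synthetic-seed", cfg$seed))
}

sample_one_genotype <- function(id, cfg) {
  alleles <- lapply(cfg$allele_freqs, function(d) {
    a <- sample(d$allele, 2L, replace = TRUE, prob = d$freq)
    setdiff(a, "NULL")
  })
  genotype(id, alleles)
}

#' Sample recipient, donor and reference-panel genotypes
#'
#' Each genotype draws two independent alleles per locus from the configured
#' frequencies (random mating, no linkage between loci). Drawing the `"NULL"`
#' pseudo-allele at DRB3/4/5 leaves that copy absent. The reference panel
#' donors are reduced to antigen-key phenotypes for cPRA.
#'
#' @param cfg A `sim_config`.
#' @return List: `recipients` and `donors` (named lists of `hla_genotype`),
#'   `pairs` (data.frame `pair_id`, `donor_id`, `recipient_id`), and `panel`
#'   (a `donor_panel`).
#' @export
sample_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 2L))
  n <- cfg$n_patients
  rec_ids <- sprintf("P%03d", seq_len(n))
  don_ids <- sprintf("D%03d", seq_len(n))
  recipients <- stats::setNames(lapply(rec_ids, sample_one_genotype, cfg = cfg),
                                rec_ids)
  donors <- stats::setNames(lapply(don_ids, sample_one_genotype, cfg = cfg),
                            don_ids)
  panel_ph <- lapply(seq_len(cfg$n_panel_donors), function(i) {
    g <- sample_one_genotype(sprintf("REF%05d", i), cfg)
    unique(antigen_key(genotype_alleles(g, HLA_LOCI)))
  })
  names(panel_ph) <- sprintf("REF%05d", seq_len(cfg$n_panel_donors))
  list(recipients = recipients, donors = donors,
       pairs = data.frame(pair_id = rec_ids, donor_id = don_ids,
                          recipient_id = rec_ids, stringsAsFactors = FALSE),
       panel = donor_panel(panel_ph,
                           source = paste0("synthetic-seed", cfg$seed)))
}

# Transplant/failure/last dates per patient (months -> ~30.44-day months).
sample_dates_table <- function(cfg, patient_ids) {
  n <- length(patient_ids)
  tx <- as.Date("1998-01-01") + round(stats::runif(n, 0, 15 * 365.25))
  m2f <- stats::runif(n, cfg$months_to_failure[1], cfg$months_to_failure[2])
  fup <- stats::runif(n, cfg$followup_months[1], cfg$followup_months[2])
  data.frame(patient_id = patient_ids,
             transplant_date = tx,
             failure_date = tx + round(m2f * 30.44),
             last_date = tx + round((m2f + fup) * 30.44),
             stringsAsFactors = FALSE)
}

# Post-failure IS timeline + troughs for one patient.
sample_is_one <- function(pid, failure, last, reduced) {
  mk <- function(start, end, category, drug) {
    data.frame(patient_id = pid, start = start, end = end,
               category = category, cni_drug = drug, stringsAsFactors = FALSE)
  }
  tr <- function(start, end, lo, hi, k = 4L) {
    data.frame(patient_id = pid,
               date = start + sort(round(stats::runif(k, 1,
                 max(2, as.numeric(end - start) - 1)))),
               ng_per_ml = round(stats::runif(k, lo, hi), 1),
               stringsAsFactors = FALSE)
  }
  if (!reduced) {
    cat_m <- sample(c("CNI_MMF", "CNI_MONO"), 1L)
    iv <- mk(failure, last, cat_m, "TACROLIMUS")
    return(list(intervals = iv, troughs = tr(failure, last, 5.5, 8.5)))
  }
  scenario <- sample(c("withdrawal", "cessation", "low_trough"), 1L)
  if (scenario == "withdrawal") {
    list(intervals = mk(failure, last, "WITHDRAWN", "NONE"),
         troughs = data.frame(patient_id = character(0),
                              date = as.Date(character(0)),
                              ng_per_ml = numeric(0)))
  } else if (scenario == "cessation") {
    cut <- failure + max(31, round(as.numeric(last - failure) *
                                     stats::runif(1, 0.2, 0.6)))
    after <- sample(c("MMF_MONO", "WITHDRAWN"), 1L)
    list(intervals = rbind(mk(failure, cut, "CNI_MONO", "TACROLIMUS"),
                           mk(cut + 1, last, after, "NONE")),
         troughs = tr(failure, cut, 5.5, 8.5))
  } else {
    list(intervals = mk(failure, last, "CNI_MMF", "TACROLIMUS"),
         troughs = tr(failure, last, 2.0, 4.5))
  }
}

#' Simulate post-failure immunosuppression exposure
#'
#' Each patient is reduced with probability `p_reduced`; reduced patients are
#' assigned one of three mechanisms (complete withdrawal, CNI cessation
#' mid-follow-up, or maintained CNI with average trough below 5 ng/mL) and
#' maintained patients keep a CNI regimen with troughs in the 5.5-8.5 ng/mL
#' range throughout.
#'
#' @param cfg A `sim_config`.
#' @param dates data.frame from the date sampler (`patient_id`,
#'   `failure_date`, `last_date`).
#' @return List: `timeline` and `troughs` data.frames (module file schemas),
#'   plus `reduced` (named logical vector).
#' @export
simulate_is <- function(cfg, dates) {
  set.seed(derive_seed(cfg$seed, 3L))
  reduced <- stats::runif(nrow(dates)) < cfg$p_reduced
  names(reduced) <- dates$patient_id
  parts <- lapply(seq_len(nrow(dates)), function(i) {
    sample_is_one(dates$patient_id[i], dates$failure_date[i],
                  dates$last_date[i], reduced[i])
  })
  list(timeline = do.call(rbind, lapply(parts, `[[`, "intervals")),
       troughs = do.call(rbind, lapply(parts, `[[`, "troughs")),
       reduced = reduced)
}

#' Simulate sensitization: latent dnDSA events and bead panels
#'
#' For each patient and locus group, a latent de novo DSA event occurs with
#' probability `plogis(alpha + beta_mm * mismatch_count + gamma_is *
#' reduced)`. Pairs with zero eplet mismatch in a group, or with no
#' antigen-level donor target, never seroconvert in that group regardless of
#' parameters (there is nothing to respond to). On an event, every bead whose
#' antigen key is a donor target of that group turns positive from the event
#' date onward; with `spreading`, every registry allele sharing at least one
#' eplet with a donor target allele of the group also turns positive
#' (cross-reactive repertoire broadening, which is what drives large cPRA
#' rises). Panels are drawn pre-transplant (always negative), at failure
#' (baseline) and then every six months until the end of follow-up; positive
#' beads get uniform MFI in `mfi_positive`, all others in `mfi_negative`.
#'
#' @param cfg A `sim_config`.
#' @param gen Output of [sample_genotypes()].
#' @param registry An `eplet_registry` (normally [make_registry()]).
#' @param dates Per-patient date table.
#' @param reduced Named logical vector of reduced-IS indicators.
#' @return List: `beads` (data.table `patient_id`, `sample_date`,
#'   `bead_allele`, `mfi`) and `ground_truth` (data.table per patient and
#'   group: `mm_count`, `mm_category`, `n_targets`, `reduced`, `p_dndsa`,
#'   `dndsa`, `event_date`).
#' @export
simulate_sensitization <- function(cfg, gen, registry, dates, reduced) {
  set.seed(derive_seed(cfg$seed, 4L))
  beads_all <- sim_alleles(cfg)
  eplets_of <- lapply(stats::setNames(beads_all, beads_all),
                      function(a) eplet_lookup(registry, a))
  mdl <- cfg$dndsa_model

  gt_rows <- list()
  pos_rows <- list()  # patient, bead, positive-from date
  for (i in seq_len(nrow(gen$pairs))) {
    pid <- gen$pairs$recipient_id[i]
    don <- gen$donors[[gen$pairs$donor_id[i]]]
    rec <- gen$recipients[[pid]]
    drow <- dates[dates$patient_id == pid, ]
    for (grp in names(LOCUS_GROUPS)) {
      mm <- eplet_mismatch(don, rec, grp, registry)
      targets <- donor_mismatched_antigens(don, rec, grp)
      p <- if (mm$count == 0L || length(targets) == 0L) 0 else
        stats::plogis(mdl$alpha + mdl$beta_mm * mm$count +
                        mdl$gamma_is * as.numeric(reduced[[pid]]))
      hit <- stats::runif(1) < p
      ev_date <- as.Date(NA)
      if (hit) {
        pre <- stats::runif(1) < cfg$p_event_prefailure
        ev_date <- if (pre) {
          span <- as.numeric(drow$failure_date - drow$transplant_date)
          drow$transplant_date + round(stats::runif(1, 90, span))
        } else {
          span <- as.numeric(drow$last_date - drow$failure_date)
          drow$failure_date + round(stats::runif(1, 30, span))
        }
        # Pre-failure antibodies may wane after the baseline draw; cPRA is
        # cumulative, so waning affects timing classes only.
        ev_until <- if (pre && stats::runif(1) < cfg$p_transient_prefailure) {
          drow$failure_date
        } else {
          as.Date("9999-12-31")
        }
        target_alleles <- genotype_alleles(don, grp)
        target_alleles <- target_alleles[antigen_key(target_alleles) %in% targets]
        pos <- if (cfg$spreading) {
          tg_ep <- unique(unlist(eplets_of[target_alleles]))
          beads_all[vapply(eplets_of, function(e) any(e %in% tg_ep),
                           logical(1))]
        } else {
          beads_all[antigen_key(beads_all) %in% targets]
        }
        pos_rows[[length(pos_rows) + 1L]] <-
          data.table::data.table(patient_id = pid, bead_allele = pos,
                                 pos_from = ev_date, pos_until = ev_until)
      }
      gt_rows[[length(gt_rows) + 1L]] <- data.table::data.table(
        patient_id = pid, group = grp, mm_count = mm$count,
        mm_category = mm$category, n_targets = length(targets),
        reduced = reduced[[pid]], p_dndsa = p, dndsa = hit,
        event_date = ev_date)
    }
  }
  ground_truth <- data.table::rbindlist(gt_rows)

  # Sample dates: pre-transplant, baseline at failure, then every 6 months.
  sched <- lapply(seq_len(nrow(dates)), function(i) {
    d <- dates[i, ]
    fu <- seq(d$failure_date, d$last_date, by = "6 months")
    if (utils::tail(fu, 1) != d$last_date) fu <- c(fu, d$last_date)
    data.table::data.table(patient_id = d$patient_id,
                           sample_date = c(d$transplant_date - 30, fu))
  })
  grid <- data.table::rbindlist(sched)[
    , .(bead_allele = beads_all), by = .(patient_id, sample_date)]

  pos_from <- if (length(pos_rows)) {
    data.table::rbindlist(pos_rows)[
      , .(pos_from = min(pos_from), pos_until = max(pos_until)),
      by = .(patient_id, bead_allele)]
  } else {
    data.table::data.table(patient_id = character(0),
                           bead_allele = character(0),
                           pos_from = as.Date(character(0)),
                           pos_until = as.Date(character(0)))
  }
  beads <- pos_from[grid, on = c("patient_id", "bead_allele")]
  beads[, positive := !is.na(pos_from) & sample_date >= pos_from &
          sample_date <= pos_until]
  beads[, mfi := round(ifelse(positive,
                              stats::runif(.N, cfg$mfi_positive[1],
                                           cfg$mfi_positive[2]),
                              stats::runif(.N, cfg$mfi_negative[1],
                                           cfg$mfi_negative[2])))]
  beads <- beads[, .(patient_id, sample_date, bead_allele, mfi)]
  data.table::setorder(beads, patient_id, sample_date, bead_allele)
  list(beads = beads[], ground_truth = ground_truth)
}

#' Generate a complete synthetic cohort
#'
#' Runs every generator under sub-seeds derived from `cfg$seed` and bundles
#' the results. All randomness is governed by the single configuration seed:
#' two calls with the same configuration produce identical cohorts.
#'
#' @param cfg A `sim_config`.
#' @return Object of class `synthetic_cohort`: `config`, `registry`,
#'   `genotypes` (recipients + donors), `pairs`, `donor_panel`, `dates`,
#'   `is_timeline`, `troughs`, `beads`, `ground_truth`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  registry <- make_registry(cfg)
  gen <- sample_genotypes(cfg)
  set.seed(derive_seed(cfg$seed, 5L))
  dates <- sample_dates_table(cfg, gen$pairs$recipient_id)
  is_sim <- simulate_is(cfg, dates)
  sens <- simulate_sensitization(cfg, gen, registry, dates, is_sim$reduced)
  structure(list(config = cfg, registry = registry,
                 genotypes = c(gen$recipients, gen$donors),
                 pairs = gen$pairs, donor_panel = gen$panel, dates = dates,
                 is_timeline = is_sim$timeline, troughs = is_sim$troughs,
                 beads = sens$beads, ground_truth = sens$ground_truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$pairs), " pairs, ",
      length(x$donor_panel$phenotypes), " panel donors, ",
      nrow(x$beads), " bead results (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to pipeline input files
#'
#' Emits every file the pipeline consumes, in the formats the other modules
#' define: `genotypes.tsv`, `pairs.tsv`, `registry.tsv`, `donor_panel.tsv`,
#' `beads.csv`, `is_timeline.csv`, `troughs.csv`, `patients.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             pairs = file.path(dir, "pairs.tsv"),
             registry = file.path(dir, "registry.tsv"),
             donor_panel = file.path(dir, "donor_panel.tsv"),
             beads = file.path(dir, "beads.csv"),
             is_timeline = file.path(dir, "is_timeline.csv"),
             troughs = file.path(dir, "troughs.csv"),
             patients = file.path(dir, "patients.csv"))

  gt <- data.table::rbindlist(lapply(cohort$genotypes, function(g) {
    al <- unlist(g$alleles, use.names = FALSE)
    loc <- rep(names(g$alleles), lengths(g$alleles))
    data.table::data.table(subject_id = g$subject_id, locus = loc, allele = al)
  }))
  data.table::fwrite(gt, paths["genotypes"], sep = "\t")
  data.table::fwrite(cohort$pairs, paths["pairs"], sep = "\t")

  reg <- data.table::rbindlist(lapply(names(cohort$registry$entries),
    function(a) data.table::data.table(allele = a,
                                       eplet = cohort$registry$entries[[a]])))
  data.table::fwrite(reg, paths["registry"], sep = "\t")

  dp <- data.table::data.table(
    donor_id = names(cohort$donor_panel$phenotypes),
    antigens = vapply(cohort$donor_panel$phenotypes, paste,
                      character(1), collapse = ";"))
  data.table::fwrite(dp, paths["donor_panel"], sep = "\t")

  data.table::fwrite(cohort$beads, paths["beads"])
  data.table::fwrite(cohort$is_timeline, paths["is_timeline"])
  data.table::fwrite(cohort$troughs, paths["troughs"])
  data.table::fwrite(cohort$dates, paths["patients"])
  invisible(paths)
}
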