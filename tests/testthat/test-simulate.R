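test_that("sim_config validates its stated world", {
  cfg <- sim_config(seed = 3)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_patients, 21L)
  bad <- default_allele_freqs()
  bad$A$freq[1] <- bad$A$freq[1] + 0.1
  expect_error(sim_config(allele_freqs = bad), "sum to")
  expect_error(sim_config(shared_eplet_fraction = 1.5), "shared_eplet_fraction")
})

test_that("make_registry shares eplets within first-field classes", {
  cfg1 <- sim_config(seed = 5, shared_eplet_fraction = 1)
  r1 <- make_registry(cfg1)
  expect_setequal(eplet_lookup(r1, "DQB1*03:01"),
                  eplet_lookup(r1, "DQB1*03:02"))

  cfg0 <- sim_config(seed = 5, shared_eplet_fraction = 0)
  r0 <- make_registry(cfg0)
  expect_length(intersect(eplet_lookup(r0, "DQB1*03:01"),
                          eplet_lookup(r0, "DQB1*03:02")), 0)

  # same class => same total eplet count; determinism under the seed
  expect_equal(length(eplet_lookup(r0, "C*07:01")),
               length(eplet_lookup(r0, "C*07:02")))
  expect_identical(make_registry(cfg1)$entries, r1$entries)
})

test_that("sample_genotypes respects frequencies and degenerate cases", {
  # single allele at freq 1 -> every subject homozygous for it
  freqs <- default_allele_freqs()
  freqs$DQB1 <- data.frame(allele = "DQB1*03:01", freq = 1)
  gen <- sample_genotypes(sim_config(seed = 2, n_patients = 10,
                                     n_panel_donors = 5,
                                     allele_freqs = freqs))
  for (g in gen$recipients) {
    expect_equal(genotype_alleles(g, "DQ")[allele_locus(
      genotype_alleles(g, "DQ")) == "DQB1"], "DQB1*03:01")
  }
  expect_identical(
    sample_genotypes(sim_config(seed = 2))$pairs,
    sample_genotypes(sim_config(seed = 2))$pairs)

  # allele frequencies recovered within 3 binomial SEs at large n
  gen2 <- sample_genotypes(sim_config(seed = 8, n_patients = 1000,
                                      n_panel_donors = 1))
  draws <- unlist(lapply(c(gen2$recipients, gen2$donors), function(g) {
    a <- g$alleles$DQB1
    if (length(a) == 1L) rep(a, 2) else a  # homozygote = two draws
  }))
  n <- length(draws)
  for (i in seq_len(nrow(default_allele_freqs()$DQB1))) {
    al <- default_allele_freqs()$DQB1$allele[i]
    p <- default_allele_freqs()$DQB1$freq[i]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(draws == al) - p), 3 * se + 1e-9)
  }
})

test_that("null and saturated dnDSA models behave as limits", {
  null_cfg <- sim_config(seed = 4, n_patients = 15,
                         dndsa_model = list(alpha = -50, beta_mm = 0,
                                            gamma_is = 0))
  co <- simulate_cohort(null_cfg)
  expect_false(any(co$ground_truth$dndsa))
  expect_true(all(co$beads$mfi <= co$config$mfi_negative[2]))  # flat panels

  sat_cfg <- sim_config(seed = 4, n_patients = 15,
                        dndsa_model = list(alpha = 50, beta_mm = 0,
                                           gamma_is = 0))
  gt <- simulate_cohort(sat_cfg)$ground_truth
  eligible <- gt$mm_count > 0 & gt$n_targets > 0
  expect_true(all(gt$dndsa[eligible]))
  expect_false(any(gt$dndsa[!eligible]))
})

test_that("simulate_cohort is deterministic under a fixed seed", {
  c1 <- simulate_cohort(sim_config(seed = 12, n_patients = 8,
                                   n_panel_donors = 30))
  c2 <- simulate_cohort(sim_config(seed = 12, n_patients = 8,
                                   n_panel_donors = 30))
  expect_identical(c1$beads, c2$beads)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(c1$is_timeline, c2$is_timeline)
  c3 <- simulate_cohort(sim_config(seed = 13, n_patients = 8,
                                   n_panel_donors = 30))
  expect_false(identical(c1$beads, c3$beads))
})

test_that("ground truth is consistent with the generated panels", {
  co <- simulate_cohort(sim_config(seed = 21, n_patients = 12,
                                   n_panel_donors = 40))
  gt <- co$ground_truth
  beads <- co$beads
  thr <- 1000
  for (i in seq_len(nrow(gt))) {
    pid <- gt$patient_id[i]
    pb <- beads[beads$patient_id == pid, ]
    pre_tx <- pb[pb$sample_date <= co$dates$transplant_date[
      co$dates$patient_id == pid], ]
    expect_true(all(pre_tx$mfi < thr))  # pre-transplant panels clean
    if (gt$dndsa[i]) {
      # some bead is positive on/after the event date
      after <- pb[pb$sample_date >= gt$event_date[i], ]
      expect_true(any(after$mfi > thr))
    }
  }
  # mismatch counts recorded in ground truth match a direct recomputation
  idx <- gt$group == "DQ"
  for (j in which(idx)[1:4]) {
    pid <- gt$patient_id[j]
    did <- co$pairs$donor_id[co$pairs$recipient_id == pid]
    m <- eplet_mismatch(co$genotypes[[did]], co$genotypes[[pid]], "DQ",
                        co$registry)
    expect_equal(m$count, gt$mm_count[j])
  }
})

test_that("write_cohort emits a readable, faithful file set", {
  co <- simulate_cohort(sim_config(seed = 6, n_patients = 6,
                                   n_panel_donors = 20))
  dir <- file.path(tempdir(), "sim-out")
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  inputs <- read_pipeline_inputs(dir)
  expect_length(inputs$genotypes, 12L)  # recipients + donors
  expect_equal(length(inputs$donor_panel$phenotypes), 20L)
  expect_equal(nrow(inputs$beads), nrow(co$beads))
  expect_identical(inputs$registry$entries[order(names(inputs$registry$entries))],
                   co$registry$entries[order(names(co$registry$entries))])
})
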