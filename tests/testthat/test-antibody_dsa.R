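test_that("unacceptable_antigens uses a strict threshold and antigen keys", {
  b <- data.frame(bead_allele = c("A*02:01", "B*07:02", "B*07:55", "C*04:01"),
                  mfi = c(1000, 1001, 5000, 999))
  expect_equal(unacceptable_antigens(b), "B*07")  # 1000 excluded, key collapse
  expect_equal(unacceptable_antigens(b[0, ]), character(0))
  expect_equal(unacceptable_antigens(data.frame(bead_allele = "A*01:01",
                                                mfi = 500)), character(0))
})

test_that("unacceptable_antigens is monotone in the threshold", {
  set.seed(5)
  b <- data.frame(bead_allele = sample(c("A*01:01", "A*02:01", "B*07:02",
                                         "DQB1*03:01"), 40, replace = TRUE),
                  mfi = runif(40, 0, 4000))
  thresholds <- sort(runif(8, 0, 4000))
  sets <- lapply(thresholds, function(th) unacceptable_antigens(b, th))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("donor_mismatched_antigens finds antigen-level targets", {
  d <- genotype("D", list(DQB1 = "DQB1*03:01"))
  r <- genotype("R", list(DQB1 = c("DQB1*05:01", "DQB1*06:02")))
  expect_equal(donor_mismatched_antigens(d, r, "DQ"), "DQB1*03")
  expect_equal(donor_mismatched_antigens(d, d, "DQ"), character(0))
  # same first-field class is an antigen-level match even if alleles differ
  r2 <- genotype("R2", list(DQB1 = "DQB1*03:02"))
  expect_equal(donor_mismatched_antigens(d, r2, "DQ"), character(0))
  # homozygous mismatch yields one key, not two
  dh <- genotype("DH", list(A = c("A*02:01", "A*02:01")))
  rh <- genotype("RH", list(A = "A*01:01"))
  expect_equal(donor_mismatched_antigens(dh, rh, "CLASS_I"), "A*02")
})

test_that("detect_dndsa classifies timing windows", {
  beads <- c("DQB1*03:01", "DQB1*03:02", "A*02:01", "DRB1*15:01")
  tx <- as.Date("2005-01-01"); fail <- as.Date("2012-01-01")

  # positive only at baseline (within failure + 31d) then waned -> PRE_FAILURE
  p <- make_panel(c("2004-12-01", "2012-01-15", "2014-01-01"),
                  list(character(0), "DQB1*03:01", character(0)), beads)
  ev <- detect_dndsa(p, c("DQB1*03", "A*02"), tx, fail)
  expect_equal(ev$target, "DQB1*03")
  expect_equal(ev$timing, "PRE_FAILURE")
  expect_equal(ev$locus_group, "DQ")
  expect_equal(ev$first_detected, as.Date("2012-01-15"))

  # positive only after the window -> POST_FAILURE
  p <- make_panel(c("2004-12-01", "2013-06-01"),
                  list(character(0), "A*02:01"), beads)
  ev <- detect_dndsa(p, c("DQB1*03", "A*02"), tx, fail)
  expect_equal(ev$timing, "POST_FAILURE")

  # positive in both windows -> BOTH
  p <- make_panel(c("2004-12-01", "2012-01-10", "2014-01-01"),
                  list(character(0), "DQB1*03:02", "DQB1*03:01"), beads)
  ev <- detect_dndsa(p, "DQB1*03", tx, fail)
  expect_equal(ev$timing, "BOTH")
})

test_that("detect_dndsa enforces de novo semantics and target specificity", {
  beads <- c("DQB1*03:01", "A*02:01")
  tx <- as.Date("2005-01-01"); fail <- as.Date("2012-01-01")
  # preformed (positive pre-transplant) is never de novo
  p <- make_panel(c("2004-12-01", "2013-01-01"),
                  list("DQB1*03:01", "DQB1*03:01"), beads)
  expect_equal(nrow(detect_dndsa(p, "DQB1*03", tx, fail)), 0L)

  # zero-target pair yields nothing even with positive beads
  p <- make_panel(c("2004-12-01", "2013-01-01"),
                  list(character(0), "A*02:01"), beads)
  expect_equal(nrow(detect_dndsa(p, character(0), tx, fail)), 0L)

  # non-target reactivity never produces an event
  ev <- detect_dndsa(p, "DQB1*03", tx, fail)
  expect_equal(nrow(ev), 0L)

  # missing pre-transplant baseline warns (assume naive) or errors in strict
  p2 <- make_panel("2013-01-01", list("DQB1*03:01"), beads)
  expect_warning(ev2 <- detect_dndsa(p2, "DQB1*03", tx, fail), "baseline")
  expect_equal(ev2$timing, "POST_FAILURE")
  expect_error(suppressWarnings(
    detect_dndsa(p2, "DQB1*03", tx, fail, strict = TRUE)), "baseline")

  # self-reactive beads are dropped with a warning
  p3 <- make_panel(c("2004-12-01", "2013-01-01"),
                   list(character(0), c("DQB1*03:01", "A*02:01")), beads)
  expect_warning(
    ev3 <- detect_dndsa(p3, c("DQB1*03", "A*02"), tx, fail,
                        recipient_keys = "A*02"),
    "self-reactive")
  expect_equal(ev3$target, "DQB1*03")
})

test_that("every event target is a donor-mismatched antigen (property)", {
  set.seed(17)
  beads <- c("DQB1*03:01", "DQB1*05:01", "DRB1*15:01", "A*02:01", "B*07:02")
  tx <- as.Date("2005-01-01"); fail <- as.Date("2012-01-01")
  for (i in 1:20) {
    targets <- sample(c("DQB1*03", "DRB1*15", "A*02"), sample(0:3, 1))
    pos <- lapply(1:3, function(j) sample(beads, sample(0:4, 1)))
    pos[[1]] <- character(0)  # clean pre-transplant baseline
    p <- make_panel(c("2004-12-01", "2012-01-15", "2014-01-01"), pos, beads)
    ev <- detect_dndsa(p, targets, tx, fail)
    expect_true(all(ev$target %in% targets))
    expect_true(all(ev$timing %in% c("PRE_FAILURE", "POST_FAILURE", "BOTH")))
    expect_false(any(duplicated(ev$target)))
  }
})
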