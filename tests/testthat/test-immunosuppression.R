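iv <- function(start, end, category, drug = "TACROLIMUS", pid = "P1") {
  data.frame(patient_id = pid, start = as.Date(start), end = as.Date(end),
             category = category,
             cni_drug = ifelse(category %in% c("MMF_MONO", "WITHDRAWN"),
                               "NONE", drug),
             stringsAsFactors = FALSE)
}
tv <- function(dates, levels, pid = "P1") {
  data.frame(patient_id = pid, date = as.Date(dates), ng_per_ml = levels,
             stringsAsFactors = FALSE)
}

test_that("average_trough averages CNI-interval measurements", {
  intervals <- iv("2015-01-01", "2016-01-01", "CNI_MMF")
  expect_equal(average_trough(intervals, tv(c("2015-03-01", "2015-09-01"),
                                            c(4, 6))), 5)
  expect_equal(average_trough(intervals, tv("2015-03-01", 7.2)), 7.2)
  expect_true(is.na(average_trough(iv("2015-01-01", "2016-01-01",
                                      "MMF_MONO"), tv("2015-03-01", 7))))
  # CNI interval without measurements warns and is excluded
  expect_warning(out <- average_trough(intervals, tv("2020-01-01", 9)),
                 "no trough")
  expect_true(is.na(out))
  # measurements outside the CNI interval are ignored
  two <- rbind(iv("2015-01-01", "2015-06-30", "CNI_MONO"),
               iv("2015-07-01", "2016-01-01", "MMF_MONO"))
  expect_equal(average_trough(two, tv(c("2015-02-01", "2015-10-01"),
                                      c(6, 2))), 6)
})

test_that("time-weighted averaging weights by interval length", {
  two <- rbind(iv("2015-01-01", "2015-01-31", "CNI_MONO"),   # 30 days
               iv("2015-02-01", "2015-05-01", "CNI_MMF"))    # 89 days
  tr <- tv(c("2015-01-15", "2015-03-01"), c(10, 4))
  expect_equal(average_trough(two, tr), 7)
  expect_equal(average_trough(two, tr, time_weighted = TRUE),
               (10 * 30 + 4 * 89) / 119)
})

test_that("classify_reduced implements the three reduction criteria", {
  tl <- iv("2015-01-01", "2017-01-01", "CNI_MONO")
  # maintained: continuous tacrolimus with average trough exactly 5.0
  expect_false(classify_reduced(tl, tv(c("2015-06-01", "2016-06-01"),
                                       c(4.5, 5.5))))
  # reduced: average trough below the cutoff
  expect_true(classify_reduced(iv("2015-01-01", "2017-01-01", "CNI_MMF"),
                               tv("2015-06-01", 4.2)))
  # reduced: complete withdrawal
  expect_true(classify_reduced(iv("2015-01-01", "2015-02-01", "WITHDRAWN"),
                               tv(character(0), numeric(0))))
  # reduced: CNI cessation (CNI followed by MMF monotherapy)
  ces <- rbind(iv("2015-01-01", "2015-12-31", "CNI_MMF"),
               iv("2016-01-01", "2017-01-01", "MMF_MONO"))
  expect_true(classify_reduced(ces, tv("2015-06-01", 8)))
  # maintained: MMF before CNI is not cessation
  esc <- rbind(iv("2015-01-01", "2015-12-31", "MMF_MONO"),
               iv("2016-01-01", "2017-01-01", "CNI_MMF"))
  expect_false(classify_reduced(esc, tv("2016-06-01", 6)))
  expect_error(classify_reduced(tl[0, ], tv("2015-06-01", 6)), "empty")
})

test_that("classify_reduced is monotone in the trough cutoff", {
  tl <- iv("2015-01-01", "2017-01-01", "CNI_MMF")
  tr <- tv(c("2015-06-01", "2016-06-01"), c(5, 7))  # average 6
  cuts <- c(2, 4, 6, 6.01, 8)
  red <- vapply(cuts, function(ct) classify_reduced(tl, tr, ct), logical(1))
  expect_equal(red, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(diff(as.integer(red)) >= 0))
})

test_that("timeline readers validate structure", {
  p <- tempfile(fileext = ".csv")
  data.table::fwrite(rbind(iv("2015-01-01", "2015-06-01", "CNI_MMF"),
                           iv("2015-05-01", "2016-01-01", "MMF_MONO")), p)
  expect_error(read_is_timeline(p), "overlapping")

  bad_drug <- iv("2015-01-01", "2015-06-01", "WITHDRAWN")
  bad_drug$cni_drug <- "TACROLIMUS"
  data.table::fwrite(bad_drug, p)
  expect_error(read_is_timeline(p), "NONE")

  ok <- rbind(iv("2015-01-01", "2015-06-01", "CNI_MONO", "CYCLOSPORIN"),
              iv("2015-06-02", "2016-01-01", "WITHDRAWN"))
  data.table::fwrite(ok, p)
  tl <- read_is_timeline(p)
  expect_equal(nrow(tl), 2L)

  tp <- tempfile(fileext = ".csv")
  data.table::fwrite(tv("2015-02-01", 6.1), tp)
  tr <- read_troughs(tp)
  expect_equal(tr$ng_per_ml, 6.1)
  out <- is_exposure_table(tl, tr)
  expect_true(out$reduced)  # withdrawal wins regardless of troughs
})
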