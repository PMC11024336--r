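test_that("load_eplet_registry unions rows and validates the file", {
  p <- tempfile(fileext = ".tsv")
  data.table::fwrite(data.frame(
    allele = c("DQB1*03:01", "DQB1*03:01", "DQB1*03:01"),
    eplet = c("eA", "eB", "eA")), p, sep = "\t")  # duplicate row
  r <- load_eplet_registry(p, version = "v1")
  expect_setequal(eplet_lookup(r, "DQB1*03:01"), c("eA", "eB"))
  expect_equal(r$version, "v1")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("foo\tbar", "x\ty"), bad)
  expect_error(load_eplet_registry(bad), "missing column")
  empty <- tempfile(fileext = ".tsv")
  writeLines("allele\teplet", empty)
  expect_error(load_eplet_registry(empty), "empty")
})

test_that("eplet_lookup falls back to two-field truncation then errors", {
  r <- toy_registry()
  expect_setequal(eplet_lookup(r, "DQB1*03:01:02"),
                  eplet_lookup(r, "DQB1*03:01"))
  expect_error(eplet_lookup(r, "DQB1*99:99"), "not found")
  expect_warning(out <- eplet_lookup(r, "DQB1*99:99", on_missing = "skip"),
                 "skipping")
  expect_null(out)
})

test_that("subject_eplets unions over the locus group", {
  r <- toy_registry()
  hom <- genotype("H", list(DQB1 = "DQB1*03:01"))
  expect_setequal(subject_eplets(hom, "DQ", r), c("e1", "e2", "e3", "e4", "e5"))

  two <- genotype("T", list(DQA1 = "DQA1*01:01", DQB1 = "DQB1*05:01"))
  expect_setequal(subject_eplets(two, "DQ", r),
                  c("qa1", "qa2", "e4", "e5", "qshared"))
  # absent DRB3/4/5 contribute nothing
  dr <- genotype("D", list(DRB1 = "DRB1*03:01"))
  expect_setequal(subject_eplets(dr, "DR", r), c("r1", "r2"))
})

test_that("eplet_mismatch matches worked examples", {
  r <- toy_registry()
  d <- genotype("D", list(DQA1 = "DQA1*01:01", DQB1 = "DQB1*03:01"))
  same <- genotype("R0", list(DQA1 = "DQA1*01:01", DQB1 = "DQB1*03:01"))
  expect_equal(eplet_mismatch(d, same, "DQ", r)$count, 0L)

  # donor eplets {e1..e5}, recipient covers {e4,e5} -> {e1,e2,e3}
  d2 <- genotype("D2", list(DQB1 = "DQB1*03:01"))
  r2 <- genotype("R2", list(DQB1 = "DQB1*05:01"))
  m <- eplet_mismatch(d2, r2, "DQ", r)
  expect_setequal(m$mismatched_eplets, c("e1", "e2", "e3"))
  expect_equal(m$count, 3L)
  expect_equal(m$category, "LOW")
})

test_that("categorize_mismatch applies the 0-11 / 12+ rule", {
  expect_equal(categorize_mismatch(c(0, 11, 12, 30)),
               c("LOW", "LOW", "HIGH", "HIGH"))
  expect_equal(categorize_mismatch(5, threshold = 5), "HIGH")
  expect_error(categorize_mismatch(-1), "non-negative")
})

test_that("mismatch equals the brute-force oracle on random worlds", {
  set.seed(42)
  for (i in 1:25) {
    w <- random_world()
    d <- w$draw_genotype("D")
    r <- w$draw_genotype("R")
    for (grp in names(LOCUS_GROUPS)) {
      m <- eplet_mismatch(d, r, grp, w$registry)
      expect_identical(m$count, oracle_mismatch_count(d, r, grp, w$registry))
      expect_lte(m$count, length(subject_eplets(d, grp, w$registry)))
      # self-mismatch is always zero
      expect_identical(eplet_mismatch(d, d, grp, w$registry)$count, 0L)
    }
  }
})

test_that("adding a recipient eplet never increases any mismatch count", {
  set.seed(99)
  for (i in 1:10) {
    w <- random_world()
    d <- w$draw_genotype("D")
    r <- w$draw_genotype("R")
    grp <- sample(names(LOCUS_GROUPS), 1)
    before <- eplet_mismatch(d, r, grp, w$registry)$count
    # graft one donor eplet onto a recipient allele of the group
    r_all <- genotype_alleles(r, grp)
    d_ep <- subject_eplets(d, grp, w$registry)
    if (!length(r_all) || !length(d_ep)) next
    reg2 <- w$registry
    tgt <- r_all[1]
    reg2$entries[[tgt]] <- unique(c(reg2$entries[[tgt]], sample(d_ep, 1)))
    after <- eplet_mismatch(d, r, grp, reg2)$count
    expect_lte(after, before)
  }
})

test_that("mismatch_table emits per-pair per-group rows", {
  r <- toy_registry()
  genos <- list(
    D1 = genotype("D1", list(DQB1 = "DQB1*03:01", DRB1 = "DRB1*03:01")),
    R1 = genotype("R1", list(DQB1 = "DQB1*05:01", DRB1 = "DRB1*15:01")))
  pairs <- data.frame(pair_id = "P1", donor_id = "D1", recipient_id = "R1")
  tab <- mismatch_table(pairs, genos, r, groups = c("DQ", "DR"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$count[tab$group == "DQ"], 3L)
  expect_equal(tab$count[tab$group == "DR"], 1L)
  expect_true(all(tab$registry_version == "toy"))
  expect_error(mismatch_table(data.frame(pair_id = "P", donor_id = "nope",
                                         recipient_id = "R1"), genos, r),
               "missing genotype")
})
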