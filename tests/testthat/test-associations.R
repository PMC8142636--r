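test_that("reading the bundled exposure file parses every field", {
  ex <- fixture_exposure()
  expect_s3_class(ex, "mr_associations")
  expect_equal(nrow(ex), 11L)
  row <- ex[ex$snp == "rs33972313", ]
  expect_equal(row$beta, 0.36)
  expect_equal(row$se, 0.018)
  expect_equal(row$eaf, 0.968)
  expect_identical(row$ea, "C")
  expect_identical(row$nea, "T")
  expect_equal(row$n, 52018)
  expect_identical(attr(ex, "label"), "vitc_exposure")
})

test_that("column dialects remap headers and alleles are upper-cased", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tA1\tA2\tfreq\tb\tstderr\tp",
               "rs1\ta\tg\t0.4\t0.1\t0.02\t1e-10"), path)
  got <- read_associations(path, dialect = c(snp = "rsid", ea = "A1",
                                             nea = "A2", eaf = "freq",
                                             beta = "b", se = "stderr",
                                             pval = "p"))
  expect_identical(got$ea, "A")
  expect_identical(got$nea, "G")
  expect_equal(got$beta, 0.1)
})

test_that("a header-only file yields an empty association list", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("snp\tea\tnea\teaf\tbeta\tse\tpval", path)
  got <- read_associations(path)
  expect_equal(nrow(got), 0L)
  expect_s3_class(got, "mr_associations")
})

test_that("invalid rows are reported by snp id, not silently dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tea\tnea\teaf\tbeta\tse\tpval",
               "rs_ok\tA\tG\t0.4\t0.1\t0.02\t1e-10",
               "rs_bad\tX\tG\t0.4\t0.1\t0.02\t1e-10"), path)
  expect_error(read_associations(path), "rs_bad")
  expect_error(toy_assoc("rs_se", "A", "G", 0.5, 0.1, se = 0), "rs_se")
  expect_error(toy_assoc("rs_eaf", "A", "G", 1.5, 0.1), "rs_eaf")
  expect_error(toy_assoc("rs_same", "A", "A", 0.5, 0.1), "rs_same")
})

test_that("missing mandatory columns are named in the error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tea\tnea\teaf\tbeta\tpval", "rs1\tA\tG\t0.4\t0.1\t1e-10"),
             path)
  expect_error(read_associations(path), "se")
})

test_that("instrument selection filters on the p-value threshold only", {
  ex <- fixture_exposure()
  expect_equal(nrow(select_instruments(ex, 5e-8)), 11L)
  expect_equal(nrow(select_instruments(ex, 1e-300)), 0L)
  expect_identical(select_instruments(ex, 1), ex)
  # order preserved, no reweighting
  kept <- select_instruments(ex, 1e-10)
  expect_identical(kept$snp, ex$snp[ex$pval < 1e-10])
  expect_error(select_instruments(ex, 0), "p_threshold")
})

test_that("associations survive a write/read round trip", {
  ex <- fixture_exposure()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_associations(ex, path)
  back <- read_associations(path)
  expect_equal(as.data.frame(back), as.data.frame(ex),
               ignore_attr = TRUE)
})
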