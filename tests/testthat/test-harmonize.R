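test_that("the bundled tables harmonize with nothing flipped or dropped", {
  h <- fixture_harmonized("pd_aao")
  expect_equal(nrow(h), 11L)
  expect_false(any(h$flipped))
  expect_equal(nrow(dropped_variants(h)), 0L)
  expect_true(all(h$beta_exp > 0))
  pal <- h[h$snp == "rs56738967", ]
  expect_true(pal$palindromic)
  expect_false(pal$flipped)
  expect_false(any(h$palindromic[h$snp != "rs56738967"]))
})

test_that("a swapped outcome record is sign- and frequency-flipped", {
  ex <- toy_assoc("rs1", "A", "G", eaf = 0.3, beta = 0.1)
  out <- toy_assoc("rs1", "G", "A", eaf = 0.7, beta = 0.2)
  h <- harmonize(ex, out)
  expect_true(h$flipped)
  expect_equal(h$beta_out, -0.2)
  expect_equal(h$eaf_out, 0.3)
})

test_that("strand-complement outcome alleles are matched before mismatch", {
  ex <- toy_assoc("rs1", "A", "G", eaf = 0.3, beta = 0.1)
  direct <- harmonize(ex, toy_assoc("rs1", "T", "C", eaf = 0.31, beta = 0.2))
  expect_false(direct$flipped)
  expect_equal(direct$beta_out, 0.2)
  swapped <- harmonize(ex, toy_assoc("rs1", "C", "T", eaf = 0.69, beta = 0.2))
  expect_true(swapped$flipped)
  expect_equal(swapped$beta_out, -0.2)
  expect_equal(swapped$eaf_out, 0.31)
})

test_that("palindromes are resolved by frequency or dropped when ambiguous", {
  ex <- toy_assoc(c("rs_clear", "rs_mid", "rs_flip"), "C", "G",
                  eaf = c(0.321, 0.50, 0.2), beta = 0.1)
  out <- toy_assoc(c("rs_clear", "rs_mid", "rs_flip"), "C", "G",
                   eaf = c(0.32, 0.5, 0.8), beta = c(0.2, 0.2, 0.2))
  h <- harmonize(ex, out)
  expect_identical(h$snp, c("rs_clear", "rs_flip"))
  expect_false(h$flipped[h$snp == "rs_clear"])
  # outcome frequency 0.8 matches the complement of exposure eaf 0.2
  expect_true(h$flipped[h$snp == "rs_flip"])
  expect_equal(h$beta_out[h$snp == "rs_flip"], -0.2)
  dropped <- dropped_variants(h)
  expect_identical(dropped$reason[dropped$snp == "rs_mid"],
                   "ambiguous palindrome")
  # window widens the ambiguity zone: eaf 0.321 is no longer resolvable
  h2 <- harmonize(ex, out, palindrome_eaf_window = 0.2)
  d2 <- dropped_variants(h2)
  expect_identical(d2$reason[d2$snp == "rs_clear"], "ambiguous palindrome")
  expect_identical(h2$snp, "rs_flip")
})

test_that("non-complementary allele mismatches are dropped with reason", {
  # A/G vs A/C shares one allele but is not resolvable on either strand
  ex <- toy_assoc(c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                  eaf = 0.3, beta = 0.1)
  out <- toy_assoc(c("rs1", "rs2"), c("A", "A"), c("C", "G"),
                   eaf = 0.3, beta = 0.2)
  h <- harmonize(ex, out)
  expect_identical(h$snp, "rs2")
  d <- dropped_variants(h)
  expect_identical(d$reason[d$snp == "rs1"], "allele mismatch")
})

test_that("variants on only one side are dropped with a reason", {
  ex <- toy_assoc(c("rs1", "rs2"), "A", "G", eaf = 0.3, beta = 0.1)
  out <- toy_assoc(c("rs2", "rs3"), "A", "G", eaf = 0.3, beta = 0.2)
  h <- harmonize(ex, out)
  expect_identical(h$snp, "rs2")
  d <- dropped_variants(h)
  expect_identical(d$reason[d$snp == "rs1"], "missing in outcome")
  expect_identical(d$reason[d$snp == "rs3"], "missing in exposure")
})

test_that("exposure records are oriented to the raising allele", {
  ex <- toy_assoc("rs1", "A", "G", eaf = 0.3, beta = -0.1)
  out <- toy_assoc("rs1", "A", "G", eaf = 0.3, beta = 0.2)
  h <- harmonize(ex, out)
  expect_equal(h$beta_exp, 0.1)
  expect_identical(h$ea, "G")
  expect_equal(h$eaf_exp, 0.7)
  # the outcome now matches the swapped orientation
  expect_true(h$flipped)
  expect_equal(h$beta_out, -0.2)
})

test_that("allele swapping is an involution", {
  set.seed(42)
  for (i in 1:20) {
    rec <- data.frame(ea = sample(c("A", "C", "G", "T"), 1),
                      nea = sample(c("A", "C", "G", "T"), 1),
                      beta = rnorm(1), eaf = runif(1))
    if (rec$ea == rec$nea) next
    expect_identical(swap_alleles(swap_alleles(rec)), rec)
  }
})

test_that("harmonization conserves shared variants and orients every pair", {
  set.seed(7)
  for (i in 1:10) {
    k <- 12
    ea <- c("A", "T", "G", "C")[sample.int(4, k, replace = TRUE)]
    nea <- ifelse(ea %in% c("A", "T"), "G", "T")
    ex <- toy_assoc(sprintf("rs%d", 1:k), ea, nea, eaf = runif(k, 0.05, 0.95),
                    beta = rnorm(k, 0, 0.1))
    flip <- runif(k) < 0.5
    out <- ex
    out[flip, ] <- swap_alleles(out[flip, ])
    out$beta <- rnorm(k, 0, 0.1)
    h <- harmonize(ex, out)
    expect_true(all(h$beta_exp > 0))
    expect_equal(nrow(h) + nrow(dropped_variants(h)), k)
  }
})
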