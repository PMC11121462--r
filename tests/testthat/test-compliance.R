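test_that("per-parameter checks fire at the documented limits", {
  # sucrose excess together with a low sugar sum
  r <- check_sample(make_final(final_type = "polyfloral", suc = 16.34,
                               glu = 20, fru = 29.5))
  expect_setequal(r$codes, c("HIGH_SUCROSE", "LOW_SUGAR_SUM"))
  expect_equal(r$sugar_sum, 49.5)

  # honeydew with only excess moisture
  r <- check_sample(make_final(declared_type = "honeydew",
                               final_type = "honeydew", mc = 26,
                               econd = 1.1))
  expect_equal(r$codes, "HIGH_MOISTURE")

  # acacia enjoys the 10 g/100 g sucrose ceiling
  expect_equal(check_sample(make_final(final_type = "acacia", suc = 8))$codes,
               character(0))
  expect_equal(check_sample(make_final(final_type = "linden", suc = 8))$codes,
               "HIGH_SUCROSE")

  # honeydew sugar floor is 45, blossom 60
  expect_equal(check_sample(make_final(final_type = "honeydew", glu = 22,
                                       fru = 24, econd = 1.0))$codes,
               character(0))
  expect_equal(check_sample(make_final(final_type = "linden", glu = 22,
                                       fru = 24))$codes, "LOW_SUGAR_SUM")

  # boundary-equal values are compliant (strict inequalities)
  r <- check_sample(make_final(final_type = "polyfloral", hmf = 40, acid = 50,
                               dia = 8, mc = 20, ins = 0.1, suc = 5,
                               glu = 30, fru = 30, econd = 0.1))
  expect_equal(r$codes, character(0))

  # pressed-honey variant relaxes insoluble matter
  expect_equal(check_sample(make_final(ins = 0.3))$codes, "HIGH_INSOLUBLE")
  expect_equal(check_sample(make_final(ins = 0.3), pressed = TRUE)$codes,
               character(0))
})

test_that("blend flag needs a flower type, a mid sugar sum and the econd band", {
  expect_true(flag_blend(make_final(final_type = "linden", glu = 26,
                                    fru = 29.8, econd = 0.76)))
  expect_false(flag_blend(make_final(final_type = "polyfloral", glu = 26,
                                     fru = 29, econd = 0.30)))
  expect_false(flag_blend(make_final(declared_type = "honeydew",
                                     final_type = "honeydew", glu = 26,
                                     fru = 29, econd = 0.9)))
  expect_false(flag_blend(make_final(final_type = "linden", glu = 20,
                                     fru = 24, econd = 0.76)))  # below 45
  expect_false(flag_blend(make_final(final_type = "linden", glu = 31,
                                     fru = 39, econd = 0.76)))  # sum fine
})

test_that("grading partitions samples with adulteration codes dominating", {
  expect_equal(grade_verdict(list(codes = "HIGH_HMF"))$grade, "ADULTERATED")
  expect_equal(grade_verdict(list(codes = "LOW_SUGAR_SUM"))$grade, "SUSPECT")
  expect_equal(grade_verdict(list(codes = character(0)))$grade, "COMPLIANT")
  expect_equal(grade_verdict(list(codes = c("HIGH_SUCROSE",
                                            "LOW_SUGAR_SUM")))$grade,
               "ADULTERATED")

  # monotonicity: adding a code never moves a sample toward COMPLIANT
  rank <- c(COMPLIANT = 0, SUSPECT = 1, ADULTERATED = 2)
  all_codes <- c(adulteration_codes(), suspect_codes())
  set.seed(42)
  for (i in 1:50) {
    codes <- sample(all_codes, sample(0:4, 1))
    extra <- sample(setdiff(all_codes, codes), 1)
    g1 <- grade_verdict(list(codes = codes))$grade
    g2 <- grade_verdict(list(codes = c(codes, extra)))$grade
    expect_gte(rank[[g2]], rank[[g1]])
  }
})

test_that("summaries partition any table and react to policy changes", {
  tab <- reclassify_table(random_table(300, 5))$table
  cs <- summarize_compliance(tab)
  expect_equal(sum(cs$grade_counts), 300)
  expect_equal(cs$nonconforming,
               cs$grade_counts[["ADULTERATED"]] + cs$grade_counts[["SUSPECT"]])

  # raising the HMF ceiling above the table maximum clears HIGH_HMF
  relaxed <- load_policy(list(hmf_max = max(tab$hmf) + 1))
  cs2 <- summarize_compliance(tab, relaxed)
  expect_equal(cs2$code_counts[["HIGH_HMF"]], 0)
  # brute-force rescan agrees
  expect_equal(cs$code_counts[["HIGH_HMF"]], sum(tab$hmf > 40))

  expect_error(summarize_compliance(tab[0, ]), "empty")

  all_ok <- reclassify_table(make_samples(10,
                                          sample_id = sprintf("C%02d", 1:10)))$table
  cs3 <- summarize_compliance(all_ok)
  expect_equal(unname(cs3$grade_counts), c(0, 0, 10))
  expect_equal(cs3$nonconforming_pct, 0)
})
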