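test_that("simple RE arithmetic, bounds and no-data outcomes", {
  expect_equal(re_simple(100, 25), 75)
  expect_equal(re_simple(100, 100), 0)
  expect_equal(re_simple(100, 150), -50)
  expect_true(is.na(re_simple(0, 10)))
  expect_true(is.na(re_simple(NA, 10)))
  # strictly decreasing in the effluent, bounded above by 100
  effl <- seq(0, 300, by = 10)
  re <- re_simple(120, effl)
  expect_true(all(diff(re) < 0))
  expect_true(all(re <= 100))
})

test_that("mass-balance RE matches hand arithmetic and reduces to the simple form", {
  expect_equal(re_mass_balance(100, 20, 0, 1000, 500), 80)
  expect_equal(re_mass_balance(100, 20, 10, 1000, 1000), 70) # (1e5-2e4-1e4)/1e5
  expect_equal(re_mass_balance(100, 100, 10, 1000, 1000), -10)
  expect_true(is.na(re_mass_balance(100, 20, NA, 1000, 500)))
  # Cs * TSP = 0 -> exact equality with the simple equation
  set.seed(11)
  ci <- runif(50, 1, 5000)
  ce <- runif(50, 0, 6000)
  f <- runif(50, 10, 1e6)
  expect_equal(re_mass_balance(ci, ce, 0, f, runif(50, 0, 100)), re_simple(ci, ce))
  expect_equal(re_mass_balance(ci, ce, runif(50, 1, 10), f, 0), re_simple(ci, ce))
})

test_that("RE classes partition the line with upper-closed bins", {
  expect_equal(as.character(classify_re(c(0, 50, 75, 95))), c("Other", "Low", "Moderate", "High"))
  expect_equal(as.character(classify_re(c(-50, 25, 60, 80, 95.001, 100))),
    c("Other", "Low", "Moderate", "High", "Excellent", "Excellent"))
  expect_equal(as.character(classify_re(NA)), "NoData")
  # every finite percent maps to exactly one non-NoData class
  set.seed(3)
  x <- c(runif(500, -200, 200), 0, 50, 75, 95, 1e-12, 50 + 1e-12)
  cls <- classify_re(x)
  expect_false(any(is.na(cls)))
  expect_false(any(cls == "NoData"))
})

test_that("RE selection follows reported > mass balance > concentration precedence", {
  rec <- tibble::tibble(
    reported_re = c(62, NA, NA, NA),
    ci = c(100, 100, NA, NA), ce = c(20, 20, NA, NA),
    cs = c(0, 0, NA, NA), f = c(1000, 1000, NA, NA), tsp = c(500, 500, NA, NA),
    c_infl = c(100, 100, 100, NA), c_infl_censored = FALSE, c_infl_stat = "median",
    c_effl = c(10, 10, 40, 40), c_effl_censored = FALSE, c_effl_stat = "median"
  )
  out <- select_re(rec)
  expect_equal(out$re_method, c("reported", "eq2", "eq1", "none"))
  expect_equal(out$re_percent, c(62, 80, 60, NA))
  expect_equal(as.character(out$re_class), c("Moderate", "High", "Moderate", "NoData"))
})

test_that("censored concentrations give NoData by default, Other under the formation policy", {
  rec <- tibble::tibble(
    reported_re = NA_real_, ci = NA_real_, ce = NA_real_, cs = NA_real_,
    f = NA_real_, tsp = NA_real_,
    c_infl = c(NA, 100), c_infl_censored = c(TRUE, FALSE),
    c_effl = c(40, NA), c_effl_censored = c(FALSE, TRUE)
  )
  default <- select_re(rec)
  expect_equal(as.character(default$re_class), c("NoData", "NoData"))
  formation <- select_re(rec, censoring_policy = "formation")
  # influent below LOQ but chemical detected in effluent: apparent formation
  expect_equal(as.character(formation$re_class), c("Other", "NoData"))
})

test_that("worst-case consensus resolves ties downward and sets NoData aside", {
  expect_equal(consensus_re(c("Low", "Other"))$consensus_class, "Other")
  expect_true(consensus_re(c("Low", "Other"))$tie_broken)
  expect_equal(consensus_re(rep("High", 3))$consensus_class, "High")
  expect_equal(
    consensus_re(c(rep("NoData", 3), "Low", "Low", "Moderate"))$consensus_class,
    "Low"
  )
  expect_equal(consensus_re(rep("NoData", 4))$consensus_class, "NoData")
  expect_error(consensus_re(character()), "at least one")
  expect_error(consensus_re("Bogus"), "unknown RE class")
  counts <- consensus_re(c("Low", "Low", "High"))$class_counts
  expect_equal(sum(counts), 3L)
})

test_that("consensus agrees with the brute-force oracle on every multiset of size <= 5", {
  multisets <- all_class_multisets(5)
  expect_gt(length(multisets), 400)
  for (ms in multisets) {
    expect_equal(
      consensus_re(ms)$consensus_class, oracle_consensus(ms),
      info = paste(ms, collapse = ",")
    )
  }
})

test_that("consensus is invariant under permutation of its records", {
  set.seed(9)
  for (i in 1:25) {
    ms <- sample(c("Other", "Low", "Moderate", "High", "Excellent", "NoData"),
      sample(2:8, 1),
      replace = TRUE
    )
    expect_equal(
      consensus_re(ms)$consensus_class,
      consensus_re(sample(ms))$consensus_class
    )
  }
})

test_that("per-chemical consensus pools plant types separately and marks resistance", {
  rec <- tibble::tibble(
    chemical = c("sot", "sot", "sot", "amp", "amp"),
    wwtp_type = c("WWTP1", "WWTP2", "WWTP2", "WWTP1", "WWTP2"),
    re_class = c("Low", "Low", "Other", "High", "Other")
  )
  cons <- consensus_by_chemical(rec)
  sot2 <- cons[cons$chemical == "sot" & cons$wwtp_type == "WWTP2", ]
  expect_equal(sot2$consensus_class, "Other") # Low + Other tie -> worst
  expect_true(sot2$resistant)
  amp1 <- cons[cons$chemical == "amp" & cons$wwtp_type == "WWTP1", ]
  expect_equal(amp1$consensus_class, "High")
  expect_false(amp1$resistant)
})
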