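test_that("endpoint aggregation averages in-domain models and honors experimental priority", {
  preds <- tibble::tibble(
    model_id = c("KOWWIN", "OPERA_LOGP"), endpoint = "log_kow",
    value = c(4.9, 4.34), in_ad = TRUE
  )
  agg <- aggregate_endpoint(preds, "log_kow")
  expect_equal(agg$value, 4.62)
  expect_equal(agg$source, "mean-of-models")

  exp_first <- aggregate_endpoint(
    tibble::tibble(model_id = "KOWWIN", endpoint = "log_kow", value = 5, in_ad = TRUE),
    "log_kow",
    exp_value = 3.0
  )
  expect_equal(exp_first$value, 3.0)
  expect_equal(exp_first$source, "experimental")
})

test_that("Koc aggregation falls back to Soil Koc when KOCWIN (MCI) is out of domain", {
  preds <- tibble::tibble(
    model_id = c("KOCWIN_MCI", "SOIL_KOC"), endpoint = "log_koc",
    value = c(6.0, 2.8), in_ad = c(FALSE, TRUE)
  )
  agg <- aggregate_endpoint(preds, "log_koc")
  expect_equal(agg$value, 2.8)
  expect_equal(agg$source, "fallback-model")
  # both in domain: their mean (the fallback rule governs only out-of-AD)
  preds$in_ad <- TRUE
  both <- aggregate_endpoint(preds, "log_koc")
  expect_equal(both$value, 4.4)
  expect_equal(both$source, "mean-of-models")
})

test_that("aggregated means stay within contributing predictions; out-of-AD values are inert", {
  set.seed(21)
  for (i in 1:20) {
    vals <- runif(4, 0, 8)
    ad <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    if (!any(ad)) ad[1] <- TRUE
    preds <- tibble::tibble(
      model_id = rep(c("KOWWIN", "OPERA_LOGP"), 2)[1:4],
      endpoint = "log_kow", value = vals, in_ad = ad
    )
    agg <- aggregate_endpoint(preds, "log_kow")
    expect_gte(agg$value, min(vals[ad]))
    expect_lte(agg$value, max(vals[ad]))
    # arbitrary perturbation of out-of-AD values never moves the aggregate
    preds2 <- preds
    preds2$value[!preds2$in_ad] <- preds2$value[!preds2$in_ad] + rnorm(sum(!ad), 0, 100)
    expect_equal(aggregate_endpoint(preds2, "log_kow")$value, agg$value)
  }
  none <- aggregate_endpoint(
    tibble::tibble(model_id = "LOGBCF", endpoint = "log_bcf", value = 5, in_ad = FALSE),
    "log_bcf"
  )
  expect_true(is.na(none$value))
  expect_equal(none$source, "unassessable")
})

test_that("molar toxicity conversion handles both unit conventions", {
  expect_equal(convert_toxicity(6, "mol/L", 100), 0.1)
  expect_equal(convert_toxicity(3, "mmol/L", 100), 0.1)
  expect_equal(convert_toxicity(0, "mol/L", 1), 1000)
  expect_equal(
    convert_toxicity(c(6, 3), c("mol/L", "mmol/L"), c(100, 100)),
    c(0.1, 0.1)
  )
  expect_error(convert_toxicity(5, "g/L", 100), "unknown toxicity units")
  expect_error(convert_toxicity(5, "mol/L", -1), "mw must be positive")
})

test_that("persistence rule combines the timeframe and fast-probability criteria", {
  expect_true(flag_persistence(0.3, 2.0, 0.4))
  expect_false(flag_persistence(0.3, 3.0, 0.4)) # timeframe criterion fails
  expect_false(flag_persistence(0.6, 2.0, 0.6)) # both fast probabilities >= 0.5
  expect_true(flag_persistence(0.6, 2.0, 0.4)) # one fast model suffices ("or")
  expect_false(flag_persistence(0.6, 2.0, 0.4, rule = "and"))
  expect_true(is.na(flag_persistence(0.3, NA, 0.4))) # unassessable
  expect_true(is.na(flag_persistence(NA, 2.0, NA)))
  expect_true(flag_persistence(NA, 2.0, 0.4)) # one fast probability is enough input
})

test_that("bioaccumulation and mobility thresholds are strict as printed", {
  expect_true(flag_bioaccumulation(log_kow = 4.62)$pB)
  expect_false(flag_bioaccumulation(log_kow = 4.5)$pB) # boundary, strict
  b <- flag_bioaccumulation(log_bcf = 3.8)
  expect_true(b$pB)
  expect_true(b$pvB)
  expect_false(flag_bioaccumulation(log_bcf = 3.5)$pvB)
  expect_true(is.na(flag_bioaccumulation()$pB))

  cons <- threshold_profile("conservative_2019")
  eu <- threshold_profile("eu_2023")
  m <- flag_mobility(3.25, cons)
  expect_true(m$pM)
  expect_false(m$pvM)
  expect_false(flag_mobility(3.25, eu)$pM)
  m2 <- flag_mobility(1.5, eu)
  expect_true(m2$pM)
  expect_true(m2$pvM)
  expect_false(flag_mobility(4, cons)$pM) # boundary, strict
})

test_that("toxicity flag compares the minimum to the profile cut-off strictly", {
  p01 <- threshold_profile("conservative_2019", t_ec50_max_mg_l = 0.1)
  p001 <- threshold_profile("conservative_2019", t_ec50_max_mg_l = 0.01)
  expect_true(flag_toxicity(c(0.05, 2), p01)$pT)
  expect_false(flag_toxicity(c(0.05, 2), p001)$pT)
  expect_false(flag_toxicity(0.1, p01)$pT) # boundary, strict
  expect_equal(flag_toxicity(c(3, 0.2, 0.7), p01)$min_value, 0.2)
  expect_true(is.na(flag_toxicity(numeric(), p01)$pT))
})

test_that("endocrine-disruption evidence is a disjunction over the three binders", {
  expect_true(flag_ed(ar_binder = TRUE))
  expect_false(flag_ed())
  expect_true(flag_ed(httr_binder = "moderate"))
  expect_false(flag_ed(httr_binder = "none"))
  expect_error(flag_ed(httr_binder = "huge"), "hTTR")
})

test_that("label combination requires the full flag conjunctions", {
  expect_equal(combine_flags(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE), "PBT")
  expect_equal(combine_flags(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE), "PMT")
  expect_equal(
    combine_flags(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    c("PBT", "PMT")
  )
  expect_equal(combine_flags(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE), character())
  expect_equal(combine_flags(TRUE, NA, FALSE, NA, NA, TRUE), character())
  # very-categories need affirmative vP evidence
  expect_equal(
    combine_flags(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, pvP = TRUE),
    c("PBT", "vPvB")
  )
  # removing a true flag never adds a label
  set.seed(5)
  for (i in 1:30) {
    fl <- as.logical(rbinom(6, 1, 0.5))
    full <- combine_flags(fl[1], fl[2], fl[3], fl[4], fl[5], fl[6])
    drop <- which(fl)
    if (length(drop) == 0) next
    j <- sample(drop, 1)
    fl[j] <- FALSE
    reduced <- combine_flags(fl[1], fl[2], fl[3], fl[4], fl[5], fl[6])
    expect_true(all(reduced %in% full))
  }
})

test_that("assessment reproduces the published borderline worked examples", {
  cons <- threshold_profile("conservative_2019")
  eu <- threshold_profile("eu_2023")
  # triclocarban-like: persistent, Log Kow above 4.5, Log Koc 3.25, toxic
  tcc <- make_bundle(
    biowin2 = 0.2, biowin3 = 1.9, biowin6 = 0.3,
    log_kow = 4.62, log_koc = 3.25, log_bcf = 2.0, p_fish = 7.5
  )
  v_cons <- assess(tcc, cons)
  expect_setequal(v_cons$labels[[1]], c("PBT", "PMT"))
  v_eu <- assess(tcc, eu)
  expect_setequal(v_eu$labels[[1]], "PBT")
  # lorazepam-like: persistent, not B, Log Koc below 3, toxic
  lor <- make_bundle(
    biowin2 = 0.2, biowin3 = 1.9, biowin6 = 0.3,
    log_kow = 2.4, log_koc = 2.5, log_bcf = 1.0, p_fish = 7.5
  )
  v_lor <- assess(lor, cons)
  expect_equal(v_lor$labels[[1]], "PMT")
  expect_true(v_lor$pvM)
  # benign bundle: no label
  ben <- make_bundle(
    biowin2 = 0.9, biowin3 = 3.3, biowin6 = 0.9,
    log_kow = 1.5, log_koc = 4.6, log_bcf = 1.0, p_fish = 2.0
  )
  expect_equal(assess(ben, cons)$labels[[1]], character())
})

test_that("conservative mobility flags are a superset of EU-2023 flags", {
  cons <- threshold_profile("conservative_2019")
  eu <- threshold_profile("eu_2023")
  set.seed(13)
  koc <- runif(200, 0, 7)
  for (k in koc) {
    m_eu <- flag_mobility(k, eu)
    m_cons <- flag_mobility(k, cons)
    if (isTRUE(m_eu$pM)) expect_true(m_cons$pM)
    if (isTRUE(m_eu$pvM)) expect_true(m_cons$pvM)
  }
})

test_that("threshold profiles validate their internal ordering and overrides", {
  expect_error(threshold_profile("eu_2023", vm_logkoc_max = 3.5), "vm_logkoc_max")
  expect_error(threshold_profile("conservative_2019", b_logbcf_min = 4), "vb_logbcf_min")
  expect_error(threshold_profile("conservative_2019", bogus = 1), "unknown threshold")
  p <- threshold_profile("eu_2023")
  expect_equal(p$m_logkoc_max, 3)
  expect_equal(p$vm_logkoc_max, 2)
})

test_that("profiles read from the shipped YAML match the built-ins", {
  path <- system.file("extdata", "threshold_profiles.yaml", package = "ppcpscreen")
  profs <- read_threshold_profiles(path)
  expect_setequal(names(profs), c("conservative_2019", "eu_2023"))
  for (nm in names(profs)) {
    builtin <- threshold_profile(nm)
    expect_equal(unclass(profs[[nm]]), unclass(builtin))
  }
})

test_that("L2 predictions annotate the verdict but never drive labels", {
  bundle <- make_bundle(
    biowin2 = 0.2, biowin3 = 1.9, biowin6 = 0.3,
    log_kow = 5.5, log_koc = 5.0, log_bcf = 4.0, p_fish = 7.5
  )
  bundle$predictions <- rbind(
    bundle$predictions,
    tibble::tibble(
      chemical = "X", model_id = "PBT_INDEX", endpoint = "pbt_index",
      value = 0.9, units = "index", in_ad = TRUE, screening_level = "L2"
    )
  )
  v <- assess(bundle, threshold_profile("conservative_2019"))
  expect_match(v$l2_annotation, "PBT_INDEX")
  bundle$predictions$value[bundle$predictions$screening_level == "L2"] <- -99
  v2 <- assess(bundle, threshold_profile("conservative_2019"))
  expect_equal(v2$labels[[1]], v$labels[[1]])
  expect_equal(v2$log_kow, v$log_kow)
})
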