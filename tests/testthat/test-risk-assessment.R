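test_that("PNEC unit arithmetic and round-trip identity", {
  expect_equal(compute_pnec(0.5), 500)
  expect_equal(compute_pnec(1000), 1e6)
  expect_equal(compute_pnec(0.001), 1)
  expect_error(compute_pnec(0), "positive")
  expect_error(compute_pnec(1, assessment_factor = -5), "assessment_factor")
  # PNEC * AF recovers the minimum in ng/L
  set.seed(31)
  m <- runif(50, 1e-4, 100)
  af <- sample(c(10, 100, 1000), 50, replace = TRUE)
  expect_equal(compute_pnec(m, af) * af, m * 1e6)
})

test_that("risk quotients divide exactly, are linear in CA, and flag strictly above 1", {
  expect_equal(compute_pr(600, 500), 1.2)
  expect_equal(compute_pr(0, 500), 0)
  expect_equal(compute_pr(500, 500), 1) # not an exceedance (strict >)
  expect_error(compute_pr(-1, 500), "non-negative")
  expect_error(compute_pr(10, 0), "positive")
  set.seed(32)
  ca <- runif(40, 0, 1e4)
  pnec <- runif(40, 1, 1e4)
  k <- runif(40, 0.1, 10)
  expect_equal(compute_pr(k * ca, pnec), k * compute_pr(ca, pnec))
})

test_that("toxicity minima split lethal and effect endpoints and gate on the AD", {
  preds <- tibble::tibble(
    chemical = "X",
    model_id = c("F1", "F2", "A1", "D1"),
    endpoint = c("pLC50_fish", "pLC50_fish", "pEC50_algae", "pEC50_daphnia"),
    value = c(6, 5, 4, 7),
    units = c("mol/L", "mol/L", "mol/L", "mmol/L"),
    in_ad = c(TRUE, TRUE, TRUE, FALSE)
  )
  mw <- tibble::tibble(chemical = "X", mw = 100)
  m <- toxicity_minima(preds, mw)
  # lc50: min(10^-6, 10^-5) * 1e5 mg/L = 0.1 ; ec50: only algae (Daphnia out of AD)
  expect_equal(m$min_lc50_mg_l, 0.1)
  expect_equal(m$min_ec50_mg_l, 10)
  expect_lte(m$min_lc50_mg_l, 0.1 + 1e-12)
  # out-of-AD Daphnia value must not matter however extreme
  preds$value[4] <- 20
  expect_equal(toxicity_minima(preds, mw)$min_ec50_mg_l, 10)
})

test_that("per-record risk table carries both bases and the exceedance flag", {
  ca <- tibble::tibble(
    chemical = c("X", "X", "Y"),
    plant_id = c("P1", "P2", "P1"),
    continent = c("Europe", "Asia", "Europe"),
    ca_ng_l = c(600, 40, 100)
  )
  minima <- tibble::tibble(
    chemical = c("X", "Y", "Z"),
    min_lc50_mg_l = c(0.5, NA, 1),
    min_ec50_mg_l = c(0.8, 0.05, 1)
  )
  risk <- assess_risk(ca, minima)
  expect_equal(nrow(risk), 3) # Z has no measured CA and is absent
  x1 <- risk[risk$plant_id == "P1" & risk$chemical == "X", ]
  expect_equal(x1$pr_lc50, 600 / 500)
  expect_equal(x1$pr_ec50, 600 / 800)
  expect_true(x1$exceeds)
  expect_false(risk$exceeds[risk$plant_id == "P2" & risk$chemical == "X"])
  y <- risk[risk$chemical == "Y", ]
  expect_true(is.na(y$pr_lc50))
  expect_true(y$exceeds) # 100 / 50 on the EC50 basis
})

test_that("prioritization intersects hazard labels with risk flags", {
  verdicts <- tibble::tibble(
    chemical = c("A", "B", "C"),
    profile = "conservative_2019",
    labels = list("PMT", character(), "PBT"),
    label_string = c("PMT", "", "PBT")
  )
  risk <- tibble::tibble(
    chemical = c("A", "A", "B"),
    continent = c("Europe", "Asia", "Europe"),
    pr_lc50 = c(0.4, 1.3, 2.0),
    pr_ec50 = c(0.2, 0.9, 1.5),
    exceeds = c(FALSE, TRUE, TRUE)
  )
  consensus <- tibble::tibble(
    chemical = c("A", "B", "C"),
    wwtp_type = "WWTP1",
    consensus_class = c("Low", "High", "Other")
  )
  pri <- prioritize(verdicts, risk, consensus)
  expect_equal(pri$intersection, "A") # C has no CA record, B has no label
  hazard_set <- verdicts$chemical[verdicts$label_string != ""]
  risk_set <- unique(risk$chemical[risk$exceeds])
  expect_true(all(pri$intersection %in% hazard_set))
  expect_true(all(pri$intersection %in% risk_set))
  a <- pri$table[pri$table$chemical == "A", ]
  expect_equal(a$exceedance_continents, "Asia")
  expect_equal(a$re_WWTP1, "Low")
})

test_that("risk cross-tab matches a brute-force group-by on the same records", {
  set.seed(33)
  n <- 150
  cases <- tibble::tibble(
    continent = sample(c("Europe", "Asia", "America", "Africa", "Oceania"), n, TRUE),
    re_class = sample(c("Other", "Low", "Moderate", "High", "Excellent"), n, TRUE)
  )
  tab <- summarize_pr_by_continent(cases)
  brute <- table(cases$continent, cases$re_class)
  for (cont in rownames(brute)) {
    for (cl in colnames(brute)) {
      expect_equal(
        tab$counts[[cl]][tab$counts$continent == cont],
        unname(brute[cont, cl])
      )
    }
  }
  expect_equal(unname(tab$class_totals[["Total"]]), n)
  expect_equal(sum(tab$class_total_pct), 100)
})
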