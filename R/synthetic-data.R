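#' Configuration for the synthetic study generator
#'
#' Defines the conditions of a literature-like monitoring study with
#' known ground truth: a roster of chemicals drawn from hazard
#' archetypes, a set of plants across continents and treatment types,
#' per-record influent/effluent concentrations with multiplicative
#' noise and left-censoring at a limit of quantification (LOQ), and
#' per-model property predictions with additive noise and optional
#' applicability-domain dropout.
#'
#' Archetypes place every true property value at least three prediction
#' noise standard deviations away from each screening threshold the
#' archetype is designed to clear (or to miss), so that stage recovery
#' is near-perfect at the default noise level:
#' \describe{
#'   \item{PMT}{persistent, highly mobile (low Log Koc), acutely toxic.}
#'   \item{PBT}{persistent, bioaccumulative (high Log Kow / Log BCF),
#'     sorbing (high Log Koc), acutely toxic.}
#'   \item{ED}{readily degradable and benign on P/B/M/T, but an
#'     androgen-receptor binder.}
#'   \item{benign}{readily degradable, no flag.}
#' }
#'
#' @param n_chemicals number of chemicals (default 40).
#' @param archetype_mix named proportions over
#'   `c("PMT", "PBT", "ED", "benign")`; must sum to 1.
#' @param plants_per_continent named integer vector of plants per
#'   continent.
#' @param records_range integer range (min, max) of records per
#'   chemical x plant.
#' @param plants_per_chemical how many plants report each chemical.
#' @param conc_meanlog,conc_sdlog log-normal influent concentration
#'   parameters (ng/L scale).
#' @param noise_cv coefficient of variation of the multiplicative
#'   effluent noise (default 0.05).
#' @param loq limit of quantification in ng/L; concentrations below it
#'   are censored (default 5).
#' @param ad_dropout probability that a prediction is out of its
#'   applicability domain. AD membership is a property of the external
#'   QSAR models rather than of the monitoring study, so the default is
#'   0; raise it to exercise AD gating.
#' @param prediction_noise_sd named per-endpoint-family additive noise
#'   standard deviations: `log` (partitioning endpoints, log10 units),
#'   `prob` (BIOWIN fast probabilities), `biowin3` (timeframe score),
#'   `tox` (toxicity p-values, log10 molar).
#' @param p_low_quality probability a record is generated with QI Low.
#' @param seed integer seed; identical configs give identical output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_chemicals = 40,
                             archetype_mix = c(PMT = 0.25, PBT = 0.25, ED = 0.2, benign = 0.3),
                             plants_per_continent = c(
                               Europe = 6, Asia = 5, America = 3, Africa = 1, Oceania = 1
                             ),
                             records_range = c(1, 3),
                             plants_per_chemical = 4,
                             conc_meanlog = log(1000), conc_sdlog = 0.8,
                             noise_cv = 0.05,
                             loq = 5,
                             ad_dropout = 0,
                             prediction_noise_sd = c(
                               log = 0.15, prob = 0.05, biowin3 = 0.1, tox = 0.15
                             ),
                             p_low_quality = 0.1,
                             seed = 1L) {
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    stop("archetype_mix proportions must sum to 1", call. = FALSE)
  }
  if (!setequal(names(archetype_mix), c("PMT", "PBT", "ED", "benign"))) {
    stop("archetype_mix must name PMT, PBT, ED and benign", call. = FALSE)
  }
  stopifnot(
    n_chemicals >= 1, noise_cv >= 0, loq >= 0,
    ad_dropout >= 0, ad_dropout <= 1,
    all(prediction_noise_sd >= 0), conc_sdlog >= 0,
    p_low_quality >= 0, p_low_quality <= 1
  )
  structure(
    list(
      n_chemicals = as.integer(n_chemicals),
      archetype_mix = archetype_mix,
      plants_per_continent = plants_per_continent,
      records_range = as.integer(records_range),
      plants_per_chemical = as.integer(plants_per_chemical),
      conc_meanlog = conc_meanlog, conc_sdlog = conc_sdlog,
      noise_cv = noise_cv, loq = loq,
      ad_dropout = ad_dropout,
      prediction_noise_sd = prediction_noise_sd,
      p_low_quality = p_low_quality,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# truncated-normal draw by clamping (margins stay exact at the bounds)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

# archetype true property values; bounds keep each value >= 3 * default
# prediction noise sd away from every threshold the archetype addresses
archetype_truth <- function(archetype, n) {
  draw <- switch(archetype,
    PMT = list(
      biowin2 = rtnorm(n, 0.20, 0.05, 0.02, 0.35),
      biowin3 = rtnorm(n, 1.60, 0.10, 1.30, 1.80),
      biowin6 = rtnorm(n, 0.20, 0.05, 0.02, 0.35),
      log_kow = rtnorm(n, 2.5, 0.20, 1.0, 4.05),
      log_koc = rtnorm(n, 1.2, 0.15, 0.5, 1.55),
      log_bcf = rtnorm(n, 1.5, 0.20, 0.5, 2.85),
      lc50_mg_l = rep(0.03, n), ec50_mg_l = rep(0.02, n),
      ar_binder = rep(FALSE, n)
    ),
    PBT = list(
      biowin2 = rtnorm(n, 0.20, 0.05, 0.02, 0.35),
      biowin3 = rtnorm(n, 1.60, 0.10, 1.30, 1.80),
      biowin6 = rtnorm(n, 0.20, 0.05, 0.02, 0.35),
      log_kow = rtnorm(n, 5.8, 0.20, 4.95, 7.5),
      log_koc = rtnorm(n, 5.5, 0.30, 4.45, 6.5),
      log_bcf = rtnorm(n, 4.5, 0.20, 4.15, 5.5),
      lc50_mg_l = rep(0.03, n), ec50_mg_l = rep(0.02, n),
      ar_binder = rep(FALSE, n)
    ),
    ED = list(
      biowin2 = rtnorm(n, 0.80, 0.05, 0.65, 0.98),
      biowin3 = rtnorm(n, 3.20, 0.20, 2.70, 4.0),
      biowin6 = rtnorm(n, 0.80, 0.05, 0.65, 0.98),
      log_kow = rtnorm(n, 2.5, 0.20, 1.0, 4.05),
      log_koc = rtnorm(n, 5.0, 0.30, 4.45, 6.0),
      log_bcf = rtnorm(n, 1.5, 0.20, 0.5, 2.85),
      lc50_mg_l = rep(60, n), ec50_mg_l = rep(50, n),
      ar_binder = rep(TRUE, n)
    ),
    benign = list(
      biowin2 = rtnorm(n, 0.80, 0.05, 0.65, 0.98),
      biowin3 = rtnorm(n, 3.20, 0.20, 2.70, 4.0),
      log_kow = rtnorm(n, 2.5, 0.20, 1.0, 4.05),
      biowin6 = rtnorm(n, 0.80, 0.05, 0.65, 0.98),
      log_koc = rtnorm(n, 5.0, 0.30, 4.45, 6.0),
      log_bcf = rtnorm(n, 1.5, 0.20, 0.5, 2.85),
      lc50_mg_l = rep(60, n), ec50_mg_l = rep(50, n),
      ar_binder = rep(FALSE, n)
    ),
    stop("unknown archetype: ", archetype, call. = FALSE)
  )
  tibble::as_tibble(draw[c(
    "biowin2", "biowin3", "biowin6", "log_kow", "log_koc", "log_bcf",
    "lc50_mg_l", "ec50_mg_l", "ar_binder"
  )])
}

# class-interior true removal efficiencies, safely away from class bounds
RE_TRUE_VALUES <- c(Other = -25, Low = 25, Moderate = 65, High = 85, Excellent = 98)

# p-value (-log10 molar) that converts back to the given mg/L value
p_from_mg_l <- function(mg_l, units, mw) {
  denom <- if (units == "mol/L") mw * 1000 else mw
  -log10(mg_l / denom)
}

#' Generate a synthetic monitoring study with known ground truth
#'
#' Produces the three input tables consumed by the pipeline stages plus
#' the ground truth they were generated from. Effluent concentrations
#' follow `effluent = influent * (1 - RE/100) * (1 + eps)` with
#' `eps ~ N(0, noise_cv)`; values below the LOQ are censored.
#' Predictions are `truth + N(0, sd)` per endpoint family, each flagged
#' in-domain with probability `1 - ad_dropout`. The true hazard labels
#' are whatever [assess()] returns on the noiseless truth.
#'
#' @param config a [generator_config()].
#' @return List with `records` (literature-style record table),
#'   `predictions` (long per-model prediction table), `ed_flags`,
#'   `mw`, `ca` (measured effluent concentrations) and `truth`
#'   (per-chemical ground truth incl. true labels per profile and true
#'   RE per plant type).
#' @export
generate_study_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)

  n <- config$n_chemicals
  counts <- round(config$archetype_mix * n)
  # rounding drift goes to the largest group
  counts[which.max(counts)] <- counts[which.max(counts)] + n - sum(counts)
  archetypes <- rep(names(counts), counts)

  chem_id <- sprintf("CHEM%03d", seq_len(n))
  truth <- purrr::map_dfr(unique(archetypes), function(a) {
    archetype_truth(a, sum(archetypes == a)) |>
      dplyr::mutate(archetype = a)
  })
  truth <- dplyr::mutate(truth,
    chemical = chem_id, mw = round(stats::runif(n, 150, 450), 1),
    .before = 1
  )

  # plants: half of each continent's plants are tertiary (WWTP2); plant
  # metadata alternates between declared levels and technology tokens so
  # classification is exercised both ways
  plants <- purrr::imap_dfr(
    as.list(config$plants_per_continent),
    function(k, continent) {
      if (k == 0) return(NULL)
      advanced <- seq_len(k) <= k %/% 2
      tibble::tibble(
        plant_id = sprintf("%s_P%02d", toupper(substr(continent, 1, 2)), seq_len(k)),
        continent = continent,
        true_type = ifelse(advanced, "WWTP2", "WWTP1"),
        declared_level = ifelse(seq_len(k) %% 2 == 0,
          ifelse(advanced, "tertiary/advanced", "secondary"),
          NA_character_
        ),
        technologies = ifelse(!is.na(declared_level), "",
          ifelse(advanced, "ozonation;uv disinfection", "activated sludge")
        )
      )
    }
  )

  # true RE per chemical x plant type: WWTP2 performs at least as well
  re1 <- sample(names(RE_TRUE_VALUES), n, replace = TRUE, prob = c(.2, .25, .2, .2, .15))
  re2 <- vapply(re1, function(c1) {
    i <- match(c1, names(RE_TRUE_VALUES))
    names(RE_TRUE_VALUES)[sample(i:length(RE_TRUE_VALUES), 1)]
  }, character(1))
  truth$true_re_wwtp1 <- unname(RE_TRUE_VALUES[re1])
  truth$true_re_wwtp2 <- unname(RE_TRUE_VALUES[re2])

  # monitoring records
  records <- purrr::map_dfr(seq_len(n), function(i) {
    sel <- plants[sample(nrow(plants), min(config$plants_per_chemical, nrow(plants))), ]
    purrr::map_dfr(seq_len(nrow(sel)), function(j) {
      plant <- sel[j, ]
      true_re <- if (plant$true_type == "WWTP2") truth$true_re_wwtp2[i] else truth$true_re_wwtp1[i]
      n_rec <- sample(config$records_range[1]:config$records_range[2], 1)
      infl <- stats::rlnorm(n_rec, config$conc_meanlog, config$conc_sdlog)
      effl <- infl * (1 - true_re / 100) * (1 + stats::rnorm(n_rec, 0, config$noise_cv))
      effl <- pmax(effl, 0)
      low_q <- stats::runif(n_rec) < config$p_low_quality
      scores <- t(vapply(low_q, function(lq) {
        if (lq) {
          s <- c(0L, 0L, 0L)
          s[sample(3, 1)] <- sample(0:1, 1)
          s
        } else {
          s <- sample(1:2, 3, replace = TRUE)
          if (sum(s) < 2) s[1] <- 2L
          s
        }
      }, integer(3)))
      tibble::tibble(
        chemical = chem_id[i],
        cas = sprintf("%d-%02d-%d", 10000 + i, (i %% 90) + 10, i %% 10),
        name = paste0("compound-", i),
        smiles = "CCO",
        use_class = sample(c("ANTB", "PDAM", "OIDM", "AIMB", "SHA", "AHCV"), 1),
        mw = truth$mw[i],
        source_id = sprintf("SRC%02d", sample(20, 1)),
        plant_id = plant$plant_id,
        continent = plant$continent,
        declared_level = plant$declared_level,
        technologies = plant$technologies,
        molecule_id_score = scores[, 1],
        re_data_score = scores[, 2],
        general_info_score = scores[, 3],
        c_infl = infl,
        c_infl_censored = infl < config$loq,
        c_infl_stat = "median",
        c_effl = effl,
        c_effl_censored = effl < config$loq,
        c_effl_stat = "median",
        ci = NA_real_, ce = NA_real_, cs = NA_real_,
        f = NA_real_, tsp = NA_real_,
        reported_re = NA_real_
      )
    })
  })
  records$c_infl[records$c_infl_censored] <- NA_real_
  records$c_effl[records$c_effl_censored] <- NA_real_

  predictions <- synth_predictions(truth, config)
  ed_flags <- tibble::tibble(
    chemical = truth$chemical,
    er_binder = FALSE,
    ar_binder = truth$ar_binder,
    httr_binder = "none"
  )
  mw <- tibble::tibble(chemical = truth$chemical, mw = truth$mw)

  ca <- records |>
    dplyr::filter(!.data$c_effl_censored) |>
    dplyr::transmute(
      chemical = .data$chemical, plant_id = .data$plant_id,
      continent = .data$continent, ca_ng_l = .data$c_effl
    )

  truth <- add_true_labels(truth)
  list(
    records = records, predictions = predictions, ed_flags = ed_flags,
    mw = mw, ca = ca, truth = truth
  )
}

# noisy long-format prediction table from the truth table
synth_predictions <- function(truth, config) {
  sd <- config$prediction_noise_sd
  n <- nrow(truth)
  noisy <- function(x, s) x + stats::rnorm(length(x), 0, s)
  in_ad <- function() stats::runif(n) >= config$ad_dropout
  rowset <- function(model_id, endpoint, value, units, level = "L1") {
    tibble::tibble(
      chemical = truth$chemical, model_id = model_id, endpoint = endpoint,
      value = value, units = units, in_ad = in_ad(), screening_level = level
    )
  }
  p_fish <- p_from_mg_l(truth$lc50_mg_l, "mol/L", truth$mw)
  p_algae <- p_from_mg_l(truth$ec50_mg_l, "mol/L", truth$mw)
  p_daph <- p_from_mg_l(truth$ec50_mg_l * 1.5, "mmol/L", truth$mw)
  dplyr::bind_rows(
    rowset("BIOWIN2", "biowin2", pmin(pmax(noisy(truth$biowin2, sd[["prob"]]), 0), 1), "probability"),
    rowset("BIOWIN3", "biowin3", noisy(truth$biowin3, sd[["biowin3"]]), "score"),
    rowset("BIOWIN6", "biowin6", pmin(pmax(noisy(truth$biowin6, sd[["prob"]]), 0), 1), "probability"),
    rowset("KOWWIN", "log_kow", noisy(truth$log_kow, sd[["log"]]), "log10"),
    rowset("OPERA_LOGP", "log_kow", noisy(truth$log_kow, sd[["log"]]), "log10"),
    rowset("KOCWIN_MCI", "log_koc", noisy(truth$log_koc, sd[["log"]]), "log10"),
    rowset("SOIL_KOC", "log_koc", noisy(truth$log_koc, sd[["log"]]), "log10"),
    rowset("LOGBCF", "log_bcf", noisy(truth$log_bcf, sd[["log"]]), "log10"),
    rowset("FISH_LC50_M1", "pLC50_fish", noisy(p_fish, sd[["tox"]]), "mol/L"),
    rowset("ALGAE_EC50_M1", "pEC50_algae", noisy(p_algae, sd[["tox"]]), "mol/L"),
    rowset("DAPHNIA_EC50_M1", "pEC50_daphnia", noisy(p_daph, sd[["tox"]]), "mmol/L"),
    rowset("GHLI", "ghli", noisy(rep(0.5, n), 0.1), "index", "L2"),
    rowset("PBT_INDEX", "pbt_index", noisy(rep(0.5, n), 0.1), "index", "L2")
  )
}

# noiseless bundles through assess() define the true labels
add_true_labels <- function(truth) {
  profiles <- list(
    threshold_profile("conservative_2019"),
    threshold_profile("eu_2023")
  )
  labels <- purrr::map(seq_len(nrow(truth)), function(i) {
    bundle <- list(
      chemical = truth$chemical[i],
      mw = truth$mw[i],
      predictions = noiseless_predictions(truth[i, ]),
      ed_flags = list(
        er_binder = FALSE, ar_binder = truth$ar_binder[i], httr_binder = "none"
      )
    )
    sapply(profiles, function(p) assess(bundle, p)$label_string)
  })
  truth$true_labels_conservative <- vapply(labels, `[`, character(1), 1)
  truth$true_labels_eu2023 <- vapply(labels, `[`, character(1), 2)
  truth
}

noiseless_predictions <- function(row) {
  tibble::tibble(
    chemical = row$chemical,
    model_id = c(
      "BIOWIN2", "BIOWIN3", "BIOWIN6", "KOWWIN", "OPERA_LOGP",
      "KOCWIN_MCI", "SOIL_KOC", "LOGBCF",
      "FISH_LC50_M1", "ALGAE_EC50_M1", "DAPHNIA_EC50_M1"
    ),
    endpoint = c(
      "biowin2", "biowin3", "biowin6", "log_kow", "log_kow",
      "log_koc", "log_koc", "log_bcf",
      "pLC50_fish", "pEC50_algae", "pEC50_daphnia"
    ),
    value = c(
      row$biowin2, row$biowin3, row$biowin6, row$log_kow, row$log_kow,
      row$log_koc, row$log_koc, row$log_bcf,
      p_from_mg_l(row$lc50_mg_l, "mol/L", row$mw),
      p_from_mg_l(row$ec50_mg_l, "mol/L", row$mw),
      p_from_mg_l(row$ec50_mg_l * 1.5, "mmol/L", row$mw)
    ),
    units = c(
      "probability", "score", "probability", "log10", "log10",
      "log10", "log10", "log10", "mol/L", "mol/L", "mmol/L"
    ),
    in_ad = TRUE,
    screening_level = "L1"
  )
}

#' Write a generated study to CSV files
#'
#' Emits the CSV dialects consumed by [run_pipeline()]:
#' `records.csv`, `predictions.csv`, `ed_flags.csv`, `mw.csv`, `ca.csv`
#' and `truth.csv`.
#'
#' @param data list from [generate_study_data()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_study_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- c("records", "predictions", "ed_flags", "mw", "ca", "truth")
  paths <- file.path(dir, paste0(nm, ".csv"))
  for (i in seq_along(nm)) {
    readr::write_csv(data[[nm[i]]], paths[i], progress = FALSE)
  }
  invisible(paths)
}

#' Recovery of the ground truth by the pipeline
#'
#' Compares pipeline outputs with the generator's ground truth and
#' reports per-stage recovery rates: the fraction of chemical x
#' plant-type pools whose consensus RE class equals the class of the
#' true RE, the fraction of chemicals whose hazard label set matches the
#' true labels (per profile), and the fraction of chemicals whose
#' any-exceedance risk flag matches the flag implied by the noiseless
#' effluents. With zero noise, no censoring and no AD dropout all rates
#' are 1.
#'
#' @param truth truth tibble from [generate_study_data()].
#' @param consensus tibble from [consensus_by_chemical()].
#' @param verdicts tibble from [assess_chemicals()] (profiles
#'   `conservative_2019` and/or `eu_2023`).
#' @param risk optional tibble from [assess_risk()].
#' @param true_risk_flags optional tibble `chemical`, `true_exceeds`
#'   (as produced by [true_risk_flags()]); required when `risk` given.
#' @return Tibble with columns `stage`, `metric`, `n`, `rate`.
#' @export
recovery_report <- function(truth, consensus, verdicts, risk = NULL,
                            true_risk_flags = NULL) {
  rows <- list()

  cons_truth <- tidyr::pivot_longer(
    truth[, c("chemical", "true_re_wwtp1", "true_re_wwtp2")],
    -"chemical",
    names_to = "wwtp_type", values_to = "true_re",
    names_pattern = "true_re_(.*)"
  )
  cons_truth$wwtp_type <- toupper(cons_truth$wwtp_type)
  cons <- dplyr::inner_join(consensus, cons_truth, by = c("chemical", "wwtp_type"))
  cons_hit <- cons$consensus_class == as.character(classify_re(cons$true_re))
  rows$consensus <- tibble::tibble(
    stage = "removal_efficiency", metric = "consensus_class_accuracy",
    n = nrow(cons), rate = mean(cons_hit)
  )

  for (prof in unique(verdicts$profile)) {
    truth_col <- switch(prof,
      conservative_2019 = "true_labels_conservative",
      eu_2023 = "true_labels_eu2023",
      NA_character_
    )
    if (is.na(truth_col)) next
    v <- verdicts[verdicts$profile == prof, c("chemical", "label_string")]
    cmp <- dplyr::inner_join(
      v, truth[, c("chemical", truth_col)],
      by = "chemical"
    )
    rows[[prof]] <- tibble::tibble(
      stage = "hazard_screening",
      metric = paste0("label_accuracy_", prof),
      n = nrow(cmp),
      rate = mean(cmp$label_string == cmp[[truth_col]])
    )
  }

  if (!is.null(risk)) {
    stopifnot(!is.null(true_risk_flags))
    flags <- risk |>
      dplyr::group_by(.data$chemical) |>
      dplyr::summarise(exceeds = any(.data$exceeds), .groups = "drop") |>
      dplyr::inner_join(true_risk_flags, by = "chemical")
    rows$risk <- tibble::tibble(
      stage = "risk_assessment", metric = "pr_flag_accuracy",
      n = nrow(flags), rate = mean(flags$exceeds == flags$true_exceeds)
    )
  }
  dplyr::bind_rows(rows)
}

#' Ground-truth risk flags from noiseless effluent concentrations
#'
#' For each chemical, recomputes the noiseless effluent concentrations
#' implied by the true RE values and the generated influents, derives
#' PNECs from the true toxicity minima, and flags chemicals whose
#' noiseless concentration would exceed a PNEC.
#'
#' @param truth truth tibble from [generate_study_data()].
#' @param records generated record table (for the influents and plant
#'   types); only quality-kept records contribute.
#' @param assessment_factor default 1000.
#' @return Tibble `chemical`, `true_exceeds`.
#' @export
true_risk_flags <- function(truth, records, assessment_factor = 1000) {
  rec <- records
  q <- qi_class_from_total(
    rec$molecule_id_score + rec$re_data_score + rec$general_info_score
  )
  rec <- rec[q != "Low", , drop = FALSE]
  joined <- dplyr::inner_join(
    rec[, c("chemical", "plant_id", "c_infl")],
    truth[, c(
      "chemical", "true_re_wwtp1", "true_re_wwtp2",
      "lc50_mg_l", "ec50_mg_l"
    )],
    by = "chemical"
  )
  wwtp2 <- grepl("WWTP2", plant_type_of(joined$plant_id, records))
  true_re <- ifelse(wwtp2, joined$true_re_wwtp2, joined$true_re_wwtp1)
  effl <- joined$c_infl * (1 - true_re / 100)
  pnec <- pmin(
    compute_pnec(joined$lc50_mg_l, assessment_factor),
    compute_pnec(joined$ec50_mg_l, assessment_factor)
  )
  ok <- !is.na(effl)
  tibble::tibble(
    chemical = joined$chemical[ok],
    exceed = effl[ok] / pnec[ok] > 1
  ) |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(true_exceeds = any(.data$exceed), .groups = "drop")
}

# map plant ids to their true type via the record metadata
plant_type_of <- function(plant_ids, records) {
  meta <- unique(records[, c("plant_id", "declared_level", "technologies")])
  types <- vapply(seq_len(nrow(meta)), function(i) {
    classify_wwtp(meta$declared_level[i], split_tokens(meta$technologies[i]))
  }, character(1))
  types[match(plant_ids, meta$plant_id)]
}
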