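#' Built-in screening threshold profiles
#'
#' Two named profiles are provided. `conservative_2019` follows the
#' screening thresholds proposed by the German Environment Agency (UBA)
#' in 2019: mobility Log Koc < 4 (pM) and < 3 (pvM). `eu_2023` follows
#' the mobility criteria of the EU CLP delegated regulation (valid over
#' the environmental pH range 4--9): Log Koc < 3 (pM) and < 2 (pvM).
#' Persistence, bioaccumulation and toxicity cut-offs are shared
#' (REACH Annex XIII screening): BIOWIN ultimate-timeframe < 2.25 with a
#' fast-biodegradation probability < 0.5 for P; Log Kow > 4.5 or
#' Log BCF > 3.3 for B, Log BCF > 3.7 for vB; minimum acute EC50/LC50
#' < 0.1 mg/L for T (a stricter 0.01 mg/L variant is selectable). All
#' comparisons are strict.
#'
#' @param name `"conservative_2019"` or `"eu_2023"`.
#' @param t_ec50_max_mg_l toxicity cut-off in mg/L: 0.1 (default,
#'   worst-case screening) or 0.01 (strict).
#' @param ... named overrides for individual thresholds
#'   (`p_biowin3_max`, `p_fastprob_max`, `b_logkow_min`, `b_logbcf_min`,
#'   `vb_logbcf_min`, `m_logkoc_max`, `vm_logkoc_max`).
#' @return An object of class `threshold_profile` (a named list).
#' @examples
#' threshold_profile("conservative_2019")
#' threshold_profile("eu_2023", t_ec50_max_mg_l = 0.01)
#' @export
threshold_profile <- function(name = c("conservative_2019", "eu_2023"),
                              t_ec50_max_mg_l = 0.1, ...) {
  name <- match.arg(name)
  prof <- list(
    name = name,
    p_biowin3_max = 2.25,
    p_fastprob_max = 0.5,
    b_logkow_min = 4.5,
    b_logbcf_min = 3.3,
    vb_logbcf_min = 3.7,
    m_logkoc_max = if (name == "conservative_2019") 4 else 3,
    vm_logkoc_max = if (name == "conservative_2019") 3 else 2,
    t_ec50_max_mg_l = t_ec50_max_mg_l
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(prof))
  if (length(unknown) > 0) {
    stop("unknown threshold field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  prof[names(overrides)] <- overrides
  validate_profile(prof)
}

validate_profile <- function(prof) {
  if (!prof$vm_logkoc_max < prof$m_logkoc_max) {
    stop("vm_logkoc_max must be below m_logkoc_max", call. = FALSE)
  }
  if (!prof$vb_logbcf_min > prof$b_logbcf_min) {
    stop("vb_logbcf_min must be above b_logbcf_min", call. = FALSE)
  }
  if (!prof$t_ec50_max_mg_l > 0) stop("t_ec50_max_mg_l must be positive", call. = FALSE)
  structure(prof, class = "threshold_profile")
}

#' @export
print.threshold_profile <- function(x, ...) {
  cat("<threshold_profile>", x$name, "\n")
  for (nm in setdiff(names(x), "name")) cat(" ", nm, "=", x[[nm]], "\n")
  invisible(x)
}

#' Read threshold profiles from a YAML file
#'
#' The file maps profile names to threshold fields; fields omitted for a
#' name fall back to the built-in defaults of [threshold_profile()]
#' (names other than the two built-ins start from `conservative_2019`
#' defaults).
#'
#' @param path YAML file; see
#'   `system.file("extdata", "threshold_profiles.yaml", package = "ppcpscreen")`.
#' @return Named list of `threshold_profile` objects.
#' @export
read_threshold_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    base <- if (nm %in% c("conservative_2019", "eu_2023")) nm else "conservative_2019"
    prof <- threshold_profile(base)
    fields <- raw[[nm]]
    unknown <- setdiff(names(fields), setdiff(names(prof), "name"))
    if (length(unknown) > 0) {
      stop("profile `", nm, "`: unknown field(s) ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    prof[names(fields)] <- fields
    prof$name <- nm
    validate_profile(prof)
  })
  names(out) <- names(raw)
  out
}

# endpoint -> L1 model ids contributing to the aggregated value
L1_MODELS <- list(
  log_kow = c("KOWWIN", "OPERA_LOGP"),
  log_koc = c("KOCWIN_MCI", "SOIL_KOC"),
  log_bcf = c("LOGBCF")
)

#' Aggregate per-model predictions for one partitioning endpoint
#'
#' Experimental values take priority. Otherwise the in-domain
#' (applicability domain, AD) level-1 predictions for the endpoint are
#' averaged arithmetically. For Log Koc only: when the KOCWIN (MCI)
#' prediction is out of its AD, the Soil Koc prediction alone is used
#' (fallback); when both are in-domain their mean is used. Out-of-AD
#' predictions never contribute.
#'
#' @param predictions tibble with columns `model_id`, `endpoint`,
#'   `value`, `in_ad` (rows for one chemical).
#' @param endpoint `"log_kow"`, `"log_koc"` or `"log_bcf"`.
#' @param exp_value optional experimental value for the endpoint.
#' @return A list with `value` (numeric or `NA` when unassessable),
#'   `source` (`"experimental"`, `"mean-of-models"`, `"fallback-model"`
#'   or `"unassessable"`) and `n_models`.
#' @examples
#' preds <- tibble::tibble(
#'   model_id = c("KOWWIN", "OPERA_LOGP"), endpoint = "log_kow",
#'   value = c(4.9, 4.34), in_ad = TRUE
#' )
#' aggregate_endpoint(preds, "log_kow") # mean 4.62
#' @export
aggregate_endpoint <- function(predictions, endpoint = c("log_kow", "log_koc", "log_bcf"),
                               exp_value = NULL) {
  endpoint <- match.arg(endpoint)
  if (!is.null(exp_value) && length(exp_value) == 1 && !is.na(exp_value)) {
    return(list(value = as.numeric(exp_value), source = "experimental", n_models = 0L))
  }
  rows <- predictions[predictions$endpoint == endpoint &
    predictions$model_id %in% L1_MODELS[[endpoint]], , drop = FALSE]
  if (endpoint == "log_koc") {
    mci <- rows[rows$model_id == "KOCWIN_MCI", , drop = FALSE]
    soil <- rows[rows$model_id == "SOIL_KOC", , drop = FALSE]
    mci_ok <- nrow(mci) > 0 && isTRUE(mci$in_ad[1]) && !is.na(mci$value[1])
    soil_ok <- nrow(soil) > 0 && isTRUE(soil$in_ad[1]) && !is.na(soil$value[1])
    if (!mci_ok && soil_ok) {
      return(list(value = soil$value[1], source = "fallback-model", n_models = 1L))
    }
  }
  ok <- isTRUE_vec(rows$in_ad) & !is.na(rows$value)
  vals <- rows$value[ok]
  if (length(vals) == 0) {
    return(list(value = NA_real_, source = "unassessable", n_models = 0L))
  }
  list(value = mean(vals), source = "mean-of-models", n_models = length(vals))
}

#' Convert a predicted molar toxicity to mg/L
#'
#' QSAR acute-toxicity models report `p` values, the negative base-10
#' logarithm of the effect concentration in mol/L or mmol/L. With the
#' molecular weight in g/mol: mol/L gives `10^(-p) * mw * 1000` mg/L,
#' mmol/L gives `10^(-p) * mw` mg/L.
#'
#' @param p_value numeric `-log10` concentration.
#' @param units `"mol/L"` or `"mmol/L"`.
#' @param mw molecular weight (g/mol, positive).
#' @return Concentration in mg/L.
#' @examples
#' convert_toxicity(6, "mol/L", 100)  # 0.1 mg/L
#' convert_toxicity(3, "mmol/L", 100) # 0.1 mg/L
#' @export
convert_toxicity <- function(p_value, units, mw) {
  if (any(is.na(mw) | mw <= 0)) stop("mw must be positive", call. = FALSE)
  scale <- ifelse(units == "mol/L", 1000,
    ifelse(units == "mmol/L", 1, NA_real_)
  )
  if (anyNA(scale)) {
    stop(
      "unknown toxicity units: ",
      paste(unique(units[is.na(scale)]), collapse = ", "),
      call. = FALSE
    )
  }
  10^(-p_value) * mw * scale
}

#' Screen persistence from BIOWIN predictions
#'
#' Flagged potentially P (or vP; the screening does not separate them)
#' when the ultimate-biodegradation timeframe (BIOWIN 3) is below 2.25
#' and a fast-biodegradation probability (BIOWIN 2 or BIOWIN 6) is below
#' 0.5. Pass `NA` for predictions that are missing or out of the
#' applicability domain. With `rule = "and"` both fast probabilities
#' must fall below the cut-off.
#'
#' @param biowin2,biowin6 fast-biodegradation probabilities in `[0, 1]`.
#' @param biowin3 ultimate-biodegradation timeframe score.
#' @param profile a [threshold_profile()].
#' @param rule how the two fast-probability models combine: `"or"`
#'   (default) or `"and"`.
#' @return `TRUE`/`FALSE`, or `NA` when unassessable (no timeframe or no
#'   fast probability available).
#' @export
flag_persistence <- function(biowin2, biowin3, biowin6,
                             profile = threshold_profile(),
                             rule = c("or", "and")) {
  rule <- match.arg(rule)
  fast <- c(biowin2, biowin6)
  fast <- fast[!is.na(fast)]
  if (is.na(biowin3) || length(fast) == 0) return(NA)
  fast_hit <- fast < profile$p_fastprob_max
  fast_ok <- if (rule == "or") any(fast_hit) else all(fast_hit)
  biowin3 < profile$p_biowin3_max && fast_ok
}

#' Screen bioaccumulation from Log Kow and Log BCF
#'
#' `pB` when Log Kow > 4.5 or Log BCF > 3.3; `pvB` when Log BCF > 3.7
#' (strict inequalities). `NA` inputs are ignored; with no input at all
#' both flags are `NA`.
#'
#' @param log_kow,log_bcf aggregated values (may be `NA`).
#' @param profile a [threshold_profile()].
#' @return List with logical `pB` and `pvB`.
#' @export
flag_bioaccumulation <- function(log_kow = NA, log_bcf = NA,
                                 profile = threshold_profile()) {
  if (is.na(log_kow) && is.na(log_bcf)) return(list(pB = NA, pvB = NA))
  kow_hit <- !is.na(log_kow) && log_kow > profile$b_logkow_min
  bcf_hit <- !is.na(log_bcf) && log_bcf > profile$b_logbcf_min
  list(
    pB = kow_hit || bcf_hit,
    pvB = if (is.na(log_bcf)) FALSE else log_bcf > profile$vb_logbcf_min
  )
}

#' Screen mobility from Log Koc
#'
#' `pM` when Log Koc is below the profile's mobility cut-off, `pvM`
#' below the very-mobile cut-off (strict inequalities; lower Koc means
#' higher aqueous mobility).
#'
#' @param log_koc aggregated Log Koc (may be `NA`).
#' @param profile a [threshold_profile()].
#' @return List with logical `pM` and `pvM` (`NA` when unassessable).
#' @export
flag_mobility <- function(log_koc, profile = threshold_profile()) {
  if (is.na(log_koc)) return(list(pM = NA, pvM = NA))
  list(
    pM = log_koc < profile$m_logkoc_max,
    pvM = log_koc < profile$vm_logkoc_max
  )
}

#' Screen toxicity from the minimum acute effect concentration
#'
#' The minimum over all available in-domain acute EC50/LC50 values
#' (mg/L) across algae, Daphnia and fish is compared to the profile's
#' toxicity cut-off (strict inequality).
#'
#' @param tox_values_mg_l numeric vector of acute toxicity values in
#'   mg/L (already converted and AD-gated).
#' @param profile a [threshold_profile()].
#' @return List with logical `pT` and `min_value` (mg/L, `NA` when no
#'   value is available).
#' @export
flag_toxicity <- function(tox_values_mg_l, profile = threshold_profile()) {
  vals <- tox_values_mg_l[!is.na(tox_values_mg_l)]
  if (length(vals) == 0) return(list(pT = NA, min_value = NA_real_))
  m <- min(vals)
  list(pT = m < profile$t_ec50_max_mg_l, min_value = m)
}

#' Screen endocrine-disruption evidence
#'
#' Flagged when the chemical is predicted to bind the estrogen receptor,
#' the androgen receptor, or human transthyretin (hTTR) at any strength.
#'
#' @param er_binder,ar_binder logical (NA treated as no evidence).
#' @param httr_binder one of `"none"`, `"weak"`, `"moderate"`,
#'   `"strong"` (NA treated as `"none"`).
#' @return Logical.
#' @export
flag_ed <- function(er_binder = FALSE, ar_binder = FALSE, httr_binder = "none") {
  httr <- if (is.na(httr_binder)) "none" else tolower(httr_binder)
  if (!httr %in% c("none", "weak", "moderate", "strong")) {
    stop("unknown hTTR binder category: ", httr_binder, call. = FALSE)
  }
  isTRUE(er_binder) || isTRUE(ar_binder) || httr != "none"
}

#' Combine screening flags into hazard labels
#'
#' `PBT` requires pP, pB and pT; `PMT` requires pP, pM and pT; `vPvB`
#' requires pvP and pvB; `vPvM` requires pvP and pvM. The BIOWIN
#' screening rule yields one joint "pP or pvP" flag that does not by
#' itself establish very-persistent status, so the very-categories are
#' only labelled when `pvP` is asserted explicitly; by default the
#' label set is a subset of `c("PBT", "PMT")` with pvB/pvM carried as
#' flags. Unassessable (`NA`) flags count as not flagged.
#'
#' @param pP,pB,pvB,pM,pvM,pT logicals (possibly `NA`).
#' @param pvP affirmative very-persistent evidence; default `FALSE`.
#' @return Character vector, a subset of
#'   `c("PBT", "PMT", "vPvB", "vPvM")`.
#' @export
combine_flags <- function(pP, pB, pvB, pM, pvM, pT, pvP = FALSE) {
  tflag <- function(x) !is.na(x) & x
  labels <- c(
    if (tflag(pP) && tflag(pB) && tflag(pT)) "PBT",
    if (tflag(pP) && tflag(pM) && tflag(pT)) "PMT",
    if (tflag(pvP) && tflag(pvB)) "vPvB",
    if (tflag(pvP) && tflag(pvM)) "vPvM"
  )
  as.character(labels)
}

#' Assess one chemical's property bundle against a threshold profile
#'
#' Aggregates the partitioning endpoints (experimental priority, AD
#' gating, Soil-Koc fallback), converts and minimizes the acute
#' toxicity predictions, evaluates every screening flag and combines
#' them into hazard labels. Level-2 (non-regulatory) predictions are
#' carried through as provenance annotation only.
#'
#' @param bundle a list describing one chemical:
#'   `chemical` (id), `mw` (g/mol), `predictions` (tibble with
#'   `model_id`, `endpoint`, `value`, `units`, `in_ad`,
#'   `screening_level`), optional `exp_log_kow`, `exp_log_koc`, and
#'   `ed_flags` (list with `er_binder`, `ar_binder`, `httr_binder`).
#' @param profile a [threshold_profile()].
#' @param p_rule passed to [flag_persistence()].
#' @return A one-row tibble: chemical, profile, the seven flags, `pED`,
#'   `labels` (list-column), `label_string`, aggregated endpoint values
#'   with sources, and `l2_annotation`.
#' @export
assess <- function(bundle, profile = threshold_profile(), p_rule = c("or", "and")) {
  p_rule <- match.arg(p_rule)
  preds <- bundle$predictions
  stopifnot(is.data.frame(preds))
  if (!"screening_level" %in% names(preds)) preds$screening_level <- "L1"
  l1 <- preds[preds$screening_level == "L1", , drop = FALSE]

  kow <- aggregate_endpoint(l1, "log_kow", bundle$exp_log_kow)
  koc <- aggregate_endpoint(l1, "log_koc", bundle$exp_log_koc)
  bcf <- aggregate_endpoint(l1, "log_bcf")

  bio <- function(model) {
    row <- l1[l1$model_id == model, , drop = FALSE]
    if (nrow(row) == 0 || !isTRUE_vec(row$in_ad)[1]) NA_real_ else row$value[1]
  }
  pP <- flag_persistence(bio("BIOWIN2"), bio("BIOWIN3"), bio("BIOWIN6"),
    profile = profile, rule = p_rule
  )
  b <- flag_bioaccumulation(kow$value, bcf$value, profile = profile)
  m <- flag_mobility(koc$value, profile = profile)

  tox <- l1[grepl("^p(lc|ec)50", tolower(l1$endpoint)) & isTRUE_vec(l1$in_ad), , drop = FALSE]
  tox_mg_l <- if (nrow(tox) > 0) {
    convert_toxicity(tox$value, tox$units, bundle$mw)
  } else {
    numeric()
  }
  t <- flag_toxicity(tox_mg_l, profile = profile)

  ed <- bundle$ed_flags
  pED <- if (is.null(ed)) {
    NA
  } else {
    flag_ed(ed$er_binder %||% FALSE, ed$ar_binder %||% FALSE, ed$httr_binder %||% "none")
  }

  labels <- combine_flags(
    pP = pP, pB = b$pB, pvB = b$pvB, pM = m$pM, pvM = m$pvM, pT = t$pT
  )
  l2 <- preds[preds$screening_level == "L2", , drop = FALSE]
  l2_note <- if (nrow(l2) == 0) {
    NA_character_
  } else {
    paste(sprintf("%s=%.3g", l2$model_id, l2$value), collapse = "; ")
  }
  label_string <- paste(labels, collapse = "+")

  tibble::tibble(
    chemical = bundle$chemical %||% NA_character_,
    profile = profile$name,
    pP = pP, pvP = pP,
    pB = b$pB, pvB = b$pvB,
    pM = m$pM, pvM = m$pvM,
    pT = t$pT, pED = pED,
    labels = list(labels),
    label_string = label_string,
    log_kow = kow$value, log_kow_source = kow$source,
    log_koc = koc$value, log_koc_source = koc$source,
    log_bcf = bcf$value, log_bcf_source = bcf$source,
    min_tox_mg_l = t$min_value,
    l2_annotation = l2_note
  )
}

#' Assess many chemicals from long-format prediction tables
#'
#' Tidy front end to [assess()]: splits the prediction table by
#' chemical, joins experimental values and endocrine-disruption flags,
#' and binds the per-chemical verdicts, once per requested profile.
#'
#' @param predictions tibble: `chemical`, `model_id`, `endpoint`,
#'   `value`, `units`, `in_ad`, `screening_level`.
#' @param mw tibble: `chemical`, `mw` (g/mol).
#' @param experimental optional tibble: `chemical`, `endpoint`
#'   (`log_kow`/`log_koc`), `value`.
#' @param ed_flags optional tibble: `chemical`, `er_binder`,
#'   `ar_binder`, `httr_binder`.
#' @param profiles list of [threshold_profile()] objects.
#' @param p_rule passed to [flag_persistence()].
#' @return Verdicts tibble, one row per chemical x profile.
#' @export
assess_chemicals <- function(predictions, mw, experimental = NULL, ed_flags = NULL,
                             profiles = list(threshold_profile("conservative_2019")),
                             p_rule = c("or", "and")) {
  p_rule <- match.arg(p_rule)
  chems <- unique(predictions$chemical)
  mw_map <- stats::setNames(mw$mw, mw$chemical)
  exp_val <- function(chem, ep) {
    if (is.null(experimental)) return(NULL)
    v <- experimental$value[experimental$chemical == chem & experimental$endpoint == ep]
    if (length(v) == 0) NULL else v[1]
  }
  purrr::map_dfr(chems, function(chem) {
    ed <- NULL
    if (!is.null(ed_flags) && chem %in% ed_flags$chemical) {
      row <- ed_flags[ed_flags$chemical == chem, , drop = FALSE]
      ed <- list(
        er_binder = row$er_binder[1], ar_binder = row$ar_binder[1],
        httr_binder = row$httr_binder[1]
      )
    }
    bundle <- list(
      chemical = chem,
      mw = unname(mw_map[chem]),
      predictions = predictions[predictions$chemical == chem, , drop = FALSE],
      exp_log_kow = exp_val(chem, "log_kow"),
      exp_log_koc = exp_val(chem, "log_koc"),
      ed_flags = ed
    )
    purrr::map_dfr(profiles, function(prof) assess(bundle, prof, p_rule = p_rule))
  })
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
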