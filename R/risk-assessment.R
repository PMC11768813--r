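#' Minimum predicted acute toxicity per chemical
#'
#' Scans the in-domain level-1 acute-toxicity predictions, converts them
#' to mg/L with [convert_toxicity()], and takes per-chemical minima
#' separately over lethal endpoints (pLC50, fish) and effect endpoints
#' (pEC50, algae and Daphnia). Out-of-domain predictions never enter the
#' minima.
#'
#' @param predictions tibble: `chemical`, `model_id`, `endpoint`,
#'   `value`, `units`, `in_ad` (and optionally `screening_level`;
#'   only `"L1"` rows are used).
#' @param mw tibble: `chemical`, `mw` (g/mol).
#' @return Tibble with one row per chemical: `chemical`,
#'   `min_lc50_mg_l`, `min_ec50_mg_l` (`NA` when no usable prediction).
#' @export
toxicity_minima <- function(predictions, mw) {
  preds <- predictions
  if ("screening_level" %in% names(preds)) {
    preds <- preds[preds$screening_level == "L1", , drop = FALSE]
  }
  ep <- tolower(preds$endpoint)
  is_tox <- grepl("^p(lc|ec)50", ep)
  preds <- preds[is_tox & isTRUE_vec(preds$in_ad) & !is.na(preds$value), , drop = FALSE]
  preds <- dplyr::left_join(preds, mw, by = "chemical")
  if (anyNA(preds$mw)) {
    stop("missing molecular weight for: ",
      paste(unique(preds$chemical[is.na(preds$mw)]), collapse = ", "),
      call. = FALSE
    )
  }
  preds$mg_l <- convert_toxicity(preds$value, preds$units, preds$mw)
  preds$basis <- ifelse(grepl("^plc50", tolower(preds$endpoint)), "lc50", "ec50")
  min_or_na <- function(x) if (length(x) == 0) NA_real_ else min(x)
  preds |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(
      min_lc50_mg_l = min_or_na(.data$mg_l[.data$basis == "lc50"]),
      min_ec50_mg_l = min_or_na(.data$mg_l[.data$basis == "ec50"]),
      .groups = "drop"
    )
}

#' Predicted no-effect concentration from a toxicity minimum
#'
#' `PNEC [ng/L] = minimum [mg/L] * 1e6 / AF`: the minimum acute
#' EC50/LC50 across trophic levels, converted to ng/L and divided by an
#' assessment factor (default 1000, the acute-to-no-effect factor of
#' the EU technical guidance).
#'
#' @param minimum_mg_l positive toxicity minimum in mg/L. Vectorized.
#' @param assessment_factor positive scalar, default 1000.
#' @return PNEC in ng/L.
#' @examples
#' compute_pnec(0.5)   # 500 ng/L
#' compute_pnec(0.001) # 1 ng/L
#' @export
compute_pnec <- function(minimum_mg_l, assessment_factor = 1000) {
  if (any(assessment_factor <= 0)) stop("assessment_factor must be positive", call. = FALSE)
  if (any(minimum_mg_l <= 0, na.rm = TRUE)) {
    stop("toxicity minimum must be positive", call. = FALSE)
  }
  minimum_mg_l * 1e6 / assessment_factor
}

#' Risk quotient from a measured effluent concentration
#'
#' `PR = CA / PNEC`, both in ng/L; a chemical is flagged when any of its
#' quotients strictly exceeds 1.
#'
#' @param ca measured effluent concentration (ng/L, non-negative).
#' @param pnec predicted no-effect concentration (ng/L, positive).
#' @return Numeric ratio. Vectorized.
#' @export
compute_pr <- function(ca, pnec) {
  if (any(pnec <= 0, na.rm = TRUE)) stop("pnec must be positive", call. = FALSE)
  if (any(ca < 0, na.rm = TRUE)) stop("ca must be non-negative", call. = FALSE)
  ca / pnec
}

#' Risk quotients for every measured effluent concentration
#'
#' Joins the per-chemical toxicity minima onto the concentration
#' records, computes PNECs and risk quotients separately on the LC50 and
#' EC50 basis, and flags exceedance. Chemicals without any measured
#' concentration are absent by construction; records for chemicals
#' without any usable toxicity prediction are dropped.
#'
#' @param ca_records tibble: `chemical`, `plant_id`, `continent`,
#'   `ca_ng_l` (one row per measured effluent concentration).
#' @param minima tibble from [toxicity_minima()].
#' @param assessment_factor default 1000.
#' @return Tibble with `pnec_lc50_ng_l`, `pnec_ec50_ng_l`, `pr_lc50`,
#'   `pr_ec50` and `exceeds` (any computed PR > 1) added per record.
#' @export
assess_risk <- function(ca_records, minima, assessment_factor = 1000) {
  risk <- dplyr::inner_join(ca_records, minima, by = "chemical")
  risk <- risk[!(is.na(risk$min_lc50_mg_l) & is.na(risk$min_ec50_mg_l)), , drop = FALSE]
  # per-basis PNEC with NA pass-through (no prediction on that basis)
  pnec_vec <- function(m) {
    out <- rep(NA_real_, length(m))
    ok <- !is.na(m)
    if (any(ok)) out[ok] <- compute_pnec(m[ok], assessment_factor)
    out
  }
  risk$pnec_lc50_ng_l <- pnec_vec(risk$min_lc50_mg_l)
  risk$pnec_ec50_ng_l <- pnec_vec(risk$min_ec50_mg_l)
  risk$pr_lc50 <- ifelse(is.na(risk$pnec_lc50_ng_l), NA_real_,
    risk$ca_ng_l / risk$pnec_lc50_ng_l
  )
  risk$pr_ec50 <- ifelse(is.na(risk$pnec_ec50_ng_l), NA_real_,
    risk$ca_ng_l / risk$pnec_ec50_ng_l
  )
  risk$exceeds <- pmax(
    ifelse(is.na(risk$pr_lc50), -Inf, risk$pr_lc50),
    ifelse(is.na(risk$pr_ec50), -Inf, risk$pr_ec50)
  ) > 1
  risk
}

#' Prioritize chemicals across the hazard, removal and risk stages
#'
#' Per-chemical roll-up: the hazard labels per profile, the consensus RE
#' class per plant type, the any-exceedance risk flag with the
#' continents where exceedances were recorded, and the intersection
#' list of chemicals that are both hazard-labelled (PMT or PBT) and
#' risk-flagged.
#'
#' @param verdicts tibble from [assess_chemicals()].
#' @param risk tibble from [assess_risk()].
#' @param consensus tibble from [consensus_by_chemical()].
#' @return List with `table` (one row per chemical) and `intersection`
#'   (chemicals with a PMT or PBT label and at least one PR > 1).
#' @export
prioritize <- function(verdicts, risk, consensus) {
  hazard <- verdicts |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(
      labels_by_profile = paste(
        sprintf("%s:%s", .data$profile, .data$label_string),
        collapse = " | "
      ),
      pmt_or_pbt = any(purrr::map_lgl(
        .data$labels, \(l) any(l %in% c("PMT", "PBT"))
      )),
      .groups = "drop"
    )
  risk_roll <- risk |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(
      n_pr_cases = dplyr::n(),
      pr_flagged = any(.data$exceeds),
      max_pr = max(c(.data$pr_lc50, .data$pr_ec50), na.rm = TRUE),
      exceedance_continents = paste(
        sort(unique(.data$continent[.data$exceeds])),
        collapse = ";"
      ),
      .groups = "drop"
    )
  cons_wide <- consensus |>
    dplyr::select("chemical", "wwtp_type", "consensus_class") |>
    tidyr::pivot_wider(
      names_from = "wwtp_type", values_from = "consensus_class",
      names_prefix = "re_"
    )
  tab <- hazard |>
    dplyr::full_join(risk_roll, by = "chemical") |>
    dplyr::left_join(cons_wide, by = "chemical") |>
    dplyr::mutate(
      pmt_or_pbt = !is.na(.data$pmt_or_pbt) & .data$pmt_or_pbt,
      pr_flagged = !is.na(.data$pr_flagged) & .data$pr_flagged
    ) |>
    dplyr::arrange(dplyr::desc(.data$pmt_or_pbt), dplyr::desc(.data$pr_flagged))
  list(
    table = tab,
    intersection = sort(tab$chemical[tab$pmt_or_pbt & tab$pr_flagged])
  )
}
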