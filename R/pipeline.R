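#' Run the full screening-and-prioritization pipeline
#'
#' Chains the four analysis stages: record curation (quality-index
#' scoring, QI-Low exclusion, WWTP typing), removal-efficiency
#' computation and consensus, hazard screening against one or more
#' threshold profiles, and risk quotients with final prioritization.
#'
#' @param records raw record tibble (see [read_records()]).
#' @param predictions long per-model prediction tibble.
#' @param mw tibble `chemical`, `mw`.
#' @param ed_flags optional endocrine-disruption flag tibble.
#' @param ca optional measured effluent concentration tibble
#'   (`chemical`, `plant_id`, `continent`, `ca_ng_l`); when `NULL`,
#'   detected effluent concentrations from the kept records are used.
#' @param experimental optional experimental Log Kow / Log Koc tibble.
#' @param profiles list of [threshold_profile()] objects; default both
#'   built-ins.
#' @param censoring_policy passed to [select_re()].
#' @param p_rule passed to [flag_persistence()].
#' @param assessment_factor passed to [assess_risk()].
#' @return List with every stage output: `curated` (kept/excluded/
#'   dropped), `re_records`, `consensus`, `verdicts`, `risk`,
#'   `prioritized`.
#' @export
run_pipeline <- function(records, predictions, mw, ed_flags = NULL, ca = NULL,
                         experimental = NULL,
                         profiles = list(
                           threshold_profile("conservative_2019"),
                           threshold_profile("eu_2023")
                         ),
                         censoring_policy = c("nodata", "formation"),
                         p_rule = c("or", "and"),
                         assessment_factor = 1000) {
  censoring_policy <- match.arg(censoring_policy)
  p_rule <- match.arg(p_rule)
  check_schema(records, c("chemical", "molecule_id_score", "re_data_score", "general_info_score"),
    what = "records"
  )
  check_schema(predictions, c("chemical", "model_id", "endpoint", "value", "in_ad"),
    what = "predictions"
  )
  check_schema(mw, c("chemical", "mw"), what = "mw")

  curated <- curate_records(records)
  kept <- curated$kept
  re_records <- select_re(kept, censoring_policy = censoring_policy)
  consensus <- consensus_by_chemical(re_records)

  roster <- unique(kept$chemical)
  verdicts <- assess_chemicals(
    predictions[predictions$chemical %in% roster, , drop = FALSE],
    mw,
    experimental = experimental, ed_flags = ed_flags,
    profiles = profiles, p_rule = p_rule
  )

  if (is.null(ca)) {
    ca <- kept |>
      dplyr::filter(!isTRUE_vec(.data$c_effl_censored), !is.na(.data$c_effl)) |>
      dplyr::transmute(
        chemical = .data$chemical, plant_id = .data$plant_id,
        continent = .data$continent, ca_ng_l = .data$c_effl
      )
  } else {
    check_schema(ca, c("chemical", "ca_ng_l"), what = "ca")
    ca <- ca[ca$chemical %in% roster, , drop = FALSE]
  }
  minima <- toxicity_minima(
    predictions[predictions$chemical %in% roster, , drop = FALSE], mw
  )
  risk <- assess_risk(ca, minima, assessment_factor = assessment_factor)
  prioritized <- prioritize(verdicts, risk, consensus)

  list(
    curated = curated, re_records = re_records, consensus = consensus,
    verdicts = verdicts, risk = risk, prioritized = prioritized
  )
}

# fail early, naming the table and the missing columns
check_schema <- function(df, required, what) {
  if (!is.data.frame(df)) stop("`", what, "` must be a data frame", call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(
      "`", what, "` is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(df)
}

#' Distribution of consensus RE classes per plant type
#'
#' The per-plant-type analogue of the classic removal-efficiency summary
#' table: counts of chemicals per consensus class and their percentage
#' of each plant type's chemical total. Percentages are kept at full
#' precision; round only when rendering.
#'
#' @param consensus tibble from [consensus_by_chemical()], or any tibble
#'   with `wwtp_type` and `consensus_class` columns (one row per
#'   chemical x plant type).
#' @return Tibble: `consensus_class`, one count and one percent column
#'   per plant type, plus a `Total` row-less attribute-free layout:
#'   columns `n_<type>` and `pct_<type>`.
#' @export
summarize_re_distribution <- function(consensus) {
  check_schema(consensus, c("wwtp_type", "consensus_class"), what = "consensus")
  consensus |>
    dplyr::count(.data$wwtp_type, consensus_class = factor(
      as.character(.data$consensus_class),
      levels = RE_CLASSES_ALL
    ), .drop = FALSE) |>
    dplyr::group_by(.data$wwtp_type) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(
      names_from = "wwtp_type", values_from = c("n", "pct"),
      names_glue = "{.value}_{wwtp_type}"
    )
}

#' Cross-tabulate risk cases by continent and RE class
#'
#' One "PR case" is one effluent record whose risk quotient exceeds 1.
#' The cross-tab counts PR cases per continent within each consensus RE
#' class and reports column percentages (share of each class's cases by
#' continent), a continent total column, and a class-total row whose
#' percentages are shares of the grand total.
#'
#' @param pr_cases tibble with one row per PR case and columns
#'   `continent` and `re_class`.
#' @return List with `counts` (continent x class tibble incl. `Total`
#'   column), `column_pct` (same shape, percentages), `class_totals`
#'   (named vector incl. grand total `Total`), `class_total_pct`
#'   (share of grand total per class).
#' @export
summarize_pr_by_continent <- function(pr_cases) {
  check_schema(pr_cases, c("continent", "re_class"), what = "pr_cases")
  if (nrow(pr_cases) == 0) {
    return(list(
      counts = tibble::tibble(continent = character(), Total = integer()),
      column_pct = tibble::tibble(continent = character()),
      class_totals = c(Total = 0L), class_total_pct = numeric()
    ))
  }
  classes <- RE_CLASSES[RE_CLASSES %in% unique(as.character(pr_cases$re_class))]
  classes <- union(classes, setdiff(unique(as.character(pr_cases$re_class)), RE_CLASSES))
  tab <- table(
    continent = pr_cases$continent,
    re_class = factor(as.character(pr_cases$re_class), levels = classes)
  )
  counts <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "continent")
  counts$Total <- unname(rowSums(tab))
  col_tot <- colSums(tab)
  grand <- sum(col_tot)
  pct <- sweep(tab, 2, pmax(col_tot, 1), "/") * 100
  column_pct <- tibble::as_tibble(as.data.frame.matrix(pct), rownames = "continent")
  column_pct$Total <- 100 * counts$Total / grand
  list(
    counts = counts,
    column_pct = column_pct,
    class_totals = c(col_tot, Total = grand),
    class_total_pct = 100 * col_tot / grand
  )
}

#' Extract the PR cases from a risk table
#'
#' Filters the per-record risk results to exceedances (any PR > 1) and
#' attaches the consensus RE class of the chemical in the plant type
#' where the case was recorded.
#'
#' @param risk tibble from [assess_risk()]; needs `plant_id`.
#' @param re_records tibble from [select_re()] (provides plant typing).
#' @param consensus tibble from [consensus_by_chemical()].
#' @return Tibble of PR cases with `continent` and `re_class` columns,
#'   ready for [summarize_pr_by_continent()].
#' @export
pr_cases <- function(risk, re_records, consensus) {
  cases <- risk[risk$exceeds, , drop = FALSE]
  plant_types <- unique(re_records[, c("plant_id", "wwtp_type")])
  cases <- dplyr::left_join(cases, plant_types, by = "plant_id")
  cases <- dplyr::left_join(
    cases,
    consensus[, c("chemical", "wwtp_type", "consensus_class")],
    by = c("chemical", "wwtp_type")
  )
  cases$re_class <- cases$consensus_class
  cases
}

#' Render a percentage for report tables
#'
#' @param pct numeric percentage (full precision).
#' @param digits decimals to print: 0 for the plant-type distribution
#'   style, 2 for the risk cross-tab style.
#' @return Character vector like `"33%"` or `"32.20%"`.
#' @export
render_percent <- function(pct, digits = 0) {
  paste0(formatC(round(pct, digits), format = "f", digits = digits), "%")
}
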