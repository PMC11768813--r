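#' Removal-efficiency classes
#'
#' Class levels in worst-to-best order (`Other` is worse than `Low`:
#' a non-positive RE indicates no net removal or in-plant formation).
#' `NoData` marks records whose RE could not be quantified.
#' @keywords internal
RE_CLASSES <- c("Other", "Low", "Moderate", "High", "Excellent")
RE_CLASSES_ALL <- c(RE_CLASSES, "NoData")

#' Simple removal efficiency from influent and effluent concentrations
#'
#' `RE% = (1 - c_effl / c_infl) * 100`. The result is bounded above by
#' 100 and may be negative (apparent in-plant formation, e.g.
#' de-conjugation of excreted conjugates).
#'
#' @param c_infl,c_effl concentrations in ng/L. Vectorized.
#' @return Numeric vector of RE percentages; `NA` where the influent is
#'   missing, zero or negative, or the effluent is missing (no-data
#'   outcome, not an error).
#' @export
re_simple <- function(c_infl, c_effl) {
  out <- (1 - c_effl / c_infl) * 100
  out[is.na(c_infl) | is.na(c_effl) | c_infl <= 0 | c_effl < 0] <- NA_real_
  out
}

#' Removal efficiency from a sludge mass balance
#'
#' `RE% = (Ci*F - (Ce*F + Cs*TSP)) / (Ci*F) * 100`, with all loads in
#' ng/d: `Ci`, `Ce` in ng/L, `F` in L/d, `Cs` in ng/g wet weight and
#' `TSP` in g/d wet weight. Reduces exactly to [re_simple()] when the
#' sludge term `Cs*TSP` is zero.
#'
#' @param ci,ce influent and effluent concentrations (ng/L).
#' @param cs sludge concentration (ng/g wet weight).
#' @param f influent flow (L/d).
#' @param tsp total sludge production (g/d wet weight).
#' @return Numeric vector of RE percentages; `NA` where any parameter is
#'   missing or the influent load `Ci*F` is not positive.
#' @export
re_mass_balance <- function(ci, ce, cs, f, tsp) {
  infl_load <- ci * f
  out <- (infl_load - (ce * f + cs * tsp)) / infl_load * 100
  bad <- is.na(ci) | is.na(ce) | is.na(cs) | is.na(f) | is.na(tsp) | infl_load <= 0
  out[bad] <- NA_real_
  out
}

#' Bin a removal efficiency into its class
#'
#' Bins partition the real line, closed on the upper side:
#' Other (RE <= 0), Low (0 < RE <= 50), Moderate (50 < RE <= 75),
#' High (75 < RE <= 95), Excellent (RE > 95). `NA` maps to `NoData`
#' (missing values or concentrations below the limit of
#' quantification/detection). No rounding is applied before binning.
#'
#' @param percent numeric vector of RE percentages (may be `NA`).
#' @return Factor with levels `Other, Low, Moderate, High, Excellent,
#'   NoData`.
#' @export
classify_re <- function(percent) {
  cls <- ifelse(
    is.na(percent), "NoData",
    ifelse(percent <= 0, "Other",
      ifelse(percent <= 50, "Low",
        ifelse(percent <= 75, "Moderate",
          ifelse(percent <= 95, "High", "Excellent")
        )
      )
    )
  )
  factor(cls, levels = RE_CLASSES_ALL)
}

#' Select and compute the removal efficiency for each record
#'
#' Per-record precedence: the RE reported by the source, if any; else the
#' sludge mass balance when all five of its parameters are present; else
#' the simple influent/effluent ratio on median concentrations (means are
#' used only when no median is available); else no data. Censored
#' influent or effluent concentrations yield `NoData` under the default
#' policy; the alternative `"formation"` policy maps a censored influent
#' with a detected effluent to RE `Other` (apparent in-plant formation).
#'
#' @param records tibble of curated records with columns `reported_re`,
#'   `ci`, `ce`, `cs`, `f`, `tsp`, `c_infl`, `c_infl_censored`,
#'   `c_infl_stat`, `c_effl`, `c_effl_censored`, `c_effl_stat` (missing
#'   columns are treated as all-`NA`).
#' @param censoring_policy `"nodata"` (default) or `"formation"`.
#' @return The input tibble with added columns `re_percent`, `re_method`
#'   (`reported`, `eq2`, `eq1` or `none`) and `re_class`.
#' @export
select_re <- function(records, censoring_policy = c("nodata", "formation")) {
  censoring_policy <- match.arg(censoring_policy)
  n <- nrow(records)
  col <- function(nm, default = NA_real_) {
    if (nm %in% names(records)) records[[nm]] else rep(default, n)
  }
  reported <- as.numeric(col("reported_re"))
  mb <- re_mass_balance(
    as.numeric(col("ci")), as.numeric(col("ce")), as.numeric(col("cs")),
    as.numeric(col("f")), as.numeric(col("tsp"))
  )
  infl_cens <- isTRUE_vec(col("c_infl_censored", FALSE))
  effl_cens <- isTRUE_vec(col("c_effl_censored", FALSE))
  c_infl <- as.numeric(col("c_infl"))
  c_effl <- as.numeric(col("c_effl"))
  simple <- re_simple(c_infl, c_effl)
  simple[infl_cens | effl_cens] <- NA_real_

  percent <- reported
  method <- ifelse(!is.na(reported), "reported", NA_character_)
  use_mb <- is.na(percent) & !is.na(mb)
  percent[use_mb] <- mb[use_mb]
  method[use_mb] <- "eq2"
  use_simple <- is.na(percent) & !is.na(simple)
  percent[use_simple] <- simple[use_simple]
  method[use_simple] <- "eq1"
  method[is.na(method)] <- "none"

  cls <- classify_re(percent)
  if (censoring_policy == "formation") {
    formed <- method == "none" & infl_cens & !effl_cens & !is.na(c_effl)
    cls[formed] <- "Other"
  }
  records$re_percent <- percent
  records$re_method <- method
  records$re_class <- cls
  records
}

# internal: coerce a logical-ish column (TRUE/FALSE/NA/0/1) to logical,
# treating NA as FALSE
isTRUE_vec <- function(x) {
  x <- as.logical(x)
  !is.na(x) & x
}

#' Worst-case consensus over a multiset of RE classes
#'
#' The modal (most represented) class wins. `NoData` records are set
#' aside whenever any quantified class is present, so the most populated
#' quantified class is used (if `NoData` itself were modal, the next
#' most populated class takes over). Ties among modal classes resolve to
#' the worst class under the ordering
#' Other < Low < Moderate < High < Excellent. All classes `NoData` (or
#' only `NoData` present) gives consensus `NoData`.
#'
#' @param classes character or factor vector of RE classes (at least one).
#' @return A list with `consensus_class` (single character),
#'   `class_counts` (named integer vector over all six classes) and
#'   `tie_broken` (TRUE when the worst-case tie rule decided).
#' @examples
#' consensus_re(c("Low", "Other"))               # Other (worst-case tie)
#' consensus_re(c("High", "High", "High"))       # High
#' consensus_re(c("NoData", "NoData", "NoData", "Low", "Low", "Moderate")) # Low
#' @export
consensus_re <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) == 0) stop("consensus_re() needs at least one class", call. = FALSE)
  bad <- setdiff(unique(classes), RE_CLASSES_ALL)
  if (length(bad) > 0) stop("unknown RE class: ", paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(classes, levels = RE_CLASSES_ALL))
  quant <- counts[RE_CLASSES]
  if (sum(quant) == 0) {
    return(list(
      consensus_class = "NoData",
      class_counts = as_count_vec(counts), tie_broken = FALSE
    ))
  }
  modal <- names(quant)[quant == max(quant)]
  # RE_CLASSES is ordered worst-to-best, so the first modal entry is worst
  list(
    consensus_class = modal[1],
    class_counts = as_count_vec(counts),
    tie_broken = length(modal) > 1
  )
}

as_count_vec <- function(tab) {
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Per-chemical consensus RE classes by plant type
#'
#' Applies [consensus_re()] separately within each chemical x plant-type
#' pool of record classes.
#'
#' @param re_records tibble with columns `chemical` (or `cas`),
#'   `wwtp_type` and `re_class` (as produced by [select_re()]).
#' @return A tibble with one row per chemical x plant type: `chemical`,
#'   `wwtp_type`, `n_records`, `consensus_class`, `tie_broken`,
#'   `resistant` (consensus in \{Low, Other\}) and `class_counts`
#'   (list-column of named counts).
#' @export
consensus_by_chemical <- function(re_records) {
  id_col <- intersect(c("chemical", "cas"), names(re_records))[1]
  if (is.na(id_col)) stop("re_records needs a `chemical` or `cas` column", call. = FALSE)
  re_records$chemical <- re_records[[id_col]]
  re_records |>
    dplyr::group_by(.data$chemical, .data$wwtp_type) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      result = list(consensus_re(.data$re_class)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      consensus_class = purrr::map_chr(.data$result, "consensus_class"),
      tie_broken = purrr::map_lgl(.data$result, "tie_broken"),
      resistant = .data$consensus_class %in% c("Low", "Other"),
      class_counts = purrr::map(.data$result, "class_counts")
    ) |>
    dplyr::select(-"result")
}
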