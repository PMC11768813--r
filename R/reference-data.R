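#' Reference screening-flag table for 16 prioritized PPCPs
#'
#' Per-chemical screening flags for the sixteen pharmaceuticals and
#' personal care products flagged as potentially PMT or PBT in a global
#' WWTP removal-efficiency survey of 245 compounds, transcribed from
#' the published per-compound flag assignments. One row per compound
#' with the joint persistence flag (`pP`), bioaccumulation (`pB`,
#' `pvB`), mobility under each threshold profile (`pM_conservative`,
#' `pvM_conservative`, `pM_eu2023`, `pvM_eu2023`), toxicity (`pT`), and
#' the published combined classification under each profile
#' (`printed_conservative`, `printed_eu2023`; empty when no label was
#' assigned under the EU 2023 mobility cut-offs).
#'
#' Feeding these flags through [combine_flags()] reproduces the
#' published classifications; the table doubles as a regression fixture
#' for the label-combination rule.
#'
#' @return A tibble with 16 rows.
#' @export
reference_screening_flags <- function() {
  path <- system.file("extdata", "screening_flags_16ppcp.csv",
    package = "ppcpscreen", mustWork = TRUE
  )
  readr::read_csv(
    path,
    col_types = readr::cols(
      compound = readr::col_character(),
      use_class = readr::col_character(),
      printed_conservative = readr::col_character(),
      printed_eu2023 = readr::col_character(),
      .default = readr::col_logical()
    ),
    progress = FALSE
  ) |>
    dplyr::mutate(dplyr::across(
      dplyr::starts_with("printed_"),
      \(x) dplyr::coalesce(x, "")
    ))
}

#' Apply the label-combination rule to a screening-flag table
#'
#' Runs [combine_flags()] row-wise over a flag table in the layout of
#' [reference_screening_flags()] and returns the label string per
#' compound under the chosen profile's mobility columns.
#'
#' @param flags tibble with columns `pP`, `pB`, `pvB`, `pT` and the
#'   profile-specific `pM_*`/`pvM_*` columns.
#' @param profile `"conservative"` or `"eu2023"`.
#' @return Character vector of label strings (e.g. `"PBT+PMT"`, `""`).
#' @export
labels_from_flags <- function(flags, profile = c("conservative", "eu2023")) {
  profile <- match.arg(profile)
  pm <- flags[[paste0("pM_", profile)]]
  pvm <- flags[[paste0("pvM_", profile)]]
  vapply(seq_len(nrow(flags)), function(i) {
    paste(
      combine_flags(
        pP = flags$pP[i], pB = flags$pB[i], pvB = flags$pvB[i],
        pM = pm[i], pvM = pvm[i], pT = flags$pT[i]
      ),
      collapse = "+"
    )
  }, character(1))
}
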