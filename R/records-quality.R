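#' Quality-index classes, in increasing order of quality
#' @keywords internal
QI_CLASSES <- c("Low", "Moderate", "Good", "Excellent")

#' Score the record-level quality index
#'
#' Each literature record carries three sub-scores on a 0--2 scale:
#' completeness of the molecular identifiers (CAS, name, SMILES), the
#' quantifiability of the removal-efficiency data, and the completeness of
#' the general plant information. Their sum (0--6) is the quality index
#' (QI), mapped onto four classes: 0--1 Low, 2--3 Moderate, 4--5 Good,
#' 6 Excellent.
#'
#' @param molecule_id_score,re_data_score,general_info_score integer
#'   vectors with values in `{0, 1, 2}`; recycled to a common length.
#' @return A tibble with columns `molecule_id_score`, `re_data_score`,
#'   `general_info_score`, `total` (0--6) and `qi_class` (ordered factor
#'   Low < Moderate < Good < Excellent).
#' @examples
#' score_quality(2, 2, 2)       # total 6, Excellent
#' score_quality(1, 1, 1)       # total 3, Moderate
#' score_quality(0:2, 1, 0)     # vectorized
#' @export
score_quality <- function(molecule_id_score, re_data_score, general_info_score) {
  scores <- vctrs_recycle(molecule_id_score, re_data_score, general_info_score)
  for (nm in names(scores)) {
    s <- scores[[nm]]
    if (!is.numeric(s) || anyNA(s) || any(s != as.integer(s)) || any(s < 0 | s > 2)) {
      stop("`", nm, "` must be an integer in {0, 1, 2}", call. = FALSE)
    }
  }
  total <- as.integer(scores[[1]] + scores[[2]] + scores[[3]])
  tibble::tibble(
    molecule_id_score = as.integer(scores[[1]]),
    re_data_score = as.integer(scores[[2]]),
    general_info_score = as.integer(scores[[3]]),
    total = total,
    qi_class = qi_class_from_total(total)
  )
}

#' Map a quality-index total onto its class
#'
#' @param total integer vector of QI totals in 0--6.
#' @return Ordered factor with levels Low < Moderate < Good < Excellent.
#' @export
qi_class_from_total <- function(total) {
  if (any(total < 0 | total > 6, na.rm = TRUE)) {
    stop("QI total must be in 0..6", call. = FALSE)
  }
  cls <- cut(total, breaks = c(-0.5, 1.5, 3.5, 5.5, 6.5), labels = QI_CLASSES)
  factor(as.character(cls), levels = QI_CLASSES, ordered = TRUE)
}

# internal: recycle named arguments to a common length, keeping names
vctrs_recycle <- function(...) {
  args <- list(...)
  names(args) <- sapply(substitute(list(...))[-1], deparse)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Filter records by quality index
#'
#' Records with QI class Low are excluded from all downstream stages;
#' chemicals whose every record is excluded disappear from the chemical
#' roster. The excluded set is retained for reporting.
#'
#' @param records A tibble with at least a `qi_class` column (as produced
#'   by [score_quality()] or [read_records()]) and, if roster tracking is
#'   wanted, a `cas` (or `chemical`) identifier column.
#' @return A list with elements `kept` (tibble), `excluded` (tibble with
#'   an added `exclusion_reason` column) and `dropped_chemicals`
#'   (character vector of identifiers present in the input but absent
#'   from `kept`).
#' @export
filter_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(list(kept = records, excluded = records, dropped_chemicals = character()))
  }
  if (!"qi_class" %in% names(records)) {
    stop("records must carry a `qi_class` column; see score_quality()", call. = FALSE)
  }
  low <- as.character(records$qi_class) == "Low"
  kept <- records[!low, , drop = FALSE]
  excluded <- records[low, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$exclusion_reason <- "QI Low"
  id_col <- intersect(c("cas", "chemical"), names(records))[1]
  dropped <- character()
  if (!is.na(id_col)) {
    dropped <- setdiff(unique(records[[id_col]]), unique(kept[[id_col]]))
  }
  list(kept = kept, excluded = excluded, dropped_chemicals = dropped)
}

#' Default keyword list signalling tertiary/advanced treatment
#'
#' Free-text technology tokens matched (case-insensitively, as
#' substrings) against a plant's reported treatment train when no clear
#' treatment level is declared.
#' @return Character vector of keywords.
#' @export
tertiary_keywords <- function() {
  c(
    "aop", "advanced oxidation", "ozon", "uv", "disinfect", "chlorin",
    "sand filtration", "activated carbon", "chemical nutrient removal",
    "reverse osmosis", "nanofiltration"
  )
}

#' Classify a plant as WWTP1 or WWTP2
#'
#' Plants are typed by treatment level: primary or secondary only ->
#' WWTP1; tertiary/advanced present -> WWTP2. When the declared level is
#' missing, the reported technology tokens are matched against a
#' configurable tertiary-keyword list: an explicit "tertiary" token or at
#' least two distinct tertiary technologies -> WWTP2; a single ambiguous
#' tertiary token with no declared level -> WWTP1 (worst case); no
#' evidence -> WWTP1.
#'
#' @param declared_level `NA` or one of `"primary"`, `"secondary"`,
#'   `"tertiary/advanced"` (a bare `"tertiary"` or `"advanced"` is also
#'   accepted).
#' @param technologies character vector of free-text technology tokens
#'   (may be empty when a level is declared).
#' @param keywords tertiary-keyword list; defaults to
#'   [tertiary_keywords()].
#' @return `"WWTP1"` or `"WWTP2"`.
#' @examples
#' classify_wwtp("secondary", character())            # WWTP1
#' classify_wwtp("tertiary/advanced", character())    # WWTP2
#' classify_wwtp(NA, c("sand filtration"))            # WWTP1 (worst case)
#' classify_wwtp(NA, c("ozonation", "uv"))            # WWTP2
#' @export
classify_wwtp <- function(declared_level, technologies = character(),
                          keywords = tertiary_keywords()) {
  techs <- tolower(trimws(technologies[!is.na(technologies) & nzchar(trimws(technologies))]))
  level <- declared_level
  if (length(level) != 1) stop("declared_level must be length 1 (possibly NA)", call. = FALSE)
  if (!is.na(level)) {
    level <- tolower(trimws(level))
    if (level %in% c("tertiary/advanced", "tertiary", "advanced")) return("WWTP2")
    if (level %in% c("primary", "secondary")) return("WWTP1")
    stop("unknown declared_level: ", declared_level, call. = FALSE)
  }
  if (length(techs) == 0) {
    stop("classify_wwtp() needs a declared level or at least one technology token",
      call. = FALSE
    )
  }
  if (any(grepl("tertiary", techs, fixed = TRUE))) return("WWTP2")
  hits <- unique(techs[vapply(
    techs,
    function(t) any(vapply(keywords, grepl, logical(1), x = t, fixed = TRUE)),
    logical(1)
  )])
  if (length(hits) >= 2) "WWTP2" else "WWTP1"
}

#' Read a literature-record table from CSV
#'
#' Expected columns: `cas`, `name`, `smiles`, `use_class`, `mw`,
#' `source_id`, `plant_id`, `continent`, `declared_level`, `technologies`
#' (semicolon-separated), the three QI sub-scores, and the concentration
#' columns consumed by the removal-efficiency stage (`c_infl`,
#' `c_infl_censored`, `c_infl_stat`, `c_effl`, `c_effl_censored`,
#' `c_effl_stat`, `ci`, `ce`, `cs`, `f`, `tsp`, `reported_re`).
#' Missing optional columns are added as `NA`.
#'
#' @param path CSV file path.
#' @return A tibble, one row per record.
#' @export
read_records <- function(path) {
  req <- c(
    "cas", "name", "source_id", "plant_id", "continent",
    "molecule_id_score", "re_data_score", "general_info_score"
  )
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(req, names(rec))
  if (length(missing) > 0) {
    stop(
      "records file ", path, " is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  opt <- c(
    "smiles", "use_class", "mw", "declared_level", "technologies",
    "c_infl", "c_infl_censored", "c_infl_stat",
    "c_effl", "c_effl_censored", "c_effl_stat",
    "ci", "ce", "cs", "f", "tsp", "reported_re"
  )
  for (col in setdiff(opt, names(rec))) rec[[col]] <- NA
  rec
}

#' Curate records: score quality, classify plants, filter QI Low
#'
#' Convenience wrapper running the whole record-curation stage on a raw
#' record table.
#'
#' @param records tibble as returned by [read_records()].
#' @param keywords tertiary-keyword list for [classify_wwtp()].
#' @return A list with `kept`, `excluded`, `dropped_chemicals` (as in
#'   [filter_records()]); `kept` and `excluded` gain `total`, `qi_class`
#'   and `wwtp_type` columns.
#' @export
curate_records <- function(records, keywords = tertiary_keywords()) {
  q <- score_quality(
    records$molecule_id_score, records$re_data_score, records$general_info_score
  )
  records$total <- q$total
  records$qi_class <- q$qi_class
  level <- if ("declared_level" %in% names(records)) records$declared_level else rep(NA, nrow(records))
  techs <- if ("technologies" %in% names(records)) records$technologies else rep(NA, nrow(records))
  records$wwtp_type <- vapply(
    seq_len(nrow(records)),
    function(i) {
      classify_wwtp(level[i], split_tokens(techs[i]), keywords = keywords)
    },
    character(1)
  )
  filter_records(records)
}

# internal: split a semicolon-separated technology field
split_tokens <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(trimws(x))) return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Summarize quality-index classes over a record set
#'
#' @param records tibble with a `qi_class` column.
#' @return A tibble with one row per QI class: `qi_class`, `n`, and
#'   `percent` of all records (full precision; round only for display).
#' @export
summarize_quality <- function(records) {
  cls <- factor(as.character(records$qi_class), levels = QI_CLASSES)
  tab <- table(cls)
  tibble::tibble(
    qi_class = names(tab),
    n = as.integer(tab),
    percent = 100 * as.integer(tab) / sum(tab)
  )
}
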