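# Reading and standardizing colony age data.
#
# Two input shapes are accepted throughout:
#   * per-individual records: one row per bat with columns
#     colony, age_years (integer, NA for unaged juveniles), and optionally
#     life_stage ("aged" / "unaged_juvenile"), sex, certainty (A/B/C), phase;
#   * pre-tabulated counts: columns age and count (optionally colony).

#' Remove records whose age could not be read reliably
#'
#' Tooth-cementum age estimates carry a certainty code: A (highest
#' certainty), B (histology supports the age to within roughly a year), or C
#' (section too compromised to age). C records are unusable and are dropped;
#' A, B and un-coded records are kept.
#'
#' @param records Tibble/data frame of per-individual records. A `certainty`
#'   column is optional; without one the input is returned unchanged.
#' @param quiet Suppress the message reporting how many records were removed.
#' @return The filtered records as a tibble, with attribute `n_removed`.
#' @export
filter_records <- function(records, quiet = FALSE) {
  records <- tibble::as_tibble(records)
  if (!"certainty" %in% names(records)) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  is_c <- !is.na(records$certainty) & toupper(records$certainty) == "C"
  out <- records[!is_c, , drop = FALSE]
  attr(out, "n_removed") <- sum(is_c)
  if (!quiet && sum(is_c) > 0) {
    rlang::inform(paste0("removed ", sum(is_c),
                         " record(s) with certainty code C"))
  }
  out
}

#' Standardize colony age structure
#'
#' Converts records to per-age observed frequencies: the proportion of
#' individuals within each age class. When a colony's captures include
#' unaged juveniles (0-year animals not submitted for tooth sectioning, a
#' known capture bias), the 0-year class is set to the observed proportion
#' `p` of such captures and the tooth-aged classes are rescaled to total
#' `1 - p`.
#'
#' @param records Per-individual records or pre-tabulated `age`/`count` rows
#'   (see package overview). Certainty-C records, if still present, are
#'   dropped with a warning.
#' @param zero_class_proportion Observed proportion of unaged 0-year
#'   individuals among all captures, in `[0, 1)`. Default `NULL`: inferred
#'   from rows flagged `life_stage == "unaged_juvenile"` (or with missing
#'   `age_years`) when such rows exist, otherwise no correction.
#' @param mode `"proportion"` (frequencies sum to 1) or `"count"`
#'   (proportions multiplied by the number of individuals represented).
#' @param by_sex Standardize separately within each sex.
#' @return Tibble with columns `colony`, `age`, `frequency`, `n_total`
#'   (and `sex` when `by_sex = TRUE`), one row per age class.
#' @export
#' @examples
#' rec <- tibble::tibble(colony = "demo",
#'                       age_years = c(rep(1, 12), rep(2, 6), rep(3, 3)))
#' standardize_ages(rec, zero_class_proportion = 0.8)
standardize_ages <- function(records, zero_class_proportion = NULL,
                             mode = c("proportion", "count"),
                             by_sex = FALSE) {
  mode <- match.arg(mode)
  records <- tibble::as_tibble(records)

  if ("age" %in% names(records) &&
      any(c("count", "frequency") %in% names(records))) {
    # pre-tabulated dialect: counts (or already-standardized frequencies)
    # act as weights, so re-standardizing proportions is a no-op
    records <- dplyr::rename(records, age_years = "age")
    records$.w <- if ("count" %in% names(records)) {
      records$count
    } else {
      records$frequency
    }
  } else if ("age_years" %in% names(records)) {
    records$.w <- 1
  } else {
    stop("records must have either an 'age_years' column or 'age'+'count' columns",
         call. = FALSE)
  }
  if (!"colony" %in% names(records)) {
    records$colony <- "colony"
  }
  if ("certainty" %in% names(records)) {
    n_c <- sum(!is.na(records$certainty) & toupper(records$certainty) == "C")
    if (n_c > 0) {
      warning("dropping ", n_c, " certainty-C record(s); ",
              "call filter_records() first to silence this", call. = FALSE)
      records <- filter_records(records, quiet = TRUE)
    }
  }

  groups <- "colony"
  if (by_sex) {
    if (!"sex" %in% names(records)) {
      stop("by_sex = TRUE requires a 'sex' column", call. = FALSE)
    }
    groups <- c("colony", "sex")
  }

  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(function(df, key) {
      standardize_one(df, zero_class_proportion, mode)
    }) |>
    dplyr::ungroup()
}

#' Standardize one colony (or colony x sex) group
#' @noRd
standardize_one <- function(df, p, mode) {
  unaged <- if ("life_stage" %in% names(df)) {
    !is.na(df$life_stage) & df$life_stage == "unaged_juvenile"
  } else {
    rep(FALSE, nrow(df))
  }
  unaged <- unaged | is.na(df$age_years)
  n_unaged <- sum(df$.w[unaged])
  n_aged <- sum(df$.w[!unaged])
  n_total <- n_unaged + n_aged
  if (n_aged <= 0) {
    stop("no usable ages", call. = FALSE)
  }
  if (is.null(p) && n_unaged > 0) {
    p <- n_unaged / n_total
  }

  aged <- df[!unaged, , drop = FALSE]
  tab <- aged |>
    dplyr::group_by(age = as.numeric(.data$age_years)) |>
    dplyr::summarise(w = sum(.data$.w), .groups = "drop") |>
    dplyr::arrange(.data$age)
  freq <- tab$w / sum(tab$w)
  ages <- tab$age

  if (!is.null(p)) {
    stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
    if (p == 1) {
      stop("zero_class_proportion = 1 is inconsistent with aged records being present",
           call. = FALSE)
    }
    has_zero <- any(ages == 0)
    if (has_zero) {
      warning("aged 0-year class present; its weight is replaced by the ",
              "observed zero-class proportion and remaining classes rescaled",
              call. = FALSE)
      keep <- ages > 0
      ages <- ages[keep]
      freq <- tab$w[keep] / sum(tab$w[keep])
    }
    ages <- c(0, ages)
    freq <- c(p, freq * (1 - p))
  }

  scale <- if (mode == "count") n_total else 1
  tibble::tibble(age = ages, frequency = freq * scale, n_total = n_total)
}

#' Read a colony data CSV
#'
#' Accepts either per-individual rows (columns `colony`, `age_years`, and
#' optionally `life_stage`, `sex`, `certainty`, `phase`) or pre-tabulated
#' rows (columns `age`, `count`, optionally `colony`). The dialect is
#' detected from the header.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return Tibble of records in the detected dialect.
#' @export
read_colony_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!("age_years" %in% names(out)) && !all(c("age", "count") %in% names(out))) {
    stop("unrecognized CSV dialect: need column 'age_years' or columns 'age' and 'count'",
         call. = FALSE)
  }
  out
}

#' Write standardized age frequencies to CSV
#'
#' @param age_frequencies Output of [standardize_ages()].
#' @param path Destination file.
#' @return The input, invisibly.
#' @export
write_age_frequencies <- function(age_frequencies, path) {
  readr::write_csv(age_frequencies, path)
  invisible(age_frequencies)
}
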