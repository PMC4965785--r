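#' Rank candidate models by DIC and apply the 2-unit rule
#'
#' Models are sorted by ascending DIC. The lowest-DIC model is flagged
#' `supported` only when it beats every other model by more than 2 DIC
#' units. Otherwise no model is decisively supported and the *working* model
#' is the most parsimonious one (fewest hazard parameters, ties broken by
#' lower DIC) among those within 2 units of the minimum — echoing the common
#' practice of retaining the constant-risk model for simplicity when richer
#' models gain little.
#'
#' @param fits Either a named list of `siler_fit` objects on the same data
#'   (as from [fit_siler_models()]), or a data frame with columns `model`
#'   and `dic` (e.g. published DIC values).
#' @return Tibble with one row per model: `model`, `n_hazard_params`, `dic`,
#'   `delta_dic`, `rank`, `supported` (TRUE only for a decisively best
#'   model), `working` (TRUE for the model retained for downstream use).
#' @export
#' @examples
#' dics <- tibble::tibble(
#'   model = c("constant", "maturation", "senescence",
#'             "maturation_senescence", "siler"),
#'   dic = c(93.88, 94.81, 94.81, 94.88, 95.29))
#' select_model(dics)
select_model <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- tibble::as_tibble(fits)
    if (!all(c("model", "dic") %in% names(tab))) {
      stop("data-frame input needs columns 'model' and 'dic'", call. = FALSE)
    }
    tab$model <- vapply(unname(tab$model), match_model, character(1),
                        USE.NAMES = FALSE)
  } else {
    stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1), "siler_fit")))
    if (length(fits) >= 2) {
      datasets <- lapply(fits, function(f) f$data[c("age", "frequency")])
      same <- vapply(datasets[-1], identical, logical(1), datasets[[1]])
      if (!all(same)) {
        stop("all fits must be on the same data", call. = FALSE)
      }
    }
    tab <- dplyr::bind_rows(lapply(fits, glance))[, c("model", "dic")]
  }
  if (nrow(tab) < 2) {
    stop("need at least two fitted models to compare", call. = FALSE)
  }
  if (anyDuplicated(tab$model)) {
    stop("duplicate models in comparison", call. = FALSE)
  }

  tab$n_hazard_params <- vapply(tab$model, n_hazard_params, integer(1))
  tab <- dplyr::arrange(tab, .data$dic)
  tab$delta_dic <- tab$dic - tab$dic[1]
  tab$rank <- seq_len(nrow(tab))
  tab$supported <- FALSE
  tab$supported[1] <- tab$delta_dic[2] > 2

  within2 <- which(tab$delta_dic <= 2)
  working <- within2[order(tab$n_hazard_params[within2], tab$dic[within2])][1]
  tab$working <- seq_len(nrow(tab)) == working
  tab[, c("model", "n_hazard_params", "dic", "delta_dic", "rank",
          "supported", "working")]
}
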