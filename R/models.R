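# Registry of the five candidate survivorship models. Component names follow
# the usual Siler decomposition: a declining Gompertz hazard acting early in
# life ("maturing"), an age-independent exponential hazard ("constant"), and
# an increasing Gompertz hazard late in life ("senescing").

.siler_model_registry <- list(
  constant              = "constant",
  maturation            = c("maturing", "constant"),
  senescence            = c("constant", "senescing"),
  maturation_senescence = c("maturing", "senescing"),
  siler                 = c("maturing", "constant", "senescing")
)

.component_params <- list(
  maturing  = c("a1", "b1"),
  constant  = "a2",
  senescing = c("a3", "b3")
)

#' Names of the candidate survivorship models
#'
#' The five nested models are `"constant"` (exponential survivorship only),
#' `"maturation"` (declining juvenile hazard plus constant hazard),
#' `"senescence"` (constant plus increasing late-life hazard),
#' `"maturation_senescence"` (declining and increasing hazards, no constant
#' term) and `"siler"` (all three components).
#'
#' @return Character vector of model names.
#' @export
#' @examples
#' siler_models()
siler_models <- function() {
  names(.siler_model_registry)
}

#' Match a model name against the registry, tolerating common spellings
#' @noRd
match_model <- function(model) {
  stopifnot(is.character(model), length(model) == 1L)
  key <- gsub("[-/ ]", "_", tolower(trimws(model)))
  if (key %in% c("maturation_senescence", "mat_sen", "both", "maturation_senescence_only")) {
    key <- "maturation_senescence"
  }
  if (!key %in% names(.siler_model_registry)) {
    stop("unknown model '", model, "'; choose one of: ",
         paste(siler_models(), collapse = ", "), call. = FALSE)
  }
  key
}

#' Hazard components included in a model
#'
#' @param model Model name, one of [siler_models()].
#' @return Character vector, a subset of `c("maturing", "constant",
#'   "senescing")`.
#' @export
#' @examples
#' model_components("maturation_senescence")
model_components <- function(model) {
  .siler_model_registry[[match_model(model)]]
}

#' Hazard parameters active in a model
#'
#' @inheritParams model_components
#' @return Character vector drawn from `c("a1", "b1", "a2", "a3", "b3")`.
#' @export
model_hazard_params <- function(model) {
  comps <- model_components(model)
  unlist(.component_params[comps], use.names = FALSE)
}

# All parameters sampled when fitting: hazard parameters plus the frequency
# amplitude and the residual standard deviation.
active_params <- function(model) {
  c(model_hazard_params(model), "a", "sigma")
}

n_hazard_params <- function(model) {
  length(model_hazard_params(model))
}
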