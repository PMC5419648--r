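#' Shipped population-model presets
#'
#' Three gentamicin population models are shipped as JSON preset files:
#' `"icu"` (intensive-care patients, high volume of distribution),
#' `"standard"` (general-ward patients) and `"endocarditis"` (metabolic
#' clearance fixed at 0.277 L/h/70 kg, renal fraction 0.698 +/- 0.358,
#' Vd 0.312 +/- 0.076 L/kg LBMc). Units: CLm in L/h per 70 kg body weight,
#' fr as a fraction of creatinine clearance, Vd in L per kg corrected lean
#' body mass.
#'
#' @param name `"icu"`, `"standard"` or `"endocarditis"`
#' @return a [population_model()]
#' @export
#' @examples
#' model_preset("endocarditis")
model_preset <- function(name = c("icu", "standard", "endocarditis")) {
  name <- match.arg(name)
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "gentapk", mustWork = TRUE)
  read_model_json(path)
}

#' Read a population model from a JSON preset file
#'
#' The schema has a `parameters` object with `CLm`, `fr`, `Vd` entries, each
#' `{mean, sd, setting}`, plus `assay_error_coeffs` `(a0, a1, a2)` and an
#' optional `name`.
#'
#' @param path JSON file path
#' @return a [population_model()]
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- j$parameters
  need <- c("CLm", "fr", "Vd")
  if (!all(need %in% names(p))) {
    stop("model preset must define parameters CLm, fr and Vd")
  }
  population_model(
    clm = param_spec("CLm", p$CLm$mean, p$CLm$sd, p$CLm$setting),
    fr = param_spec("fr", p$fr$mean, p$fr$sd, p$fr$setting),
    vd = param_spec("Vd", p$Vd$mean, p$Vd$sd, p$Vd$setting),
    assay_error_coeffs = j$assay_error_coeffs,
    name = if (!is.null(j$name)) j$name else "custom"
  )
}

#' Write a population model to a JSON preset file
#'
#' Inverse of [read_model_json()]; numbers are serialized at full precision
#' so a read/write round trip is exact.
#'
#' @param model a [population_model()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model_json <- function(model, path) {
  tab <- model_param_table(model)
  j <- list(
    name = model$name,
    parameters = stats::setNames(lapply(seq_len(3), function(i) {
      list(mean = tab$mean[i], sd = tab$sd[i], setting = tab$setting[i])
    }), tab$name),
    units = list(CLm = "L/h/70kgBW", fr = "fraction of CLcr",
                 Vd = "L/kgLBMc"),
    assay_error_coeffs = model$assay_error_coeffs
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
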