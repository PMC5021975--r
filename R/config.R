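# YAML/JSON configuration for simulations, mirroring the spec constructors'
# field names, so a study is reproducible from a single config + seed.

#' Read a simulation configuration
#'
#' The file (YAML; JSON is a subset) mirrors the [population_spec()] and
#' [effect_spec()] argument names:
#'
#' ```yaml
#' population:
#'   n_patients: 100000
#'   birth_month_probs: [0.0833, ...]   # optional, uniform if omitted
#'   birth_year_range: [1926, 2000]
#'   demographic_specs:
#'     - name: sex
#'       labels: [female, male]
#'       probs: [0.55, 0.45]
#' effects:
#'   - condition_code: COND001
#'     prevalence_p0: 0.05
#'     amplitude_A: 0.10
#'     peak_month_phi: 1
#' null_conditions: 40
#' ```
#'
#' @param path Path to the YAML config.
#' @return List with `population` (a `population_spec`), `effects` (list of
#'   `effect_spec`) and `null_conditions`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$population)) stopf("config '%s' lacks a 'population' block",
                                     path)
  pop_args <- cfg$population
  if (!is.null(pop_args$birth_month_probs)) {
    pop_args$birth_month_probs <- as.numeric(pop_args$birth_month_probs)
  }
  if (!is.null(pop_args$birth_year_range)) {
    pop_args$birth_year_range <- as.integer(pop_args$birth_year_range)
  }
  pop <- do.call(population_spec, pop_args)
  effects <- lapply(cfg$effects %||% list(), function(e) {
    if (!is.null(e$custom_curve)) e$custom_curve <- as.numeric(e$custom_curve)
    do.call(effect_spec, e)
  })
  list(population = pop, effects = effects,
       null_conditions = as.integer(cfg$null_conditions %||% 0L))
}
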