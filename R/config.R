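#' Read a run configuration file
#'
#' Run-level settings live in a YAML (or JSON) file rather than in code:
#' sampler controls (`chains`, `warmup`, `sampling`, `seed`, `target_accept`,
#' `path_length`, `init`), ODE solver controls (`rtol`, `atol`,
#' `max_num_step`), prior specifications (`priors: {name: {family, pars}}`)
#' and allometric constants (`e_cl`, `e_v`, `ref_weight`).  Missing keys take
#' the package defaults.
#'
#' @param path path to a YAML/JSON configuration file.
#' @return a named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(chains = 4L, warmup = 1000L, sampling = 1000L, seed = 1L,
                   target_accept = 0.8, path_length = 1.5, init = "prior",
                   rtol = 1e-6, atol = 1e-6, max_num_step = 100000L,
                   e_cl = 0.75, e_v = 1, ref_weight = 70,
                   truth = list(CL = 10, Q = 15, Vcent = 35, Vperi = 105,
                                ka = 2, sigma = 0.2))
  utils::modifyList(defaults, cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list from [read_run_config()].
#' @export
ode_settings_from_config <- function(cfg) {
  ode_settings(rtol = cfg$rtol, atol = cfg$atol,
               max_num_step = cfg$max_num_step)
}

#' @rdname read_run_config
#' @param model passed to [default_pk_priors()] when the config has no
#'   `priors` block.
#' @export
priors_from_config <- function(cfg, model = "twocpt") {
  if (is.null(cfg$priors)) return(default_pk_priors(model))
  lapply(cfg$priors, function(p)
    list(family = p$family, pars = as.numeric(unlist(p$pars))))
}
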