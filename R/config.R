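# YAML run-configuration interface for scripted use.

#' Read a loop configuration from YAML
#'
#' Recognised top-level keys mirror the [loop_config()] arguments
#' (`n_iterations`, `batch_q`, `n_blocks`, `grid_res`, `seed`), plus nested
#' `space:` (`glucose: [lo, hi]`, `nh4cl: [lo, hi]`), `surface:`
#' ([surface_spec()] fields `peak`, `peak_relative_height`, `widths`,
#' `baseline`) and `noise:` ([noise_spec()] fields). Missing keys keep the
#' package defaults.
#'
#' @param path YAML file path.
#' @return a [loop_config()].
#' @export
loop_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  space <- if (!is.null(y$space)) {
    design_space(glucose = as.numeric(y$space$glucose %||% c(0.1, 2.0)),
                 nh4cl = as.numeric(y$space$nh4cl %||% c(5, 120)))
  } else design_space()
  surf <- if (!is.null(y$surface)) {
    surface_spec(peak = as.numeric(y$surface$peak %||% c(0.8, 50)),
                 peak_relative_height = y$surface$peak_relative_height %||% 2.6,
                 widths = as.numeric(y$surface$widths %||% c(0.35, 30)),
                 baseline = as.numeric(y$surface$baseline %||% c(0.4, 18.7)))
  } else surface_spec()
  noi <- if (!is.null(y$noise)) {
    do.call(noise_spec, y$noise)
  } else noise_spec()
  loop_config(n_iterations = y$n_iterations %||% 3,
              batch_q = y$batch_q %||% 7,
              n_blocks = y$n_blocks %||% 6,
              grid_res = y$grid_res %||% 101,
              seed = y$seed %||% 1,
              space = space, titre_spec = surf, noise = noi)
}
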