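# YAML configuration interface for command-line driven runs.

#' Read a simulation configuration from YAML
#'
#' Maps a YAML document onto [simulation_config()]. Recognised blocks:
#' `domain:` (`h`, `L`), `cells:` (`count`, `shape`, `hct`, `condition`),
#' `adhesion:` (preset name or explicit parameters), `aggregation:`
#' (`enabled`, `De`, `beta`, `r0`, `cutoff`), `macrophages:` (list of
#' `{x, radius}` or `count`/`radius`), `velocity:` (number or `{time: [...],
#' v: [...]}`), `seed`, `time_scaling`, and `constants:` overrides.
#'
#' @param path YAML file.
#' @param seed optional seed override.
#' @return a [simulation_config()].
#' @export
read_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  cells <- y$cells %||% list()
  adh <- y$adhesion
  if (is.list(adh) && !is.null(adh$preset)) adh <- adh$preset
  if (is.list(adh)) adh <- do.call(adhesion_params, adh)
  agg <- y$aggregation
  if (!is.null(agg)) {
    agg <- aggregation_params(
      De = agg$De %||% aggregation_params()$De,
      beta = agg$beta %||% 3.9, r0 = agg$r0 %||% 0.3,
      cutoff = agg$cutoff %||% 1.2,
      enabled = isTRUE(agg$enabled))
  }
  macs <- y$macrophages
  n_macs <- 2L
  mac_radius <- 9
  mac_df <- NULL
  if (!is.null(macs)) {
    if (!is.null(macs$count)) {
      n_macs <- macs$count
      mac_radius <- macs$radius %||% 9
    } else {
      mac_df <- do.call(rbind, lapply(macs, function(m)
        data.frame(x = m$x, radius = m$radius)))
    }
  }
  vel <- y$velocity %||% 150
  if (is.list(vel)) vel <- data.frame(time = unlist(vel$time),
                                      v = unlist(vel$v))
  simulation_config(
    n_cells = cells$count %||% 12L,
    shape = cells$shape %||% "biconcave",
    hct = cells$hct %||% 0.02,
    condition = cells$condition %||% "sickle_hypoxia",
    adhesion = adh, aggregation = agg,
    macrophages = mac_df, n_macs = n_macs, mac_radius = mac_radius,
    h = y$domain$h %||% 20, L = y$domain$L,
    velocity = vel, seed = seed %||% y$seed %||% 1L,
    time_scaling = y$time_scaling %||% 1,
    constants = y$constants %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
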