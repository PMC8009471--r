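#' Read step-end observations from CSV
#'
#' Expects columns `power_mW`, `t_s`, `dT_K`, `se_K`; powers are converted to
#' watts internally.
#'
#' @param path CSV file path.
#' @return A data frame with columns `power` (W), `t_obs` (s),
#'   `delta_T_mean` (K), `delta_T_se` (K).
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path)
  req <- c("power_mW", "t_s", "dT_K", "se_K")
  if (!all(req %in% names(df)))
    stop("observation CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  validate_observations(data.frame(
    power = df$power_mW * 1e-3,
    t_obs = df$t_s,
    delta_T_mean = df$dT_K,
    delta_T_se = df$se_K
  ))
}

#' Write step-end observations to CSV
#'
#' Inverse of [read_observations()] (powers written in mW).
#'
#' @param observations Observation data frame (internal units).
#' @param path Output CSV file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  observations <- validate_observations(observations)
  utils::write.csv(data.frame(
    power_mW = 1e3 * observations$power,
    t_s = observations$t_obs,
    dT_K = observations$delta_T_mean,
    se_K = observations$delta_T_se
  ), path, row.names = FALSE)
  invisible(path)
}

#' Read a power protocol from a YAML or JSON config
#'
#' The file must contain a `segments` list, each segment with fields
#' `t_start`, `t_end` (s) and `power_mW`.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A [power_protocol()] object.
#' @export
read_protocol <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", path, call. = FALSE)
  }
  segs <- cfg$segments
  if (is.null(segs)) stop("config has no 'segments' entry", call. = FALSE)
  if (is.data.frame(segs)) {
    power_protocol(segs$t_start, segs$t_end, segs$power_mW * 1e-3)
  } else {
    power_protocol(vapply(segs, `[[`, numeric(1), "t_start"),
                   vapply(segs, `[[`, numeric(1), "t_end"),
                   vapply(segs, `[[`, numeric(1), "power_mW") * 1e-3)
  }
}
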