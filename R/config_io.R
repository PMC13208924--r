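# YAML serialization of generator configurations.

#' Write / read a generator configuration as YAML
#'
#' The file mirrors the [generator_config()] structure: a `params` mapping
#' of group -> side -> distribution parameters plus the cohort-level
#' settings. Reading validates the configuration fully before returning.
#'
#' @param config A `putatex_config`.
#' @param path YAML file path.
#' @return `write_generator_config` returns the path invisibly;
#'   `read_generator_config` the validated `putatex_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "putatex_config"))
  out <- unclass(config)
  # named atomic vectors lose names in YAML; serialize them as mappings
  for (f in c("female_counts", "age_mean", "age_sd")) {
    out[[f]] <- as.list(out[[f]])
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  needed <- c("params", "n_per_group", "female_counts", "age_mean", "age_sd")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("configuration missing field(s): ", paste(missing, collapse = ", "))
  }
  generator_config(
    params = raw$params,
    n_per_group = raw$n_per_group,
    female_counts = unlist(raw$female_counts),
    age_mean = unlist(raw$age_mean),
    age_sd = unlist(raw$age_sd),
    intensity_quantization = raw$intensity_quantization %||% 4095L,
    axes_ratio = raw$axes_ratio %||% 2.2,
    roughness = raw$roughness %||% 0.08)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
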