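#' Write a trajectory, interval, or sweep table as TSV
#'
#' Tab-separated output with '#'-prefixed metadata header lines (package
#' version plus any parameters attached to the object), '.' decimal marks,
#' and no row names — stable across runs for identical inputs.
#'
#' @param x An `accum_trajectory`, `equilibrium_interval`, `sim_record`, or
#'   plain data.frame.
#' @param path Output file path (or `""` for stdout).
#' @param meta Optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_tsv_output <- function(x, path, meta = character(0)) {
  hdr <- c(sprintf("senaccum %s",
                   as.character(utils::packageVersion("senaccum"))))
  if (inherits(x, "accum_trajectory")) {
    p <- x$params
    hdr <- c(hdr, sprintf("Ne=%g mu=%g alpha=%g x_min=%g delta=%g", p$Ne,
                          p$mu, p$alpha, p$x_min, p$delta),
             sprintf("terminated_reason=%s", x$terminated_reason))
    df <- x$steps
  } else if (inherits(x, "equilibrium_interval")) {
    p <- x$params
    hdr <- c(hdr, sprintf("Ne=%g mu=%g alpha=%g x_min=%g delta=%g", p$Ne,
                          p$mu, p$alpha, p$x_min, p$delta))
    df <- data.frame(lower = x$lower, upper = x$upper)
  } else if (inherits(x, "sim_record")) {
    hdr <- c(hdr, sprintf("seed=%d N=%d", x$config$seed, x$config$N))
    df <- x$series
  } else {
    stop_unless(is.data.frame(x), "x must be a supported object or data.frame")
    df <- x
  }
  if (length(meta)) hdr <- c(hdr, paste(names(meta), meta, sep = "="))
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  write.table(format(df, trim = TRUE, scientific = FALSE, digits = 15),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON summary of a run
#'
#' Serializes parameters plus results (trajectory steps, interval bounds, or
#' IBM fixation events and extinction time) as JSON.
#'
#' @inheritParams write_tsv_output
#' @return `path`, invisibly.
#' @export
write_json_summary <- function(x, path) {
  obj <- if (inherits(x, "accum_trajectory")) {
    list(params = unclass(x$params), steps = x$steps,
         terminated_reason = x$terminated_reason)
  } else if (inherits(x, "equilibrium_interval")) {
    list(params = unclass(x$params),
         lower = x$lower, upper = x$upper, delta = x$delta)
  } else if (inherits(x, "sim_record")) {
    list(config = unclass(x$config), fixations = x$fixations,
         extinction_time = x$extinction_time,
         final = x$series[nrow(x$series), ])
  } else {
    stop_unless(is.list(x), "x must be a supported object or list")
    x
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Parses a YAML (or JSON) configuration into a named list of parameters;
#' unknown keys are rejected against the set of allowed names.
#'
#' @param path Config file path.
#' @param allowed Character vector of allowed keys.
#' @return Named list.
#' @export
read_run_config <- function(path, allowed = NULL) {
  stop_unless(file.exists(path), sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  stop_unless(is.list(cfg), "config must be a mapping of parameter: value")
  if (!is.null(allowed)) {
    bad <- setdiff(names(cfg), allowed)
    stop_unless(length(bad) == 0,
                sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  cfg
}
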