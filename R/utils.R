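# Internal helpers: seeded RNG, child-seed fan-out, logging, flat config.

# Run expr under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a reproducible child seed from a global seed and a stage offset,
# kept inside 32-bit integer range so stages can be re-run independently.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483647)
}

#' Log a message to standard error
#'
#' Timestamped logging used by the pipeline stages and the command-line
#' wrapper. The threshold is controlled by
#' \code{options(dietRS.logLevel = )}, one of \code{"debug"},
#' \code{"info"} (default), \code{"warn"}, \code{"quiet"}.
#'
#' @param ... message parts, pasted together.
#' @param level severity of this message.
#' @return Invisibly, the formatted line (or NULL when suppressed).
#' @export
logMessage <- function(..., level = c("info", "debug", "warn")) {
  level <- match.arg(level)
  threshold <- getOption("dietRS.logLevel", "info")
  rank <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (rank[[level]] < rank[[threshold]]) return(invisible(NULL))
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(...))
  message(line)
  invisible(line)
}

#' Read a flat key-value configuration file
#'
#' YAML-style flat configuration (scalar values and simple vectors) for
#' the pipeline stages, e.g. zero-replacement fraction, CV fold count,
#' or an explicit outlier-exclusion list.
#'
#' @param path path to a YAML file.
#' @return Named list of configuration values.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a flat key-value mapping")
  cfg
}

# Format numbers with 12 significant digits for bit-stable text output.
num12 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
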