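# internal argument checks shared across modules

stop_bad_arg <- function(name, msg) {
  stop(sprintf("`%s` %s", name, msg), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad_arg(name, "must be a single finite number")
  if (strict_lower) {
    if (x <= lower) stop_bad_arg(name, sprintf("must be > %g", lower))
  } else if (x < lower) stop_bad_arg(name, sprintf("must be >= %g", lower))
  if (strict_upper) {
    if (x >= upper) stop_bad_arg(name, sprintf("must be < %g", upper))
  } else if (x > upper) stop_bad_arg(name, sprintf("must be <= %g", upper))
  x
}

check_times <- function(times, name = "times", require_zero_start = FALSE) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times))
    stop_bad_arg(name, "must be a non-empty numeric vector without NA")
  if (any(times < 0)) stop_bad_arg(name, "must be nonnegative")
  if (is.unsorted(times, strictly = TRUE))
    stop_bad_arg(name, "must be strictly increasing")
  if (require_zero_start && times[1L] != 0)
    stop_bad_arg(name, "must start at 0")
  times
}

# md5 of the canonical JSON rendering of a config, for output provenance
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}
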