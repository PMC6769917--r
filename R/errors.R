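# Classed conditions so callers (and the CLI) can map failures to exit codes:
# fac_io_error -> 2, fac_fit_error -> 3, fac_validation_error -> 4.

fac_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fac_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_io <- function(message) fac_stop(message, "fac_io_error")

stop_fit <- function(message) fac_stop(message, "fac_fit_error")

stop_validation <- function(message) fac_stop(message, "fac_validation_error")

#' Map a caught condition to the CLI exit status
#'
#' Convention used by the `facprofile` command-line script: 0 success, 2 I/O
#' errors, 3 model/fit errors, 4 validation errors, 1 anything else.
#'
#' @param cond a condition object.
#' @return integer exit status.
#' @export
fac_exit_status <- function(cond) {
  if (inherits(cond, "fac_io_error")) return(2L)
  if (inherits(cond, "fac_fit_error")) return(3L)
  if (inherits(cond, "fac_validation_error")) return(4L)
  1L
}

# One RNG stream per (seed, operation) so fixtures are independent yet
# reproducible; kept well below 2^31.
stream_seed <- function(seed, op) {
  base <- as.integer(seed) %% 1000000L
  base * 1009L + (sum(utf8ToInt(op)) %% 1009L)
}
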