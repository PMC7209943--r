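#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream.  A NULL seed runs the code on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed; stays below 2^31.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 1103L + 7919 * as.double(index)) %% 2147483629
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (5 rounds away from
#' zero), the convention used when matching reported survey percentages.
#' Base [round()] rounds halves to even, which would turn 0.125 into 0.12.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.345, 2)  # 2.35
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Condition constructors used by the pipeline driver so a wrapper script can
# map failures onto distinct exit codes.
stop_config <- function(msg) {
  stop(structure(class = c("sniffself_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_data <- function(msg) {
  stop(structure(class = c("sniffself_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
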