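#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft pnorm qnorm dnorm var sd integrate uniroot quantile
#'   rnorm median approx convolve
#' @importFrom utils read.csv write.csv head modifyList
#' @importFrom grDevices grey
#' @importFrom graphics arrows axis legend points
NULL

stop_npwmf <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_npwmf(sprintf("'%s' must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_npwmf(sprintf("'%s' must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_npwmf(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

#' Derive independent per-stream seeds from one master seed
#'
#' All randomness in the simulator flows through a single master seed; each
#' repeat scan / slice / resample draws from its own stream whose seed is
#' derived deterministically here, so partial reruns reproduce bit-identical
#' fields.
#'
#' @param master single integer master seed.
#' @param n number of streams required.
#' @return integer vector of `n` sub-seeds, all below 2^31.
#' @keywords internal
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

# trapezoidal rule on an (x, y) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
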