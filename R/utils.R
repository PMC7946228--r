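#' Four-parameter log-logistic response curve
#'
#' Evaluates \code{floor + (top - floor) / (1 + (conc / ec50)^hill)}, the
#' standard 4PL sigmoid used both for normalized viability (floor in
#' \code{[0, 1]}) and for GR dose-response curves (floor in \code{[-1, 1]}).
#'
#' @param conc concentration vector (nM, >= 0; 0 is mapped to the top asymptote)
#' @param floor lower asymptote
#' @param ec50 inflection concentration (nM, > 0)
#' @param hill slope (> 0)
#' @param top upper asymptote (default 1)
#' @return numeric vector of responses, non-increasing in \code{conc}
#' @export
four_pl <- function(conc, floor, ec50, hill, top = 1) {
  stopifnot(ec50 > 0, hill > 0)
  out <- floor + (top - floor) / (1 + (conc / ec50)^hill)
  out[conc == 0] <- top
  out
}

#' Derive a per-stream child seed from a global seed
#'
#' A single run seed fans out to independent child seeds, one per named
#' random stream, so that adding one generator to a pipeline does not shift
#' the draws of another. The mapping is a fixed polynomial hash of the
#' stream name folded into the seed; results stay below 2^31 - 1.
#'
#' @param seed integer global seed
#' @param stream character stream name
#' @return integer seed for the stream
#' @export
child_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L, nzchar(stream))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds in R's integer range
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% m
  as.integer((h + (as.numeric(seed) %% m) * 31) %% m)
}

# internal: strictly ascending numeric check (a single value passes)
.check_ascending <- function(x, what = "concentrations") {
  if (length(x) < 1L || any(diff(x) <= 0)) {
    stop(sprintf("%s must be strictly ascending", what), call. = FALSE)
  }
  invisible(TRUE)
}

# internal: stop unless all finite
.check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s must be finite", what), call. = FALSE)
  invisible(TRUE)
}
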