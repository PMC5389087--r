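# Internal helpers shared across the package.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulator calls are reproducible
#' without disturbing the caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' All pipeline randomness flows from one global seed; each stage gets a
#' deterministic 31-bit seed derived from the stage name so stages are
#' individually reproducible.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "wgac")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (k in utf8ToInt(stage)) {
    h <- (h * 31 + k) %% m
  }
  as.integer(h %% (m - 1L) + 1)
}

stop_invalid <- function(msg, ...) {
  abort(msg, class = "sdscape_invalid_spec", ...)
}

stop_placement <- function(msg, ...) {
  abort(msg, class = "sdscape_placement_error", ...)
}

stop_calibration <- function(msg, ...) {
  abort(msg, class = "sdscape_calibration_error", ...)
}

stop_undefined <- function(msg, ...) {
  abort(msg, class = "sdscape_undefined_result", ...)
}

# Named numeric vector of chromosome lengths from a DNAStringSet or a
# named numeric vector passed through.
chrom_lengths_of <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    stop_invalid("expected a DNAStringSet or a named numeric vector of chromosome lengths")
  }
}
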