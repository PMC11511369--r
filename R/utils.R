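## internal helpers

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Root mean square
#'
#' \eqn{RMS(x) = \sqrt{\frac{1}{N}\sum_i x_i^2}}.  Used both as the
#' self-noise normalization factor and inside the NSPA metric.
#'
#' @param x non-empty numeric vector.
#' @return nonnegative scalar; equals `|c|` for a constant `c`.
#' @examples
#' rms(c(3, 4))  # sqrt(12.5)
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop("rms of an empty vector is undefined")
  if (anyNA(x)) stop("rms input contains NA")
  sqrt(mean(x^2))
}

# amplitude ratio -> dB
ampDb <- function(r) 20 * log10(r)

# power ratio -> dB
powDb <- function(r) 10 * log10(r)
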