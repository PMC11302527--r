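`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive independent substream seeds from a master seed
#'
#' A single master seed is expanded into named integer seeds for the
#' independent sources of randomness in a simulation (network generation,
#' type placement, initialization, dynamics, ...), so one component can be
#' varied while the others are held fixed.
#'
#' @param master integer master seed.
#' @param n number of seeds to derive.
#' @param labels optional character labels for the seeds.
#' @return integer vector of length `n` (named if `labels` given), each in
#'   `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n, labels = NULL) {
  stopifnot(is.numeric(master), length(master) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(labels)) names(s) <- labels
  s
}

assert_scalar_num <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || (finite && !is.finite(x)))
    stop("`", name, "` must be a single finite number", call. = FALSE)
  invisible(x)
}
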