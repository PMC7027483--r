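# Internal helpers shared across modules.

#' Derive a named child seed from a master seed
#'
#' All stochastic stages draw their own substream seed from one global
#' integer seed plus a stage name, so stages are individually reproducible
#' and inserting a new stage does not shift the streams of the others.
#'
#' @param master integer master seed.
#' @param name character stage name.
#' @return an integer in \[0, 2^31).
#' @keywords internal
child_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- as.double(master) %% 2147483647
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Spatially autocorrelated Gaussian noise field
#'
#' White noise smoothed with a separable box-iterated kernel (three passes
#' approximate a Gaussian low-pass filter), then re-standardised to zero
#' mean, unit variance. `range_cells` controls the correlation length.
#'
#' @keywords internal
smooth_noise <- function(nrow, ncol, range_cells = 3) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (range_cells < 1) return(z)
  w <- 2L * as.integer(range_cells) + 1L
  k <- rep(1 / w, w)
  pad_filter <- function(m) {
    # reflective padding so edges are not biased toward zero
    p <- (w - 1L) %/% 2L
    mp <- m[c(p:1, seq_len(nrow(m)), nrow(m):(nrow(m) - p + 1L)), , drop = FALSE]
    mp <- mp[, c(p:1, seq_len(ncol(m)), ncol(m):(ncol(m) - p + 1L)), drop = FALSE]
    sm <- apply(mp, 2, function(col) as.numeric(stats::filter(col, k, sides = 2)))
    sm <- t(apply(sm, 1, function(row) as.numeric(stats::filter(row, k, sides = 2))))
    sm[p + seq_len(nrow(m)), p + seq_len(ncol(m)), drop = FALSE]
  }
  for (i in 1:3) z <- pad_filter(z)
  z <- z - mean(z)
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# kg C -> Mg CO2eq conversion applied only at reporting time
#' @keywords internal
c_to_co2eq_mg <- function(kg_c) kg_c * (44 / 12) / 1000
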