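#' Decomposition parameters for the EMD family
#'
#' @param max_imfs maximum number of intrinsic mode functions to extract
#'   (default 13).
#' @param max_sift_iter cap on sifting iterations per mode.
#' @param sd_stop Cauchy stopping threshold for sifting: iteration stops when
#'   `sum((h_prev - h)^2) / sum(h_prev^2)` falls below it.
#' @param ensemble_size number of noise realizations N for the ensemble
#'   variants.
#' @param noise_strength relative noise amplitude epsilon (fraction of the
#'   signal's standard deviation).
#' @param seed integer seed for the ensemble noise streams.
#' @param variant one of `"EMD"`, `"EEMD"`, `"CEEMD"`, `"CEEMDAN"`,
#'   `"ICEEMDAN"`.
#' @return An object of class `decomp_params`.
#' @export
decomp_params <- function(max_imfs = 13, max_sift_iter = 100, sd_stop = 0.2,
                          ensemble_size = 100, noise_strength = 0.2,
                          seed = 1L, variant = "ICEEMDAN") {
  variant <- match.arg(toupper(variant),
                       c("EMD", "EEMD", "CEEMD", "CEEMDAN", "ICEEMDAN"))
  if (max_imfs < 1) stop("invalid params: max_imfs must be >= 1", call. = FALSE)
  if (ensemble_size < 1) stop("invalid params: ensemble_size must be >= 1",
                              call. = FALSE)
  if (noise_strength < 0) stop("invalid params: noise_strength must be >= 0",
                               call. = FALSE)
  structure(list(max_imfs = as.integer(max_imfs),
                 max_sift_iter = as.integer(max_sift_iter),
                 sd_stop = sd_stop,
                 ensemble_size = as.integer(ensemble_size),
                 noise_strength = noise_strength,
                 seed = as.integer(seed), variant = variant),
            class = "decomp_params")
}

imf_set <- function(imfs, residual, method, params) {
  structure(list(imfs = imfs, residual = residual,
                 method = method, params = params),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %s: %d IMFs + residual, n = %d\n",
              x$method, length(x$imfs), length(x$residual)))
  invisible(x)
}

#' Reconstruct the signal from an IMF set
#'
#' @param x an `imf_set`.
#' @return The sum of all IMFs and the residual.
#' @export
reconstruct <- function(x) {
  out <- x$residual
  for (imf in x$imfs) out <- out + imf
  out
}

degenerate_error <- function() {
  stop(structure(class = c("degenerate_signal", "error", "condition"),
                 list(message = "too few extrema for envelope interpolation",
                      call = NULL)))
}

#' Locate strict local extrema
#'
#' Finds interior local maxima and minima; runs of equal values (plateaus)
#' bounded by a rise and a fall count as a single extremum at the plateau's
#' midpoint (floor convention).
#'
#' @param samples numeric vector, length >= 3.
#' @return A list with integer index vectors `maxima` and `minima`.
#' @export
find_extrema <- function(samples) {
  n <- length(samples)
  stopifnot(n >= 3)
  s <- sign(diff(samples))
  if (!any(s == 0)) {
    ds <- diff(s)
    return(list(maxima = which(ds == -2) + 1L, minima = which(ds == 2) + 1L))
  }
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nz <- which(r$values != 0)
  if (length(nz) < 2)
    return(list(maxima = integer(0), minima = integer(0)))
  p <- nz[-length(nz)]
  q <- nz[-1]
  ## extremum spans x[ends[p]+1 .. starts[q]]; midpoint by floor
  pos <- (ends[p] + 1L + starts[q]) %/% 2L
  list(maxima = pos[r$values[p] == 1 & r$values[q] == -1],
       minima = pos[r$values[p] == -1 & r$values[q] == 1])
}

## Natural cubic spline envelope through extrema, with each end mirrored by
## two extrema about the signal boundary to curb envelope end-swing.
spline_envelope <- function(idx, vals, n) {
  k <- min(2L, length(idx))
  li <- 2L - rev(idx[seq_len(k)])                       # mirrored left
  lv <- rev(vals[seq_len(k)])
  m <- length(idx)
  ri <- 2L * n - rev(idx[(m - k + 1L):m])
  rv <- rev(vals[(m - k + 1L):m])
  stats::spline(x = c(li, idx, ri), y = c(lv, vals, rv),
                xout = seq_len(n), method = "natural")$y
}

#' Local mean via spline envelopes
#'
#' The mean of the upper envelope (natural cubic spline through the local
#' maxima) and the lower envelope (through the local minima), after mirror
#' boundary extension. This is the averaging operator at the heart of sifting
#' and of the stagewise ensemble decompositions.
#'
#' @param samples numeric vector.
#' @return Numeric vector of the same length. Throws a `degenerate_signal`
#'   error when fewer than 2 maxima or 2 minima exist.
#' @export
local_mean <- function(samples) {
  n <- length(samples)
  if (n < 3) degenerate_error()
  ex <- find_extrema(samples)
  if (length(ex$maxima) < 2 || length(ex$minima) < 2) degenerate_error()
  upper <- spline_envelope(ex$maxima, samples[ex$maxima], n)
  lower <- spline_envelope(ex$minima, samples[ex$minima], n)
  (upper + lower) / 2
}

zero_crossings <- function(x) {
  s <- sign(x)
  s[s == 0] <- 1
  sum(diff(s) != 0)
}

## The defining property of an intrinsic mode function: the numbers of
## extrema and zero crossings differ by at most one.
is_imf <- function(x) {
  ex <- find_extrema(x)
  abs(length(ex$maxima) + length(ex$minima) - zero_crossings(x)) <= 1
}

#' Extract one IMF by sifting
#'
#' Iterates `h <- h - local_mean(h)` until both the Cauchy criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < sd_stop` and the IMF property
#' (extrema and zero-crossing counts differing by at most one) hold, or
#' `max_sift_iter` is reached. A signal whose local mean is already
#' negligible (e.g. a pure sinusoid) is returned nearly unchanged after a
#' single pass.
#'
#' @param samples numeric vector.
#' @param params a [decomp_params()].
#' @return The intrinsic mode function as a numeric vector.
#' @export
sift <- function(samples, params = decomp_params()) {
  h <- samples
  for (it in seq_len(params$max_sift_iter)) {
    m <- if (it == 1) {
      local_mean(h)                        # degenerate input propagates
    } else {
      tryCatch(local_mean(h), degenerate_signal = function(e) NULL)
    }
    if (is.null(m)) break
    denom <- sum(h^2)
    h <- h - m
    if (denom > 0 && sum(m^2) / denom < params$sd_stop && is_imf(h)) break
  }
  h
}

n_extrema <- function(x) {
  if (length(x) < 3) return(0L)
  ex <- find_extrema(x)
  length(ex$maxima) + length(ex$minima)
}

#' Empirical mode decomposition
#'
#' Classical EMD: repeatedly sift the running residual until it is degenerate
#' (fewer than 3 extrema) or `max_imfs` modes have been extracted. The sum of
#' all IMFs plus the final residual reproduces the input exactly (telescoping).
#'
#' @param samples numeric vector.
#' @param params a [decomp_params()].
#' @return An `imf_set`.
#' @export
emd <- function(samples, params = decomp_params()) {
  stopifnot(length(samples) > 0, all(is.finite(samples)))
  r <- samples
  imfs <- list()
  while (length(imfs) < params$max_imfs && n_extrema(r) >= 3) {
    imf <- tryCatch(sift(r, params), degenerate_signal = function(e) NULL)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1L]] <- imf
    r <- r - imf
  }
  imf_set(imfs, r, "EMD", params)
}
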