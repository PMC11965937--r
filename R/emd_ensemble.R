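## Noise machinery shared by the ensemble decompositions. Realizations are
## drawn once per decomposition from params$seed and reused across stages, so
## E_k(w_i) always refers to the k-th EMD mode of the same realization.

draw_noise <- function(n, N, seed) {
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  matrix(stats::rnorm(n * N), nrow = n, ncol = N)
}

## k-th EMD mode of each stored noise realization (zero vector when a
## realization has fewer than k modes).
noise_mode_bank <- function(W, params) {
  lapply(seq_len(ncol(W)), function(i) emd(W[, i], params)$imfs)
}

bank_mode <- function(bank, i, k, n) {
  if (k <= length(bank[[i]])) bank[[i]][[k]] else numeric(n)
}

## Local-mean operator used by the stagewise variants: the residue after
## removing one fully sifted mode. Returns NULL on degenerate input.
sift_residue <- function(z, params) {
  tryCatch(z - sift(z, params), degenerate_signal = function(e) NULL)
}

first_mode <- function(z, params) {
  tryCatch(sift(z, params), degenerate_signal = function(e) NULL)
}

#' Noise-assisted ensemble decompositions: EEMD, CEEMD, CEEMDAN
#'
#' * **EEMD** decomposes `N` noisy copies `x + eps * sd(x) * w_i` by plain EMD
#'   and averages mode-by-mode; the residual is the average of the
#'   per-realization residuals, so the reconstruction error shrinks as
#'   `1/sqrt(N)`.
#' * **CEEMD** does the same with complementary noise pairs `+w_i` / `-w_i`,
#'   cancelling the added noise in the mean.
#' * **CEEMDAN** extracts modes stagewise: at each stage the matching EMD mode
#'   of the stored noise realizations is added to the current residual, the
#'   first sifted mode of each perturbed residual is averaged, and the
#'   average is subtracted before the next stage (reconstruction is exact by
#'   telescoping).
#'
#' With `noise_strength = 0` every variant degenerates to plain EMD and the
#' output equals [emd()] exactly.
#'
#' @param samples numeric vector.
#' @param params a [decomp_params()] with `variant` one of `"EEMD"`,
#'   `"CEEMD"`, `"CEEMDAN"`.
#' @return An `imf_set`.
#' @export
ensemble_emd <- function(samples, params = decomp_params(variant = "EEMD")) {
  if (!params$variant %in% c("EEMD", "CEEMD", "CEEMDAN"))
    stop("invalid params: variant must be EEMD, CEEMD or CEEMDAN", call. = FALSE)
  stopifnot(all(is.finite(samples)))
  if (params$noise_strength == 0) {
    out <- emd(samples, params)
    out$method <- params$variant
    return(out)
  }
  n <- length(samples)
  W <- draw_noise(n, params$ensemble_size, params$seed)
  out <- switch(params$variant,
    EEMD = eemd_average(samples, W, params, paired = FALSE),
    CEEMD = eemd_average(samples, W, params, paired = TRUE),
    CEEMDAN = ceemdan_stagewise(samples, W, params)
  )
  out$method <- params$variant
  out
}

eemd_average <- function(x, W, params, paired) {
  eps <- params$noise_strength * stats::sd(x)
  noises <- lapply(seq_len(ncol(W)), function(i) W[, i])
  if (paired) noises <- c(noises, lapply(noises, function(w) -w))
  decomps <- lapply(noises, function(w) emd(x + eps * w, params))
  K <- max(vapply(decomps, function(d) length(d$imfs), integer(1)))
  n <- length(x)
  imfs <- lapply(seq_len(K), function(k) {
    acc <- numeric(n)
    for (d in decomps) if (k <= length(d$imfs)) acc <- acc + d$imfs[[k]]
    acc / length(decomps)
  })
  residual <- Reduce(`+`, lapply(decomps, `[[`, "residual")) / length(decomps)
  imf_set(imfs, residual, params$variant, params)
}

ceemdan_stagewise <- function(x, W, params) {
  n <- length(x)
  N <- ncol(W)
  bank <- noise_mode_bank(W, params)
  eps <- params$noise_strength
  imfs <- list()
  r <- x
  ## stage 1 perturbs with the raw noise; later stages with its k-th EMD mode
  repeat {
    if (length(imfs) >= params$max_imfs || n_extrema(r) < 3) break
    k <- length(imfs) + 1L
    beta <- eps * stats::sd(r)
    acc <- numeric(n)
    used <- 0L
    for (i in seq_len(N)) {
      pert <- if (k == 1) W[, i] else bank_mode(bank, i, k - 1L, n)
      m <- first_mode(r + beta * pert, params)
      if (!is.null(m)) {
        acc <- acc + m
        used <- used + 1L
      }
    }
    if (used == 0L) break
    ck <- acc / used
    imfs[[k]] <- ck
    r <- r - ck
  }
  imf_set(imfs, r, "CEEMDAN", params)
}

#' Improved CEEMDAN (ICEEMDAN)
#'
#' Stagewise ensemble decomposition with adaptive noise. Stage 1 perturbs the
#' signal with the *first EMD mode* of each stored white-noise realization,
#' scaled so the perturbation is `noise_strength` times the signal's standard
#' deviation; the first residual is the ensemble average of the local-mean
#' operator applied to the perturbed copies, and the first IMF is the signal
#' minus that residual. Each later stage perturbs the running residual with
#' the matching higher-order noise mode, scaled by `noise_strength` times the
#' residual's standard deviation. Because every IMF is the difference of
#' consecutive residuals, reconstruction is exact for any ensemble size or
#' noise strength.
#'
#' The local-mean operator is the residue left after removing one fully
#' sifted mode, so with `noise_strength = 0` the recursion reproduces plain
#' EMD exactly.
#'
#' @param samples numeric vector.
#' @param params a [decomp_params()].
#' @return An `imf_set`.
#' @export
iceemdan <- function(samples, params = decomp_params(variant = "ICEEMDAN")) {
  stopifnot(all(is.finite(samples)))
  if (params$noise_strength == 0) {
    out <- emd(samples, params)
    out$method <- "ICEEMDAN"
    return(out)
  }
  n <- length(samples)
  N <- params$ensemble_size
  W <- draw_noise(n, N, params$seed)
  bank <- noise_mode_bank(W, params)
  eps <- params$noise_strength

  imfs <- list()
  r <- samples
  repeat {
    if (length(imfs) >= params$max_imfs || n_extrema(r) < 3) break
    k <- length(imfs) + 1L
    acc <- numeric(n)
    used <- 0L
    for (i in seq_len(N)) {
      ek <- bank_mode(bank, i, k, n)
      beta <- if (k == 1) {
        s_ek <- stats::sd(ek)
        if (s_ek > 0) eps * stats::sd(samples) / s_ek else 0
      } else {
        eps * stats::sd(r)
      }
      m <- sift_residue(r + beta * ek, params)
      if (!is.null(m)) {
        acc <- acc + m
        used <- used + 1L
      }
    }
    if (used == 0L) break
    r_next <- acc / used
    imfs[[k]] <- r - r_next
    r <- r_next
  }
  imf_set(imfs, r, "ICEEMDAN", params)
}

#' Decompose a signal with any EMD-family variant
#'
#' Dispatches on `params$variant` to [emd()], [ensemble_emd()] or
#' [iceemdan()].
#'
#' @param samples numeric vector.
#' @param params a [decomp_params()].
#' @return An `imf_set`.
#' @export
decompose <- function(samples, params = decomp_params()) {
  switch(params$variant,
    EMD = emd(samples, params),
    EEMD = ,
    CEEMD = ,
    CEEMDAN = ensemble_emd(samples, params),
    ICEEMDAN = iceemdan(samples, params)
  )
}

#' Write / read an IMF set as wide CSV with a JSON parameter sidecar
#'
#' Columns are `time_s`, `imf1` ... `imfK`, `residual`; the sidecar records
#' the variant and decomposition parameters.
#'
#' @param x an `imf_set`.
#' @param path CSV path (sidecar gets the same path with `.json` appended).
#' @param fs sampling rate used for the time column.
#' @return `write_imfs()` returns `path` invisibly; `read_imfs()` an `imf_set`.
#' @export
write_imfs <- function(x, path, fs = 1000) {
  n <- length(x$residual)
  df <- data.frame(time_s = (seq_len(n) - 1) / fs)
  for (k in seq_along(x$imfs)) df[[paste0("imf", k)]] <- x$imfs[[k]]
  df$residual <- x$residual
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(method = x$method, params = unclass(x$params), fs = fs),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_imfs
#' @export
read_imfs <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  imf_cols <- grep("^imf[0-9]+$", names(df), value = TRUE)
  imf_cols <- imf_cols[order(as.integer(sub("imf", "", imf_cols)))]
  params <- meta$params
  class(params) <- "decomp_params"
  imf_set(lapply(imf_cols, function(cl) df[[cl]]), df$residual,
          meta$method, params)
}
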