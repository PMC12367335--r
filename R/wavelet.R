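# Orthogonal discrete wavelet transform (DWT) filter bank used to separate
# the slow trend of a vital-sign series (approximation branch) from
# high-frequency monitor noise (detail branch, discarded).
#
# Convention: the analysis step correlates the padded signal with the
# decomposition filters and keeps every second sample,
#   approx[k] = sum_m dec_lo[m] * x[2(k-1) + m],   k = 1..ceil(n/2),
# with the signal extended on the right according to `padding_mode`.
# Filters are normalized so that sum(dec_lo) = sqrt(2); a constant series
# therefore maps to a sqrt(2)-scaled constant at each level.

# Scaling filters h (correlation convention, h[1] first), published
# Daubechies coefficients; haar == db1.
.WAVELET_DEC_LO <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db1  = c(0.70710678118654757, 0.70710678118654757),
  db2  = c(0.48296291314453416, 0.83651630373780794,
           0.22414386804201339, -0.12940952255126037),
  db3  = c(0.33267055295008263, 0.80689150931109255,
           0.45987750211849154, -0.13501102001025458,
           -0.085441273882026658, 0.035226291885709533),
  db4  = c(0.23037781330889651, 0.71484657055291567,
           0.63088076792985892, -0.027983769416859854,
           -0.18703481171909309, 0.030841381835560764,
           0.032883011666885197, -0.010597401785069032)
)

#' Named orthogonal wavelet specifications
#'
#' Builds the filter set of a named orthogonal wavelet: decomposition
#' low/high-pass filters and their reconstruction counterparts. The
#' high-pass filter is the quadrature mirror of the low-pass filter,
#' `dec_hi[m] = (-1)^(m-1) * dec_lo[L + 1 - m]`, so the two analysis
#' branches form an orthonormal filter bank.
#'
#' @param name Wavelet name: one of `"haar"`, `"db1"`, `"db2"`, `"db3"`,
#'   `"db4"`.
#' @return An object of class `wavelet_spec`: a list with `name`, `dec_lo`,
#'   `dec_hi`, `rec_lo`, `rec_hi` and logical `orthogonal`.
#' @examples
#' wavelet_spec("haar")$dec_lo  # c(1, 1) / sqrt(2)
#' @export
wavelet_spec <- function(name = "db4") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% names(.WAVELET_DEC_LO)) {
    stop(sprintf("unknown wavelet '%s'; available: %s", name,
                 paste(list_wavelets(), collapse = ", ")), call. = FALSE)
  }
  h <- .WAVELET_DEC_LO[[name]]
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)  # quadrature mirror
  structure(list(name = name, dec_lo = h, dec_hi = g,
                 rec_lo = h, rec_hi = g, orthogonal = TRUE),
            class = "wavelet_spec")
}

#' @rdname wavelet_spec
#' @export
list_wavelets <- function() setdiff(names(.WAVELET_DEC_LO), "db1")

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec '%s'>  %d taps, %s\n", x$name,
              length(x$dec_lo), if (x$orthogonal) "orthogonal" else "biorthogonal"))
  invisible(x)
}

#' Denoising configuration for the wavelet filter bank
#'
#' @param level Number of cascaded low-pass/downsample stages (non-negative
#'   integer). `level = 0` is a pass-through. The default 2 halves the
#'   sampling rate twice, so a 5-minute vitals grid becomes a 20-minute
#'   trend series in approximation mode.
#' @param output_mode `"approximation"` returns the final-level approximation
#'   coefficients (length about `n / 2^level`); `"reconstruction"` inverts
#'   the cascade with all detail branches zeroed and returns a full-length
#'   low-pass version of the input.
#' @param padding_mode Signal extension at the right boundary: `"symmetric"`
#'   (reflect, default; fewest edge artifacts on short clinical windows),
#'   `"zero"`, or `"periodic"` (wrap; required for exact perfect
#'   reconstruction and energy conservation).
#' @param wavelet Name of the mother wavelet whose filters are used, see
#'   [wavelet_spec()].
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(level = 2L,
                           output_mode = c("approximation", "reconstruction"),
                           padding_mode = c("symmetric", "zero", "periodic"),
                           wavelet = "db4") {
  level <- as.integer(level)
  if (is.na(level) || level < 0L) stop("level must be a non-negative integer", call. = FALSE)
  structure(list(level = level,
                 output_mode = match.arg(output_mode),
                 padding_mode = match.arg(padding_mode),
                 wavelet = wavelet),
            class = "denoise_config")
}

# Extend x on the right by `by` samples according to the padding mode.
.pad_right <- function(x, by, padding_mode) {
  if (by <= 0L) return(x)
  n <- length(x)
  ext <- switch(padding_mode,
    zero = rep(0, by),
    periodic = x[((seq_len(by) - 1L) %% n) + 1L],
    symmetric = {
      idx <- n - ((seq_len(by) - 1L) %% n)  # n, n-1, ..., reflected
      x[idx]
    },
    stop(sprintf("unknown padding_mode '%s'", padding_mode), call. = FALSE)
  )
  c(x, ext)
}

.check_signal <- function(signal, spec) {
  if (!is.numeric(signal)) stop("signal must be numeric", call. = FALSE)
  if (any(!is.finite(signal))) stop("signal contains non-finite values", call. = FALSE)
  L <- length(spec$dec_lo)
  if (length(signal) < L) {
    stop(sprintf("series too short for this wavelet: length %d < filter length %d",
                 length(signal), L), call. = FALSE)
  }
}

#' One analysis stage of the DWT filter bank
#'
#' Pads the signal, correlates it with the decomposition low-pass and
#' high-pass filters, and keeps every second sample of each branch.
#'
#' @param signal Finite numeric vector, at least as long as the filter.
#' @param spec A [wavelet_spec()].
#' @param padding_mode See [denoise_config()].
#' @return List with numeric vectors `approx` and `detail`, each of length
#'   `ceiling(length(signal) / 2)`.
#' @examples
#' analysis_step(c(1, 1, 1, 1), wavelet_spec("haar"))$approx  # sqrt(2), sqrt(2)
#' @export
analysis_step <- function(signal, spec, padding_mode = "symmetric") {
  .check_signal(signal, spec)
  n <- length(signal)
  L <- length(spec$dec_lo)
  K <- ceiling(n / 2)
  xe <- .pad_right(signal, 2L * (K - 1L) + L - n, padding_mode)
  approx <- numeric(K)
  detail <- numeric(K)
  base <- 2L * (seq_len(K) - 1L)
  for (m in seq_len(L)) {
    xm <- xe[base + m]
    approx <- approx + spec$dec_lo[m] * xm
    detail <- detail + spec$dec_hi[m] * xm
  }
  list(approx = approx, detail = detail)
}

#' One synthesis stage of the DWT filter bank
#'
#' Upsamples the approximation and detail branches by two, filters them with
#' the reconstruction filters (circular indexing), sums, and trims to
#' `original_length`. For orthogonal wavelets and periodic padding this
#' exactly inverts [analysis_step()].
#'
#' @param approx,detail Coefficient vectors of equal length.
#' @param spec A [wavelet_spec()].
#' @param original_length Length of the signal to restore (defaults to
#'   `2 * length(approx)`).
#' @return Numeric vector of length `original_length`.
#' @export
synthesis_step <- function(approx, detail, spec, original_length = 2L * length(approx)) {
  if (length(approx) != length(detail)) {
    stop("approx and detail must have the same length", call. = FALSE)
  }
  K <- length(approx)
  n2 <- 2L * K
  L <- length(spec$rec_lo)
  out <- numeric(n2)
  # out[i] = sum_k approx[k] rec_lo[(i - 2k) mod n2] + detail[k] rec_hi[...]
  for (m in seq_len(L)) {
    pos <- ((2L * (seq_len(K) - 1L) + (m - 1L)) %% n2) + 1L
    contrib <- spec$rec_lo[m] * approx + spec$rec_hi[m] * detail
    if (anyDuplicated(pos)) {
      # offsets wrap onto each other when the block is shorter than the filter
      for (k in seq_len(K)) out[pos[k]] <- out[pos[k]] + contrib[k]
    } else {
      out[pos] <- out[pos] + contrib
    }
  }
  if (original_length > n2) {
    stop("original_length exceeds reconstructed length", call. = FALSE)
  }
  out[seq_len(original_length)]
}

#' Low-pass wavelet denoising of a vital-sign series
#'
#' Applies [analysis_step()] `level` times to successive approximations,
#' discarding every detail branch. In `"approximation"` mode the final-level
#' approximation coefficients are returned (the default input to the LSTM);
#' in `"reconstruction"` mode the cascade is inverted with all detail
#' branches zeroed, giving a full-length low-pass version of the input.
#'
#' @param series Finite numeric vector.
#' @param config A [denoise_config()].
#' @param spec A [wavelet_spec()]; defaults to the wavelet named in `config`.
#' @return Numeric vector: the denoised series.
#' @examples
#' denoise(rep(1, 16), denoise_config(level = 2, wavelet = "haar"))  # all 2
#' @export
denoise <- function(series, config = denoise_config(), spec = wavelet_spec(config$wavelet)) {
  stopifnot(inherits(config, "denoise_config"))
  if (config$level == 0L) return(series)
  if (any(!is.finite(series))) stop("signal contains non-finite values", call. = FALSE)
  L <- length(spec$dec_lo)
  min_len <- L * 2L^(config$level - 1L)
  if (length(series) < min_len) {
    stop(sprintf(
      "series too short for level %d with wavelet '%s': length %d < minimum %d",
      config$level, spec$name, length(series), min_len), call. = FALSE)
  }
  lens <- integer(config$level)
  cur <- series
  for (j in seq_len(config$level)) {
    lens[j] <- length(cur)
    cur <- analysis_step(cur, spec, config$padding_mode)$approx
  }
  if (config$output_mode == "approximation") return(cur)
  for (j in rev(seq_len(config$level))) {
    cur <- synthesis_step(cur, numeric(length(cur)), spec, original_length = lens[j])
  }
  cur
}
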