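#' Relaxation protocol
#'
#' Describes an acquisition schedule for a relaxometry experiment: an ordered
#' set of inversion times (inversion recovery, for T1) or echo times (spin
#' echo, for T2), the repetition time, and the inversion efficiency scale.
#'
#' @param kind `"inversion_recovery"` or `"spin_echo"`.
#' @param times strictly increasing vector of inversion or echo times, seconds.
#' @param tr repetition time in seconds; must exceed `max(times)`.
#' @param inversion_scale inversion efficiency `d` in (0, 1]; `d = 1` is a
#'   perfect 180 degree inversion. Ignored by spin-echo models but stored.
#' @return An object of class `relax_protocol`.
#' @examples
#' p <- relax_protocol("inversion_recovery",
#'                     times = c(0.05, 0.15, 0.35, 0.5, 0.95, 1.995),
#'                     tr = 2.4)
#' p
#' @export
relax_protocol <- function(kind = c("inversion_recovery", "spin_echo"),
                           times, tr, inversion_scale = 0.95) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (length(times) < 1L || anyNA(times) || any(times <= 0))
    stop("`times` must be positive and non-missing", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= max(times))
    stop("`tr` must be a single value greater than max(times)", call. = FALSE)
  if (inversion_scale <= 0 || inversion_scale > 1)
    stop("`inversion_scale` must lie in (0, 1]", call. = FALSE)
  structure(list(kind = kind, times = times, tr = tr,
                 inversion_scale = inversion_scale),
            class = "relax_protocol")
}

#' @export
print.relax_protocol <- function(x, ...) {
  cat(sprintf("<relax_protocol> %s\n", x$kind))
  cat(sprintf("  %s [s]: %s\n",
              if (x$kind == "inversion_recovery") "TI" else "TE",
              paste(format(x$times), collapse = ", ")))
  cat(sprintf("  TR [s]: %g   inversion scale d: %g\n", x$tr, x$inversion_scale))
  invisible(x)
}

#' Built-in acquisition protocols
#'
#' The optimized in vivo inversion-recovery T1 protocol (TR 2.4 s, six TIs),
#' the in vivo multi-echo T2 protocol (TR 3 s, ten TEs), and the long
#' 29-TI reference T1 protocol (TR 2.8 s) used for phantom validation.
#'
#' @return A `relax_protocol`.
#' @export
ir_protocol_invivo <- function() {
  relax_protocol("inversion_recovery",
                 times = c(0.05, 0.15, 0.35, 0.5, 0.95, 1.995),
                 tr = 2.4, inversion_scale = 0.95)
}

#' @rdname ir_protocol_invivo
#' @export
se_protocol_invivo <- function() {
  relax_protocol("spin_echo",
                 times = c(0.037, 0.111, 0.185, 0.259, 0.333,
                           0.407, 0.480, 0.554, 0.628, 0.702),
                 tr = 3, inversion_scale = 0.95)
}

#' @rdname ir_protocol_invivo
#' @export
ir_protocol_reference <- function() {
  relax_protocol("inversion_recovery",
                 times = c(seq(0.1, 0.6, by = 0.05), seq(0.7, 2.4, by = 0.1)),
                 tr = 2.8, inversion_scale = 0.95)
}

#' Tissue relaxation parameters
#'
#' @param t1,t2 relaxation times in seconds, both > 0. Conventionally
#'   `t2 <= t1`; violating this warns but is accepted.
#' @param s0 nominal voxel signal amplitude, arbitrary units > 0.
#' @return A list of class `tissue_params`.
#' @export
tissue_params <- function(t1, t2 = t1, s0 = 1) {
  if (!is.finite(t1) || t1 <= 0) stop("`t1` must be > 0", call. = FALSE)
  if (!is.finite(t2) || t2 <= 0) stop("`t2` must be > 0", call. = FALSE)
  if (!is.finite(s0) || s0 <= 0) stop("`s0` must be > 0", call. = FALSE)
  if (t2 > t1) warning("t2 > t1 is physically unusual", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, s0 = s0), class = "tissue_params")
}

#' Inversion-recovery magnitude signal
#'
#' Magnitude signal of an inversion-recovery experiment with finite TR and
#' imperfect inversion:
#' \deqn{S = S_0 | 1 - (1+d) e^{-TI/T_1} + e^{-TR/T_1} |}
#'
#' @param ti inversion time(s), seconds, >= 0. Vectorized.
#' @param t1 longitudinal relaxation time, seconds, > 0.
#' @param tr repetition time, seconds, > 0 (may be `Inf`).
#' @param d inversion scale in (0, 1].
#' @param s0 amplitude, > 0.
#' @return Magnitude signal(s), same length as `ti`; always in
#'   `[0, s0 * (1 + d)]`.
#' @export
ir_signal <- function(ti, t1, tr, d = 0.95, s0 = 1) {
  if (!is.finite(t1) || t1 <= 0) stop("`t1` must be > 0", call. = FALSE)
  if (is.na(tr) || tr <= 0) stop("`tr` must be > 0", call. = FALSE)
  if (d <= 0 || d > 1) stop("`d` must lie in (0, 1]", call. = FALSE)
  if (any(ti < 0)) stop("`ti` must be >= 0", call. = FALSE)
  s0 * abs(1 - (1 + d) * exp(-ti / t1) + exp(-tr / t1))
}

#' Inversion-recovery signal in the full-recovery (TR >> T1) limit
#'
#' \deqn{S = S_0 | 1 - (1+d) e^{-TI/T_1} |}
#' Appropriate when TR exceeds roughly 5 T1, as in bench NMR measurements.
#'
#' @inheritParams ir_signal
#' @export
ir_signal_full_recovery <- function(ti, t1, d = 0.95, s0 = 1) {
  ir_signal(ti, t1, tr = Inf, d = d, s0 = s0)
}

#' Spin-echo (monoexponential) magnitude signal
#'
#' \deqn{S = S_0 e^{-TE/T_2}}
#'
#' @param te echo time(s), seconds, >= 0. Vectorized.
#' @param t2 transverse relaxation time, seconds, > 0.
#' @param s0 amplitude, > 0.
#' @export
se_signal <- function(te, t2, s0 = 1) {
  if (!is.finite(t2) || t2 <= 0) stop("`t2` must be > 0", call. = FALSE)
  if (any(te < 0)) stop("`te` must be >= 0", call. = FALSE)
  s0 * exp(-te / t2)
}

#' Add Rician noise to a magnitude signal
#'
#' The magnitude of a complex measurement whose real and imaginary channels
#' each carry independent zero-mean Gaussian noise of standard deviation
#' `sigma`: `sqrt((S + g1)^2 + g2^2)`. For `S = 0` this is a Rayleigh draw.
#' SNR is defined throughout the package as `s0 / sigma` with `sigma` the
#' per-channel SD.
#'
#' @param signal true magnitude signal(s), >= 0. Vectorized.
#' @param sigma per-channel Gaussian SD, >= 0.
#' @param seed optional integer; when given, draws are made reproducible by
#'   seeding R's RNG locally (the caller's RNG state is restored).
#' @return Noisy magnitude value(s), always >= 0.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (any(signal < 0)) stop("`signal` must be >= 0 (magnitude data)", call. = FALSE)
  if (sigma == 0) return(signal)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Null inversion time of the IR signal
#'
#' The TI at which the finite-TR inversion-recovery signal crosses zero:
#' \deqn{TI_{null} = T_1 \ln\!\frac{1+d}{1+e^{-TR/T_1}}}
#' Reduces to the classic `T1 log(1 + d)` as TR grows. Useful for
#' initializing T1 fits and for protocol sanity checks.
#'
#' @inheritParams ir_signal
#' @return Null time in seconds.
#' @export
ir_null_time <- function(t1, tr, d = 0.95) {
  if (any(!is.finite(t1)) || any(t1 <= 0)) stop("`t1` must be > 0", call. = FALSE)
  if (is.na(tr) || tr <= 0) stop("`tr` must be > 0", call. = FALSE)
  if (d <= 0 || d > 1) stop("`d` must lie in (0, 1]", call. = FALSE)
  t1 * log((1 + d) / (1 + exp(-tr / t1)))
}

# Save/restore .Random.seed so seeded helpers do not disturb callers.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
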