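#' Calcium-indicator kernel parameters
#'
#' The impulse response of the nuclear-localized calcium indicator is modeled
#' as a peak-normalized double exponential
#' \eqn{k(t) = e^{-t/\tau_d} - e^{-t/\tau_r}}, with a decay constant of at
#' most 3 s (jRGECO1a-class indicators) and a fast rise. The same kernel is
#' used by the forward model of the synthetic generator and by the stimulus
#' regressors of the responsiveness analysis.
#'
#' @param tau_rise rise time constant, seconds (default 0.1).
#' @param tau_decay decay time constant, seconds (default 3).
#' @param normalize peak-normalize the kernel (default TRUE).
#' @return an object of class \code{"KernelParams"}.
#' @examples
#' k <- kernelParams()
#' kv <- calciumKernel(k, sampling_rate = 2.18)
#' max(kv) <= 1
#' @export
kernelParams <- function(tau_rise = 0.1, tau_decay = 3, normalize = TRUE) {
  .assert(is.numeric(tau_rise) && tau_rise > 0, "tau_rise must be > 0")
  .assert(is.numeric(tau_decay) && tau_decay > tau_rise,
          "tau_decay must exceed tau_rise")
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 normalize = isTRUE(normalize)),
            class = "KernelParams")
}

#' @rdname kernelParams
#' @param kernel a \code{"KernelParams"} object.
#' @param sampling_rate frames per second.
#' @param duration kernel support in seconds; default 5 decay constants,
#'   beyond which the transient is treated as extinguished.
#' @return numeric vector of kernel values on the frame grid, starting at
#'   the onset frame (t = 0).
#' @export
calciumKernel <- function(kernel = kernelParams(), sampling_rate,
                          duration = 5 * kernel$tau_decay) {
  .assert(inherits(kernel, "KernelParams"), "kernel must be kernelParams()")
  .assert(sampling_rate > 0, "sampling_rate must be positive")
  n <- max(2L, as.integer(ceiling(duration * sampling_rate)))
  t <- (seq_len(n) - 1) / sampling_rate
  k <- exp(-t / kernel$tau_decay) - exp(-t / kernel$tau_rise)
  if (kernel$normalize) {
    # analytic peak of the continuous kernel
    tpk <- log(kernel$tau_decay / kernel$tau_rise) *
      kernel$tau_rise * kernel$tau_decay / (kernel$tau_decay - kernel$tau_rise)
    pk <- exp(-tpk / kernel$tau_decay) - exp(-tpk / kernel$tau_rise)
    k <- k / pk
  }
  k
}
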