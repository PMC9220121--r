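#' Smoothing-kernel specification
#'
#' Describes one fixed-weight smoothing kernel used by curriculum-by-smoothing:
#' either a Laplacian-of-Gaussian (LoG) kernel, which emphasises
#' intensity-varying regions, or a Gaussian anti-aliasing kernel.
#'
#' @param kind `"LoG"` or `"Gaussian"`.
#' @param sigma Kernel bandwidth in pixels; must be positive.
#' @param size Odd kernel side length, at least 3. The 2D kernels are
#'   `size x size`; the 1D LoG kernel has length `size`.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("LoG", sigma = 1, size = 3)
#' @export
kernel_spec <- function(kind = c("LoG", "Gaussian"), sigma = 1, size = 3L) {
  kind <- match.arg(kind)
  stop_if(!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0,
          "`sigma` must be a single positive number")
  stop_if(!is_count(size) || size %% 2 == 0 || size < 3,
          "`size` must be an odd integer >= 3")
  structure(list(kind = kind, sigma = sigma, size = as.integer(size)),
            class = "kernel_spec")
}

# Signed integer offsets covered by a kernel of the given size.
kernel_offsets <- function(size) seq.int(-(size %/% 2), size %/% 2)

# The LoG surface at squared radius r2 for bandwidth sigma:
#   -(1 / (pi sigma^4)) (1 - r2 / (2 sigma^2)) exp(-r2 / (2 sigma^2))
log_value <- function(r2, sigma) {
  -(1 / (pi * sigma^4)) * (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
}

#' Laplacian-of-Gaussian kernels
#'
#' `log_kernel_2d()` evaluates the LoG surface
#' \deqn{\mathrm{LoG}(x,y) = -\frac{1}{\pi\sigma^4}
#'   \Big(1 - \frac{x^2+y^2}{2\sigma^2}\Big) e^{-\frac{x^2+y^2}{2\sigma^2}}}
#' at integer pixel offsets \eqn{(x, y)} centred on the kernel.
#' `log_kernel_1d()` is the same surface restricted to \eqn{y = 0}, used by the
#' graph network to smooth aggregated node messages along the feature axis.
#'
#' The raw LoG kernel does not sum to zero at finite size; `zero_sum = TRUE`
#' subtracts the mean so that the kernel annihilates constant inputs. The
#' default keeps the raw analytic weights.
#'
#' @param spec A [kernel_spec()] with `kind = "LoG"`.
#' @param zero_sum Subtract the kernel mean so entries sum to zero.
#' @return `log_kernel_2d()`: a `size x size` numeric matrix;
#'   `log_kernel_1d()`: a numeric vector of length `size`.
#' @examples
#' log_kernel_2d(kernel_spec("LoG", sigma = 1))[2, 2]  # -1/pi at the centre
#' log_kernel_1d(kernel_spec("LoG", sigma = 1))
#' @export
log_kernel_2d <- function(spec, zero_sum = FALSE) {
  stopifnot(inherits(spec, "kernel_spec"))
  stop_if(spec$kind != "LoG", "`spec` must have kind = \"LoG\"")
  off <- kernel_offsets(spec$size)
  r2 <- outer(off^2, off^2, "+")
  k <- log_value(r2, spec$sigma)
  if (zero_sum) k <- k - mean(k)
  k
}

#' @rdname log_kernel_2d
#' @export
log_kernel_1d <- function(spec, zero_sum = FALSE) {
  stopifnot(inherits(spec, "kernel_spec"))
  stop_if(spec$kind != "LoG", "`spec` must have kind = \"LoG\"")
  off <- kernel_offsets(spec$size)
  k <- log_value(off^2, spec$sigma)
  if (zero_sum) k <- k - mean(k)
  k
}

#' Normalized Gaussian anti-aliasing kernel
#'
#' Entries are proportional to \eqn{e^{-(x^2+y^2)/(2\sigma^2)}} at integer
#' offsets and are normalized to sum exactly to 1, so that the kernel preserves
#' the mean level of the field it smooths.
#'
#' @param spec A [kernel_spec()] with `kind = "Gaussian"`.
#' @return A `size x size` numeric matrix summing to 1.
#' @examples
#' sum(gaussian_kernel_2d(kernel_spec("Gaussian", sigma = 1)))
#' @export
gaussian_kernel_2d <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  stop_if(spec$kind != "Gaussian", "`spec` must have kind = \"Gaussian\"")
  off <- kernel_offsets(spec$size)
  r2 <- outer(off^2, off^2, "+")
  k <- exp(-r2 / (2 * spec$sigma^2))
  k / sum(k)
}

#' Curriculum schedule for the smoothing bandwidth
#'
#' Curriculum-by-smoothing starts training with a wide smoothing kernel and
#' shrinks it on a step schedule, progressively admitting higher-frequency
#' features. `curriculum_state()` holds the schedule; `curriculum_sigma()`
#' evaluates the effective bandwidth
#' \eqn{\sigma(e) = \sigma_0 \cdot d^{\lfloor e / p \rfloor}}.
#'
#' The printed defaults mirror the graph-network schedule (`sigma0 = 1`,
#' `decay = 0.985` every 20 epochs); the feature-extractor preset uses
#' `decay = 0.9` every 5 epochs.
#'
#' @param sigma0 Initial bandwidth (pixels), positive.
#' @param decay Multiplicative decay in `(0, 1]` applied once per period.
#' @param period_epochs Epochs between decay steps.
#' @param current_epoch Zero-based epoch counter.
#' @return `curriculum_state()`: an object of class `curriculum_state`;
#'   `curriculum_sigma()`: the effective sigma, a positive scalar.
#' @examples
#' st <- curriculum_state(sigma0 = 1, decay = 0.9, period_epochs = 5,
#'                        current_epoch = 10)
#' curriculum_sigma(st)  # 0.81
#' @export
curriculum_state <- function(sigma0 = 1, decay = 0.985, period_epochs = 20L,
                             current_epoch = 0L) {
  stop_if(!is.numeric(sigma0) || sigma0 <= 0, "`sigma0` must be positive")
  stop_if(!is.numeric(decay) || decay <= 0 || decay > 1,
          "`decay` must lie in (0, 1]")
  stop_if(!is_count(period_epochs), "`period_epochs` must be a positive integer")
  stop_if(!is.numeric(current_epoch) || current_epoch < 0 ||
            current_epoch != floor(current_epoch),
          "`current_epoch` must be a non-negative integer")
  structure(list(sigma0 = sigma0, decay = decay,
                 period_epochs = as.integer(period_epochs),
                 current_epoch = as.integer(current_epoch)),
            class = "curriculum_state")
}

#' @rdname curriculum_state
#' @param state A `curriculum_state`.
#' @export
curriculum_sigma <- function(state) {
  stopifnot(inherits(state, "curriculum_state"))
  state$sigma0 * state$decay^(state$current_epoch %/% state$period_epochs)
}

#' Apply a fixed smoothing kernel depthwise to a feature map
#'
#' Convolves every channel of an `H x W x C` feature array with the same fixed
#' 2D kernel (depthwise: no cross-channel mixing, no trainable weights), using
#' zero padding so the spatial size is preserved.
#'
#' @param features Numeric array `H x W x C` (a single `H x W` matrix is
#'   treated as one channel).
#' @param kernel Square odd-sized numeric matrix, e.g. from
#'   [gaussian_kernel_2d()] or [log_kernel_2d()].
#' @return An array of the same dimensions as `features`.
#' @export
apply_smoothing <- function(features, kernel) {
  if (is.matrix(features)) features <- array(features, c(dim(features), 1L))
  stop_if(length(dim(features)) != 3L, "`features` must be an H x W x C array")
  stop_if(!is.matrix(kernel) || nrow(kernel) != ncol(kernel) ||
            nrow(kernel) %% 2 == 0,
          "`kernel` must be a square odd-sized matrix")
  d <- dim(features)
  x <- array(features, c(d, 1L))                # H x W x C x 1
  out <- conv2d_depthwise(x, kernel)
  array(out, d)
}
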