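#' Phase-perturbation state for Fourier image scrambling
#'
#' Draws the random phase perturbations used to render a gray-scale image
#' at a given visibility. Perturbations `dphi[k, l]` are uniform on
#' `[-pi, pi]` and satisfy the Hermitian antisymmetry
#' `dphi[k, l] = -dphi[(nx - k) mod nx, (ny - l) mod ny]` (0-based
#' indices), so the inverse FFT stays real-valued; self-conjugate bins are
#' forced to zero. The lowest spatial frequencies (DC plus the first ring,
#' wrapped index magnitude <= `exclude` on both axes) are excluded from the
#' perturbation, which prevents the scrambled image from developing
#' horizontal/vertical stripe artefacts.
#'
#' @param nx,ny image dimensions in pixels.
#' @param exclude wrapped frequency-index magnitude below which components
#'   are left unperturbed (default 1: the 3 x 3 block around DC).
#' @param seed optional integer seed.
#' @return list of class `scramble_state` with `dphi` (nx x ny matrix of
#'   radians), `excluded` (logical matrix), `nx`, `ny`.
#' @export
scramble_state <- function(nx, ny, exclude = 1L, seed = NULL) {
  stopifnot(nx >= 2L, ny >= 2L)
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(stats::runif(nx * ny, -pi, pi), nx, ny)

  k <- rep(0:(nx - 1L), times = ny)
  l <- rep(0:(ny - 1L), each = nx)
  pk <- (nx - k) %% nx
  pl <- (ny - l) %% ny
  self_conj <- k == pk & l == pl
  # canonical member of each conjugate pair carries the draw, partner its negative
  canonical <- (k < pk) | (k == pk & l <= pl)
  dphi <- matrix(0, nx, ny)
  idx <- cbind(k + 1L, l + 1L)
  pidx <- cbind(pk + 1L, pl + 1L)
  dphi[idx[canonical, , drop = FALSE]] <- u[idx[canonical, , drop = FALSE]]
  dphi[pidx[canonical, , drop = FALSE]] <- -u[idx[canonical, , drop = FALSE]]
  dphi[idx[self_conj, , drop = FALSE]] <- 0

  wk <- pmin(k, nx - k)
  wl <- pmin(l, ny - l)
  excluded <- matrix(wk <= exclude & wl <= exclude, nx, ny)
  dphi[excluded] <- 0

  structure(
    list(dphi = dphi, excluded = excluded, nx = nx, ny = ny),
    class = "scramble_state"
  )
}

#' Scramble an image to a target visibility
#'
#' Renders a gray-scale image at visibility `c` in `[0, 1]` by rotating
#' the phases of its 2D Fourier transform: the demeaned image is
#' transformed, multiplied elementwise by `exp(i * dphi * (1 - c))`,
#' inverse-transformed, and the mean luminance is restored. At `c = 1` the
#' original image is recovered; at any `c` the amplitude spectrum and the
#' mean luminance are untouched, so low-level image statistics stay
#' constant while recognizability varies.
#'
#' @param image numeric matrix (gray-scale pixel intensities).
#' @param c visibility in `[0, 1]`.
#' @param state a `scramble_state` matching the image dimensions; drawn
#'   fresh (unseeded) if omitted.
#' @return numeric matrix of the same dimensions.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' identical_up_to_fft <- scramble_image(img, 1, scramble_state(8, 8, seed = 1))
#' @export
scramble_image <- function(image, c, state = NULL) {
  if (!is.matrix(image) || !is.numeric(image) || is.complex(image)) {
    stop("image must be a real-valued matrix")
  }
  stopifnot(length(c) == 1L, c >= 0, c <= 1)
  if (is.null(state)) state <- scramble_state(nrow(image), ncol(image))
  if (!inherits(state, "scramble_state") ||
    state$nx != nrow(image) || state$ny != ncol(image)) {
    stop("state does not match image dimensions")
  }
  mu <- mean(image)
  ihat <- stats::fft(image - mu)
  pert <- exp(1i * state$dphi * (1 - c))
  out <- stats::fft(ihat * pert, inverse = TRUE) / length(image)
  Re(out) + mu
}
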