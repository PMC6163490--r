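# Multi-height phase recovery and autofocus.
#
# An in-line hologram records intensity only; the lost phase produces the
# twin-image ghost on reconstruction. Capturing holograms at several
# sample-to-sensor distances and iteratively enforcing each measured
# amplitude while propagating between the planes recovers a consistent
# phase, after which a single back-propagation yields a clean object image.

#' Set of super-resolved holograms at multiple detector heights
#'
#' @param holograms List of nonnegative intensity matrices (pixel
#'   super-resolution output), one per height, all the same shape.
#' @param z_nominal Strictly increasing sample-to-sensor distances in um,
#'   one per hologram. Adjacent spacings below 2 um are rejected: with a
#'   sub-micron step the intensity barely changes between planes and the
#'   recovery becomes unreliable.
#' @param pitch Grid pitch in um (high-res).
#' @param wavelength Wavelength in um.
#' @param z_refined Optional autofocus-refined heights (filled by
#'   \code{\link{refine_heights}}).
#' @return An object of class \code{multiheight_set}.
#' @export
multiheight_set <- function(holograms, z_nominal, pitch, wavelength,
                            z_refined = NULL) {
  if (!is.list(holograms) || length(holograms) < 2L)
    stop("need at least 2 heights for phase recovery", call. = FALSE)
  if (length(z_nominal) != length(holograms))
    stop("one z value per hologram required", call. = FALSE)
  if (any(diff(z_nominal) <= 0))
    stop("`z_nominal` must be strictly increasing", call. = FALSE)
  if (any(diff(z_nominal) < 2))
    stop("adjacent heights closer than 2 um make phase recovery unreliable",
         call. = FALSE)
  dims <- dim(holograms[[1L]])
  for (h in holograms) {
    if (!is.matrix(h) || !identical(dim(h), dims))
      stop("holograms must be matrices of one shape", call. = FALSE)
    if (any(!is.finite(h)) || any(h < 0))
      stop("holograms must be finite nonnegative intensities", call. = FALSE)
  }
  if (!is.null(z_refined) && length(z_refined) != length(holograms))
    stop("`z_refined` must match the number of heights", call. = FALSE)
  structure(
    list(holograms = holograms, z_nominal = as.numeric(z_nominal),
         z_refined = z_refined, pitch = pitch, wavelength = wavelength),
    class = "multiheight_set"
  )
}

#' Sobel sharpness score
#'
#' Root-mean-square gradient magnitude of the horizontal plus vertical
#' Sobel operators, evaluated over the image interior. The quadratic mean
#' (rather than the arithmetic mean of |g|) rewards gradient energy that is
#' concentrated on few pixels, which is what distinguishes a refocused edge
#' from defocused fringes spread over the whole frame; the score is
#' invariant to additive constants, scales linearly with edge height, and
#' is maximized at the focus plane. Complex fields are scored on their
#' amplitude.
#'
#' @param image Numeric matrix (>= 3x3), or a \code{complex_field}.
#' @return Nonnegative scalar; 0 for a constant image.
#' @export
sharpness <- function(image) {
  if (inherits(image, "complex_field")) image <- Mod(image$data)
  if (!is.matrix(image) || nrow(image) < 3L || ncol(image) < 3L)
    stop("`image` must be a matrix of at least 3 x 3", call. = FALSE)
  if (any(!is.finite(image))) stop("`image` must be finite", call. = FALSE)
  ny <- nrow(image); nx <- ncol(image)
  i <- 2:(ny - 1L); j <- 2:(nx - 1L)
  a <- image
  gx <- (a[i - 1L, j + 1L] + 2 * a[i, j + 1L] + a[i + 1L, j + 1L]) -
        (a[i - 1L, j - 1L] + 2 * a[i, j - 1L] + a[i + 1L, j - 1L])
  gy <- (a[i + 1L, j - 1L] + 2 * a[i + 1L, j] + a[i + 1L, j + 1L]) -
        (a[i - 1L, j - 1L] + 2 * a[i - 1L, j] + a[i - 1L, j + 1L])
  sqrt(mean(gx^2 + gy^2))
}

#' Autofocus by golden-section search on the sharpness score
#'
#' Back-propagates the hologram over candidate distances and maximizes the
#' Sobel sharpness of the refocused amplitude. A coarse 11-point pre-scan of
#' the interval picks the initial bracket (and warns if the sharpness
#' response looks multi-modal); a golden-section search then narrows the
#' bracket below \code{tol}. Deterministic for fixed inputs.
#'
#' @param hologram A \code{complex_field}, or a nonnegative intensity matrix
#'   (its square root is taken as the amplitude; \code{pitch} and
#'   \code{wavelength} must then be supplied).
#' @param z_lo,z_hi Search interval in um (\code{z_lo <= z_hi}).
#' @param tol Bracket width tolerance in um (default 1).
#' @param pitch,wavelength Grid pitch and wavelength in um, used only when
#'   \code{hologram} is a plain matrix.
#' @return The focus distance in um (bracket midpoint).
#' @export
autofocus <- function(hologram, z_lo, z_hi, tol = 1,
                      pitch = NULL, wavelength = NULL) {
  if (!inherits(hologram, "complex_field")) {
    if (is.null(pitch) || is.null(wavelength))
      stop("supply `pitch` and `wavelength` with a plain intensity matrix",
           call. = FALSE)
    hologram <- complex_field(sqrt(pmax(hologram, 0)), pitch, wavelength)
  }
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (z_lo > z_hi) stop("`z_lo` must not exceed `z_hi`", call. = FALSE)
  if (z_lo == z_hi) return(z_lo)

  score <- function(z) sharpness(Mod(propagate(hologram, -z)$data))

  # coarse pre-scan picks the bracket and flags non-unimodal responses;
  # repeated until the bracket is narrow enough that the twin-image side
  # lobes are excluded and golden-section can assume unimodality
  a <- z_lo; b <- z_hi
  warned <- FALSE
  repeat {
    zs <- seq(a, b, length.out = 11L)
    ss <- vapply(zs, score, numeric(1L))
    peaks <- sum(ss[2:10] > ss[1:9] & ss[2:10] > ss[3:11])
    if (peaks > 1L && !warned) {
      warning("sharpness response is not unimodal over the search ",
              "interval; returning the best local optimum found")
      warned <- TRUE
    }
    ibest <- which.max(ss)
    a <- zs[max(1L, ibest - 1L)]
    b <- zs[min(11L, ibest + 1L)]
    if ((b - a) <= max(20 * tol, 1e-9)) break
  }

  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- score(x1); f2 <- score(x2)
  while ((b - a) > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- score(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- score(x1)
    }
  }
  (a + b) / 2
}

#' Refine nominal heights by autofocus
#'
#' Runs \code{\link{autofocus}} on each hologram of a multi-height set in a
#' window around its nominal distance and stores the refined values in
#' \code{z_refined}.
#'
#' @param set A \code{multiheight_set}.
#' @param window Half-width of the search window around each nominal z (um,
#'   default 30).
#' @param tol Autofocus tolerance in um (default 1).
#' @return The set with \code{z_refined} populated.
#' @export
refine_heights <- function(set, window = 30, tol = 1) {
  stopifnot(inherits(set, "multiheight_set"))
  zr <- vapply(seq_along(set$holograms), function(i) {
    autofocus(set$holograms[[i]],
              set$z_nominal[i] - window, set$z_nominal[i] + window,
              tol = tol, pitch = set$pitch, wavelength = set$wavelength)
  }, numeric(1L))
  set$z_refined <- zr
  set
}

#' Multi-height iterative phase recovery
#'
#' Recovers the hologram phase from intensity measurements at several
#' sample-to-sensor distances. The field is initialized at the first
#' (closest) height with the measured amplitude and zero phase, then swept
#' forward through the heights and back: at each height the calculated
#' amplitude is replaced by the arithmetic mean of the calculated and the
#' measured amplitude (the square root of the measured intensity) while the
#' phase is kept. One forward plus backward sweep is one iteration; the loop
#' stops when the normalized L2 change of the first-plane field drops below
#' \code{tol} or after \code{max_iter} iterations.
#'
#' @param set A \code{multiheight_set}; \code{z_refined} is used when
#'   populated, otherwise the nominal heights (with a warning).
#' @param max_iter Maximum iterations (default 50).
#' @param tol Convergence tolerance on the relative first-plane change
#'   (default 1e-4).
#' @param init Initial phase: \code{"zero"} (default, deterministic) or
#'   \code{"random"} (uniform in \code{[0, 2*pi)}, controlled by
#'   \code{seed}).
#' @param seed Seed for \code{init = "random"}.
#' @return A list with \code{field} (the recovered \code{complex_field} at
#'   the first height) and \code{report} (iterations run, residual history,
#'   convergence flag).
#' @export
recover_phase <- function(set, max_iter = 50L, tol = 1e-4,
                          init = c("zero", "random"), seed = 1L) {
  stopifnot(inherits(set, "multiheight_set"))
  init <- match.arg(init)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  z <- set$z_refined
  if (is.null(z)) {
    warning("z_refined not populated; falling back to nominal heights")
    z <- set$z_nominal
  }
  amps <- lapply(set$holograms, function(h) sqrt(h))
  J <- length(amps)

  phase0 <- if (init == "random") {
    with_seed(seed, matrix(stats::runif(length(amps[[1L]]), 0, 2 * pi),
                           nrow(amps[[1L]])))
  } else {
    matrix(0, nrow(amps[[1L]]), ncol(amps[[1L]]))
  }
  field <- complex_field(amps[[1L]] * exp(1i * phase0),
                         set$pitch, set$wavelength, z_position = z[1L])

  enforce <- function(field, amp) {
    newamp <- (Mod(field$data) + amp) / 2
    ph <- Arg(field$data)
    field$data <- newamp * exp(1i * ph)
    field
  }

  residuals <- numeric(0L)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    prev <- field$data
    for (j in 2:J) {                       # forward sweep away from sample
      field <- propagate(field, z[j] - z[j - 1L])
      field <- enforce(field, amps[[j]])
    }
    for (j in (J - 1L):1L) {               # backward sweep to first height
      field <- propagate(field, z[j] - z[j + 1L])
      field <- enforce(field, amps[[j]])
    }
    res <- sqrt(sum(Mod(field$data - prev)^2)) /
      max(sqrt(sum(Mod(prev)^2)), .Machine$double.eps)
    residuals <- c(residuals, res)
    iters <- it
    if (res < tol) { converged <- TRUE; break }
  }

  list(
    field = field,
    report = list(iterations_run = iters, residual_history = residuals,
                  converged = converged)
  )
}

#' Data-fidelity residual of a recovered hologram
#'
#' Mean over heights of the relative L2 difference between the amplitude of
#' the recovered field propagated to each measured height and the measured
#' amplitude there. A diagnostic of how well the recovery honours the data.
#'
#' @param field Recovered \code{complex_field} at the first height.
#' @param set The \code{multiheight_set} it was recovered from.
#' @return Nonnegative scalar.
#' @export
amplitude_residual <- function(field, set) {
  stopifnot(inherits(field, "complex_field"), inherits(set, "multiheight_set"))
  z <- if (is.null(set$z_refined)) set$z_nominal else set$z_refined
  res <- vapply(seq_along(set$holograms), function(j) {
    amp <- sqrt(set$holograms[[j]])
    calc <- Mod(propagate(field, z[j] - z[1L])$data)
    sqrt(sum((calc - amp)^2)) / max(sqrt(sum(amp^2)), .Machine$double.eps)
  }, numeric(1L))
  mean(res)
}
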