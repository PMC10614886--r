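#' Construct a synthetic spindle scene
#'
#' Builds the parameter object consumed by
#' \code{\link{generateSpindleImage}} and \code{\link{generateTimelapse}}.
#' Defaults describe a metaphase spindle typical of the cell lines this
#' package targets: an 11 um pole-to-pole axis, a kinetochore band of
#' axial sigma 1.5 um centred on the spindle equator, and a KIF18A channel
#' peaking 2 um inside each pole (plus-end-like accumulation; set
#' \code{kif18aPeakDistance = 0} for a pole-accumulated, inhibited-like
#' motor).  Default amplitudes and noise give the kinetochore channel a
#' peak signal-to-noise ratio of about 10 (peak amplitude over the Poisson
#' + read noise standard deviation at the peak).
#'
#' @param poleA,poleB pole positions \code{c(x, y)} in micrometres.
#' @param kinetochoreSigma axial sigma of the kinetochore band (um).
#' @param kif18aPeakDistance distance from each pole to the KIF18A peak
#'   (um); at most half the pole-pole distance.
#' @param channelAmplitudes named peak amplitudes (a.u.) for
#'   \code{gamma_tubulin}, \code{alpha_tubulin}, \code{kinetochore},
#'   \code{kif18a}.
#' @param background additive background (a.u.).
#' @param shotNoise apply Poisson noise to expected counts?
#' @param readSD Gaussian read-noise standard deviation (a.u.).
#' @param pixelSize micrometres per pixel.
#' @param imageShape raster shape \code{c(nrow, ncol)} in pixels.
#' @param seed integer seed used when noise is drawn.
#' @return a validated \linkS4class{SpindleScene}.
#' @export
SpindleScene <- function(poleA = c(3, 6.5), poleB = c(14, 6.5),
                         kinetochoreSigma = 1.5, kif18aPeakDistance = 2,
                         channelAmplitudes = c(gamma_tubulin = 500,
                                               alpha_tubulin = 150,
                                               kinetochore = 120,
                                               kif18a = 120),
                         background = 20, shotNoise = TRUE, readSD = 3,
                         pixelSize = 0.1083,
                         imageShape = c(120L, 160L), seed = 1L) {
  new("SpindleScene", poleA = as.numeric(poleA), poleB = as.numeric(poleB),
      kinetochoreSigma = kinetochoreSigma,
      kif18aPeakDistance = kif18aPeakDistance,
      channelAmplitudes = channelAmplitudes, background = background,
      shotNoise = shotNoise, readSD = readSD, pixelSize = pixelSize,
      imageShape = as.integer(imageShape), seed = as.integer(seed))
}

# Fixed render-model shape parameters (um).  Poles are isotropic 2D
# Gaussians; alpha-tubulin a stadium-shaped density around the pole-pole
# segment; the kinetochore band an axial Gaussian times a lateral
# envelope; KIF18A two mirrored axial peaks plus a faint lattice term.
RENDER_SHAPE <- list(
  pole_sigma = 0.4,       # gamma-tubulin punctum width
  alpha_sigma = 1.2,      # half-thickness of the spindle body
  kin_lateral_sigma = 1.5,  # lateral envelope of the kinetochore band
  kif_sigma = 0.5,        # axial width of each KIF18A peak
  kif_lateral_sigma = 1.0,
  kif_lattice_frac = 0.15)  # faint spindle-lattice KIF18A component

# Per-pixel scene geometry: axial coordinate s (um from poleA along the
# axis), perpendicular distance t, distances to each pole and to the
# segment.  Pixel (row r, col c), 0-based, has its centre at
# (c * pixelSize, r * pixelSize) um.
sceneGeometry <- function(scene) {
  nr <- scene@imageShape[1]; nc <- scene@imageShape[2]
  px <- scene@pixelSize
  X <- matrix(rep((0:(nc - 1)) * px, each = nr), nr, nc)
  Y <- matrix(rep((0:(nr - 1)) * px, times = nc), nr, nc)
  pA <- scene@poleA; pB <- scene@poleB
  L <- sqrt(sum((pB - pA)^2))
  u <- (pB - pA) / L
  dxA <- X - pA[1]; dyA <- Y - pA[2]
  s <- dxA * u[1] + dyA * u[2]
  t <- -dxA * u[2] + dyA * u[1]
  dA <- sqrt(dxA^2 + dyA^2)
  dB <- sqrt((X - pB[1])^2 + (Y - pB[2])^2)
  dseg <- ifelse(s < 0, dA, ifelse(s > L, dB, abs(t)))
  list(s = s, t = t, dA = dA, dB = dB, dseg = dseg, L = L)
}

# Noise-free expected intensity per channel, excluding background.
renderExpected <- function(scene) {
  g <- sceneGeometry(scene)
  sh <- RENDER_SHAPE
  A <- scene@channelAmplitudes
  gam <- A[["gamma_tubulin"]] *
    (exp(-g$dA^2 / (2 * sh$pole_sigma^2)) +
     exp(-g$dB^2 / (2 * sh$pole_sigma^2)))
  alp <- A[["alpha_tubulin"]] * exp(-g$dseg^2 / (2 * sh$alpha_sigma^2))
  kin <- A[["kinetochore"]] *
    exp(-(g$s - g$L / 2)^2 / (2 * scene@kinetochoreSigma^2)) *
    exp(-g$t^2 / (2 * sh$kin_lateral_sigma^2))
  d <- scene@kif18aPeakDistance
  kif <- A[["kif18a"]] *
    (exp(-(g$s - d)^2 / (2 * sh$kif_sigma^2)) +
     exp(-(g$s - (g$L - d))^2 / (2 * sh$kif_sigma^2))) *
    exp(-g$t^2 / (2 * sh$kif_lateral_sigma^2)) +
    sh$kif_lattice_frac * A[["kif18a"]] *
      exp(-g$dseg^2 / (2 * sh$alpha_sigma^2))
  list(gamma_tubulin = gam, alpha_tubulin = alp,
       kinetochore = kin, kif18a = kif)
}

# Poisson shot noise on expected counts, then additive Gaussian read
# noise; negative values are clamped at zero.  Draws from the current RNG
# stream (callers wrap in withSeed).
applyNoise <- function(expected, scene) {
  m <- expected
  if (scene@shotNoise)
    m[] <- stats::rpois(length(m), lambda = pmax(m, 0))
  if (scene@readSD > 0)
    m[] <- m + stats::rnorm(length(m), sd = scene@readSD)
  pmax(m, 0)
}

checkPoleMargins <- function(scene, margin = 2) {
  ext <- (rev(scene@imageShape) - 1) * scene@pixelSize  # (x, y) extent
  for (p in list(scene@poleA, scene@poleB)) {
    if (any(p < margin) || any(p > ext - margin))
      stop("poles must lie inside the image with >= ", margin,
           " um margin (extent ", paste(round(ext, 2), collapse = " x "),
           " um)", call. = FALSE)
  }
}

groundTruthFromScene <- function(scene) {
  L <- sqrt(sum((scene@poleB - scene@poleA)^2))
  list(true_fwhm = 2 * sqrt(2 * log(2)) * scene@kinetochoreSigma,
       true_spindle_length = L,
       true_peak_distance = scene@kif18aPeakDistance,
       pole_a_px = scene@poleA / scene@pixelSize,
       pole_b_px = scene@poleB / scene@pixelSize)
}

#' Render a synthetic spindle image with known ground truth
#'
#' Renders the four channel rasters of a scene (gamma-tubulin poles,
#' alpha-tubulin spindle body, kinetochore/DNA band, KIF18A motor) at
#' pixel centres, adds the background, and, unless noise is disabled in
#' the scene, applies seeded Poisson shot noise and Gaussian read noise.
#' With noise disabled the render is deterministic and exact, and serves
#' as the oracle for the extraction stages.
#'
#' @param scene a \linkS4class{SpindleScene}.
#' @return a list with elements \code{image} (a
#'   \linkS4class{SpindleImage}) and \code{truth} (a list of ground-truth
#'   values: \code{true_fwhm}, \code{true_spindle_length},
#'   \code{true_peak_distance}, and the pole positions in 0-based pixel
#'   coordinates, \code{pole_a_px} / \code{pole_b_px}).
#' @examples
#' sc <- SpindleScene(shotNoise = FALSE, readSD = 0)
#' res <- generateSpindleImage(sc)
#' res$truth$true_fwhm   # 2*sqrt(2*log(2)) * 1.5
#' @export
generateSpindleImage <- function(scene) {
  validObject(scene)
  checkPoleMargins(scene)
  expected <- renderExpected(scene)
  chans <- withSeed(scene@seed, lapply(expected, function(m)
    applyNoise(m + scene@background, scene)))
  img <- new("SpindleImage", channels = chans,
             pixelSize = scene@pixelSize)
  list(image = img, truth = groundTruthFromScene(scene))
}

#' Render a KIF18A relocalization time-lapse
#'
#' Simulates the mid-spindle gap that forms in KIF18A localization after
#' motor inhibition: in frame \code{t} the KIF18A channel is suppressed
#' within \code{gapHalfwidths[t]} micrometres of the spindle midpoint
#' (smooth 0.2 um edge) and the suppressed intensity is redistributed to
#' the two poles, so the total (non-background) KIF18A intensity is
#' conserved across frames.  All other channels are static.  A gap of 0
#' reproduces the untreated frame exactly.
#'
#' @param scene a \linkS4class{SpindleScene}.
#' @param gapHalfwidths non-decreasing gap half-widths in um, one per
#'   frame, each < half the spindle length.
#' @param frameTimes frame times in minutes relative to treatment;
#'   defaults to a grid from -1.5 (initial, pre-treatment) to 12 min
#'   (final).
#' @return a list with \code{stack} (a \linkS4class{SpindleStack}) and
#'   \code{truth} (scene ground truth plus the gap schedule).
#' @export
generateTimelapse <- function(scene, gapHalfwidths, frameTimes = NULL) {
  validObject(scene)
  checkPoleMargins(scene)
  n <- length(gapHalfwidths)
  if (n < 1L) stop("need at least one frame", call. = FALSE)
  if (is.unsorted(gapHalfwidths))
    stop("gap half-widths must be non-decreasing", call. = FALSE)
  g <- sceneGeometry(scene)
  if (any(gapHalfwidths < 0) || any(gapHalfwidths >= g$L / 2))
    stop("gap half-widths must lie in [0, half spindle length)",
         call. = FALSE)
  if (is.null(frameTimes))
    frameTimes <- if (n == 1L) 0 else seq(-1.5, 12, length.out = n)
  expected <- renderExpected(scene)
  K0 <- expected$kif18a
  # Pole-redistribution kernel, unit total intensity.
  sh <- RENDER_SHAPE
  P <- exp(-g$dA^2 / (2 * sh$pole_sigma^2)) +
       exp(-g$dB^2 / (2 * sh$pole_sigma^2))
  P <- P / sum(P)
  edge <- 0.2
  frames <- withSeed(scene@seed, lapply(seq_len(n), function(i) {
    gw <- gapHalfwidths[i]
    W <- if (gw <= 0) 1 else stats::pnorm((abs(g$s - g$L / 2) - gw) / edge)
    Kt <- K0 * W
    removed <- sum(K0) - sum(Kt)
    Kt <- Kt + removed * P
    chans <- expected
    chans$kif18a <- Kt
    chans <- lapply(chans, function(m)
      applyNoise(m + scene@background, scene))
    new("SpindleImage", channels = chans, pixelSize = scene@pixelSize,
        frameTime = frameTimes[i] * 60)
  }))
  stack <- new("SpindleStack", frames = frames, frameTimes = frameTimes)
  truth <- groundTruthFromScene(scene)
  truth$gap_halfwidths = gapHalfwidths
  list(stack = stack, truth = truth)
}

#' Four-fold (or k-fold) serial dilution series
#'
#' @param top highest concentration (nM).
#' @param n number of points.
#' @param fold dilution factor between successive points.
#' @return concentrations in nM, descending.
#' @examples
#' serialDilution(1000, 8, 4)  # 1000, 250, 62.5, ...
#' @export
serialDilution <- function(top = 1000, n = 8, fold = 4) {
  if (n < 1) stop("need n >= 1", call. = FALSE)
  top / fold^(0:(n - 1))
}

#' Simulate an ATPase-assay plate
#'
#' Luminescence signals follow the four-parameter logistic inhibition
#' model: positive-control wells (enzyme, no compound) sit at the high
#' asymptote, negative-control wells (no enzyme) at the low asymptote,
#' and sample wells at
#' \code{pos - (pos - neg) / (1 + (ic50/x)^hill)}.  Multiplicative
#' Gaussian noise with coefficient of variation \code{cv} is applied to
#' every well.
#'
#' @param trueIC50 ground-truth IC50 (nM).
#' @param hill ground-truth Hill slope.
#' @param concentrations sample concentrations in nM (> 0).
#' @param cv coefficient of variation of the multiplicative noise.
#' @param nReps replicate wells per concentration.
#' @param nControl wells per control role.
#' @param positiveSignal,negativeSignal control luminescence levels (a.u.).
#' @param compound compound label.
#' @param seed RNG seed.
#' @return a plate \code{data.frame} with columns \code{compound},
#'   \code{concentration_nM} (\code{NA} for controls), \code{signal},
#'   \code{role} (\code{sample}, \code{positive_control},
#'   \code{negative_control}).
#' @export
generateDoseResponse <- function(trueIC50, hill = 1,
                                 concentrations = serialDilution(),
                                 cv = 0.05, nReps = 2, nControl = 4,
                                 positiveSignal = 1e6,
                                 negativeSignal = 5e4,
                                 compound = "compound", seed = NULL) {
  if (length(concentrations) == 0)
    stop("concentration list must not be empty", call. = FALSE)
  if (any(concentrations <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  conc <- rep(concentrations, each = nReps)
  mu <- positiveSignal -
    (positiveSignal - negativeSignal) / (1 + (trueIC50 / conc)^hill)
  mu <- c(mu, rep(positiveSignal, nControl), rep(negativeSignal, nControl))
  role <- c(rep("sample", length(conc)),
            rep("positive_control", nControl),
            rep("negative_control", nControl))
  sig <- withSeed(seed, mu * (1 + stats::rnorm(length(mu), sd = cv)))
  data.frame(compound = compound,
             concentration_nM = c(conc, rep(NA_real_, 2 * nControl)),
             signal = pmax(sig, 0), role = role)
}

#' Simulate an exponential proliferation time series
#'
#' Cell counts grow as \code{n0 * exp(rate * t)} with optional
#' multiplicative Gaussian noise of coefficient of variation
#' \code{noiseCV}.
#'
#' @param ratePerHour exponential growth rate (per hour); a doubling time
#'   of 24 h corresponds to \code{log(2)/24}.
#' @param n0 starting cell count (>= 0).
#' @param hours observation times in hours.
#' @param noiseCV coefficient of variation of the count noise.
#' @param wellId,condition,batch labels carried into the output.
#' @param seed RNG seed.
#' @return a \code{data.frame} with columns \code{batch}, \code{well_id},
#'   \code{condition}, \code{time_h}, \code{count}.
#' @export
generateGrowthSeries <- function(ratePerHour, n0, hours, noiseCV = 0,
                                 wellId = "w1", condition = "treated",
                                 batch = "b1", seed = NULL) {
  if (!is.finite(ratePerHour)) stop("rate must be finite", call. = FALSE)
  if (n0 < 0) stop("n0 must be >= 0", call. = FALSE)
  if (is.unsorted(hours, strictly = TRUE))
    stop("hours must be strictly increasing", call. = FALSE)
  mu <- n0 * exp(ratePerHour * hours)
  cnt <- withSeed(seed,
    pmax(mu * (1 + stats::rnorm(length(mu), sd = noiseCV)), 0))
  data.frame(batch = batch, well_id = wellId, condition = condition,
             time_h = hours, count = cnt)
}

#' Simulate a per-field mitotic count table
#'
#' Each field holds \code{cellsPerField} cells; the number of mitotic
#' cells is a binomial draw with probability \code{mitoticFraction}.  Each
#' mitotic cell is scored multipolar (n_poles drawn from {3, 4}) with
#' probability \code{multipolarFraction}, monopolar (n_poles = 1) with
#' probability \code{monopolarFraction}, and bipolar otherwise.
#'
#' @param nFields number of imaging fields.
#' @param cellsPerField cells per field.
#' @param mitoticFraction,multipolarFraction,monopolarFraction
#'   proportions in [0, 1].
#' @param seed RNG seed.
#' @return a \linkS4class{CountTable}.
#' @export
generateCountTable <- function(nFields = 20, cellsPerField = 100,
                               mitoticFraction = 0.1,
                               multipolarFraction = 0,
                               monopolarFraction = 0, seed = NULL) {
  fr <- c(mitoticFraction, multipolarFraction, monopolarFraction)
  if (any(fr < 0) || any(fr > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (multipolarFraction + monopolarFraction > 1)
    stop("multipolar + monopolar fractions must not exceed 1",
         call. = FALSE)
  withSeed(seed, {
    mitotic <- stats::rbinom(nFields, cellsPerField, mitoticFraction)
    fields <- data.frame(field = seq_len(nFields),
                         total_cells = cellsPerField,
                         mitotic_cells = mitotic)
    poles <- do.call(rbind, lapply(seq_len(nFields), function(f) {
      m <- mitotic[f]
      if (m == 0) return(NULL)
      cls <- sample(c("multi", "mono", "bi"), m, replace = TRUE,
                    prob = c(multipolarFraction, monopolarFraction,
                             1 - multipolarFraction - monopolarFraction))
      np <- ifelse(cls == "bi", 2L,
             ifelse(cls == "mono", 1L,
                    sample(3:4, m, replace = TRUE, prob = c(0.8, 0.2))))
      data.frame(field = f, cell = seq_len(m), n_poles = np)
    }))
    if (is.null(poles))
      poles <- data.frame(field = integer(), cell = integer(),
                          n_poles = integer())
    new("CountTable", fields = fields, poles = poles)
  })
}
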