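#' Percent inhibition of ATPase activity
#'
#' \code{100 * (positive - sample) / (positive - negative)}: a sample at
#' the positive-control (uninhibited) level maps to exactly 0, one at the
#' negative-control (no-enzyme) level to exactly 100.  Values outside
#' [-20, 120] are permitted (assay noise) but flagged with a warning.
#'
#' @param sample sample luminescence signal(s).
#' @param positiveMean mean positive-control signal.
#' @param negativeMean mean negative-control signal.
#' @return percent inhibition, same length as \code{sample}.
#' @export
percentInhibition <- function(sample, positiveMean, negativeMean) {
  if (positiveMean == negativeMean)
    stop("positive and negative control means are equal", call. = FALSE)
  y <- 100 * (positiveMean - sample) / (positiveMean - negativeMean)
  out <- y < -20 | y > 120
  if (any(out))
    warning(sum(out), " well(s) outside [-20, 120] percent inhibition",
            call. = FALSE)
  y
}

#' Percent-inhibition table for a plate
#'
#' Aggregates control wells by their per-plate means and converts every
#' sample well to percent inhibition.  Controls are never shared across
#' plates.
#'
#' @param plate plate \code{data.frame} as produced by
#'   \code{\link{generateDoseResponse}} (columns \code{concentration_nM},
#'   \code{signal}, \code{role}).
#' @return \code{data.frame} with \code{concentration_nM} and
#'   \code{inhibition} for the sample wells.
#' @export
plateInhibition <- function(plate) {
  need <- c("concentration_nM", "signal", "role")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop("plate lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pos <- plate$signal[plate$role == "positive_control"]
  neg <- plate$signal[plate$role == "negative_control"]
  if (length(pos) == 0 || length(neg) == 0)
    stop("plate needs >= 1 positive and >= 1 negative control well",
         call. = FALSE)
  s <- plate[plate$role == "sample", ]
  data.frame(concentration_nM = s$concentration_nM,
             inhibition = percentInhibition(s$signal, mean(pos),
                                            mean(neg)))
}

#' Four-parameter logistic (variable slope) IC50 fit
#'
#' Fits \code{y = bottom + (top - bottom) / (1 + (ic50/x)^hill)} to
#' percent inhibition versus concentration by bounded
#' Levenberg-Marquardt on log10 concentration (the
#' "log(inhibitor) vs response -- variable slope" parameterization).
#' Initialization: bottom = min y, top = max y, IC50 = the concentration
#' whose response is nearest 50%, hill = 1.  The Hill slope is bounded to
#' [0.1, 10]; a fit ending on a bound, or failing to converge, is
#' flagged.  Standard errors for bottom/top/hill come from the fit; the
#' IC50 standard error is delta-method propagated from log10(IC50).
#'
#' @param concentration concentrations in nM (> 0; >= 5 distinct values
#'   spanning the inflection).
#' @param inhibition percent inhibition at each concentration.
#' @return a \linkS4class{FourPLFit}.
#' @examples
#' conc <- serialDilution(1000, 8, 4)
#' y <- 100 / (1 + (8.2 / conc)^1)
#' fit4PL(conc, y)  # recovers IC50 = 8.2 nM
#' @export
fit4PL <- function(concentration, inhibition) {
  if (length(concentration) != length(inhibition))
    stop("concentration and inhibition lengths differ", call. = FALSE)
  if (any(concentration <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  if (length(unique(concentration)) < 5)
    stop("need >= 5 distinct concentrations", call. = FALSE)
  lx <- log10(concentration)
  y <- inhibition
  start <- c(bottom = min(y), top = max(y),
             logIC50 = lx[which.min(abs(y - 50))], hill = 1)
  lower <- c(bottom = -Inf, top = -Inf, logIC50 = min(lx) - 3,
             hill = 0.1)
  upper <- c(bottom = Inf, top = Inf, logIC50 = max(lx) + 3, hill = 10)
  residFn <- function(p)
    y - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
           (1 + 10^((p[["logIC50"]] - lx) * p[["hill"]])))
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = residFn, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(out) || !out$info %in% 1:4)
    return(new("FourPLFit", bottom = unname(start["bottom"]),
               top = unname(start["top"]),
               ic50 = 10^unname(start["logIC50"]),
               hill = unname(start["hill"]),
               rss = sum((y - mean(y))^2),
               se = c(bottom = NA_real_, top = NA_real_,
                      ic50 = NA_real_, hill = NA_real_),
               converged = FALSE, flags = "fit_failed"))
  cf <- out$par
  ic50 <- 10^cf[["logIC50"]]
  sev <- tryCatch(summary(out)$coefficients[, "Std. Error"],
                  error = function(e)
                    c(bottom = NA_real_, top = NA_real_,
                      logIC50 = NA_real_, hill = NA_real_))
  se <- c(bottom = sev[["bottom"]], top = sev[["top"]],
          ic50 = log(10) * ic50 * sev[["logIC50"]],
          hill = sev[["hill"]])
  flags <- character()
  if (abs(cf[["hill"]] - 0.1) < 1e-6 || abs(cf[["hill"]] - 10) < 1e-6)
    flags <- c(flags, "hill_at_bound")
  if (abs(cf[["logIC50"]] - (min(lx) - 3)) < 1e-6 ||
      abs(cf[["logIC50"]] - (max(lx) + 3)) < 1e-6)
    flags <- c(flags, "ic50_at_bound")
  new("FourPLFit", bottom = cf[["bottom"]], top = cf[["top"]],
      ic50 = ic50, hill = cf[["hill"]], rss = out$deviance, se = se,
      converged = length(flags) == 0, flags = flags)
}

#' Predicted percent inhibition from a 4PL fit
#'
#' @param fit a \linkS4class{FourPLFit}.
#' @param concentration concentrations in nM.
#' @return predicted percent inhibition.
#' @export
predict4PL <- function(fit, concentration) {
  stopifnot(is(fit, "FourPLFit"))
  fit@bottom + (fit@top - fit@bottom) /
    (1 + (fit@ic50 / concentration)^fit@hill)
}

#' Dose-response analysis of a plate table
#'
#' Percent-inhibition transform followed by the 4PL fit.
#'
#' @param plate plate \code{data.frame} (see
#'   \code{\link{plateInhibition}}).
#' @return list with \code{inhibition} (the per-well table) and
#'   \code{fit} (a \linkS4class{FourPLFit}).
#' @export
doseResponseAnalysis <- function(plate) {
  tab <- plateInhibition(plate)
  list(inhibition = tab,
       fit = fit4PL(tab$concentration_nM, tab$inhibition))
}
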