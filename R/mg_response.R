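#' Fit a bell-shaped Mg dose-response curve
#'
#' Least-squares Gaussian fit `rate = A * exp(-(Mg - c)^2 / (2 * w^2))` of
#' maximal synthesis rate against added Mg2+. The fitted center `c` is the
#' magnesium optimum. Initialisation is deterministic: center at the grid
#' point with the highest rate, amplitude at that rate, width a quarter of
#' the grid span. Fitting uses Levenberg-Marquardt (`minpack.lm::nlsLM`),
#' with a Nelder-Mead fallback on the same objective.
#'
#' @param points data.frame with columns `mg_mM` and `rate` (one row per Mg
#'   concentration, replicates already averaged), or numeric vectors via
#'   `mg` and `rate`.
#' @param mg,rate Alternative vector interface.
#' @return Object of class `mg_bell`: `amplitude`, `optimum` (mM), `width`
#'   (mM), `fitted`, `residuals`, `extrapolated` flag (optimum more than
#'   0.2 mM outside the data range), and the data.
#' @examples
#' mg <- seq(0.2, 1.4, by = 0.2)
#' fit_bell(mg = mg, rate = 100 * exp(-(mg - 0.8)^2 / (2 * 0.3^2)))
#' @export
fit_bell <- function(points = NULL, mg = NULL, rate = NULL) {
  if (!is.null(points)) {
    stopifnot(is.data.frame(points), all(c("mg_mM", "rate") %in% names(points)))
    mg <- points$mg_mM
    rate <- points$rate
  }
  mg <- as.numeric(mg)
  rate <- as.numeric(rate)
  if (length(unique(mg)) < 4L) {
    stop("bell fit needs at least 4 distinct Mg concentrations")
  }
  if (length(mg) != length(rate) || anyNA(mg) || anyNA(rate)) {
    stop("mg and rate must be NA-free vectors of equal length")
  }
  if (diff(range(rate)) == 0) {
    stop("degenerate dose-response data: all rates are equal")
  }
  c0 <- mg[which.max(rate)]
  a0 <- max(rate)
  w0 <- diff(range(mg)) / 4
  dat <- data.frame(mg = mg, rate = rate)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = a0, c = c0, w = w0),
      fn = function(th) rate - th[1L] * exp(-(mg - th[2L])^2 / (2 * th[3L]^2)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (!is.null(fit) && all(is.finite(fit$par))) {
    cf <- fit$par
  } else {
    ss <- function(th) {
      sum((rate - th[1L] * exp(-(mg - th[2L])^2 / (2 * th[3L]^2)))^2)
    }
    opt <- stats::optim(c(a0, c0, w0), ss, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    cf <- stats::setNames(opt$par, c("A", "c", "w"))
  }
  amplitude <- unname(cf["A"])
  optimum <- unname(cf["c"])
  width <- abs(unname(cf["w"]))
  fitted <- amplitude * exp(-(mg - optimum)^2 / (2 * width^2))
  structure(
    list(amplitude = amplitude, optimum = optimum, width = width,
         fitted = fitted, residuals = rate - fitted,
         extrapolated = optimum < min(mg) - 0.2 || optimum > max(mg) + 0.2,
         data = dat),
    class = "mg_bell"
  )
}

#' @export
print.mg_bell <- function(x, ...) {
  cat(sprintf("<mg_bell> optimum %.3f mM, amplitude %.4g, width %.3f mM%s\n",
              x$optimum, x$amplitude, x$width,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' @export
coef.mg_bell <- function(object, ...) {
  c(amplitude = object$amplitude, optimum = object$optimum,
    width = object$width)
}

#' @export
predict.mg_bell <- function(object, newdata = NULL, ...) {
  mg <- if (is.null(newdata)) object$data$mg
        else if (is.data.frame(newdata)) newdata$mg
        else as.numeric(newdata)
  object$amplitude * exp(-(mg - object$optimum)^2 / (2 * object$width^2))
}

#' @export
plot.mg_bell <- function(x, ...) {
  graphics::plot(x$data$mg, x$data$rate, xlab = "added Mg2+ (mM)",
                 ylab = "max synthesis rate (ALU/min)", ...)
  gg <- seq(min(x$data$mg), max(x$data$mg), length.out = 200)
  graphics::lines(gg, predict(x, gg))
  graphics::abline(v = x$optimum, lty = 2)
  invisible(x)
}

#' Magnesium optimum of a fitted response curve
#'
#' Returns the fitted bell center: the added-Mg2+ concentration that
#' maximises the maximal synthesis rate.
#'
#' @param curve A [fit_bell()] result or an [response_curves()] element.
#' @return Optimum in mM added Mg2+.
#' @export
mg_optimum <- function(curve) {
  if (inherits(curve, "mg_response_curve")) curve <- curve$bell
  if (!inherits(curve, "mg_bell")) {
    stop("mg_optimum requires a fitted curve (mg_bell or mg_response_curve)")
  }
  curve$optimum
}

#' Build per-construct Mg-response curves from a rate table
#'
#' Averages replicate maximal synthesis rates per (construct, Mg, K, lysate)
#' and fits the bell curve per (construct, K, lysate). Groups with fewer
#' than 4 distinct Mg concentrations are skipped with a warning.
#'
#' @param rates data.frame from [rate_table()] (columns `construct`, `mg_mM`,
#'   `k_mM`, `replicate`, `lysate`, `max_rate`).
#' @return List of `mg_response_curve` objects, each with fields `construct`,
#'   `k_mM`, `lysate`, `points` (mg_mM, rate, sd, n), `bell`, `normalized`,
#'   `reference`.
#' @export
response_curves <- function(rates) {
  stopifnot(is.data.frame(rates),
            all(c("construct", "mg_mM", "k_mM", "max_rate") %in% names(rates)))
  if (!"lysate" %in% names(rates)) rates$lysate <- "lysate1"
  key <- interaction(rates$construct, rates$k_mM, rates$lysate, drop = TRUE)
  out <- list()
  for (grp in split(rates, key)) {
    pts <- do.call(rbind, lapply(split(grp, grp$mg_mM), function(g) {
      data.frame(mg_mM = g$mg_mM[1L], rate = mean(g$max_rate),
                 sd = stats::sd(g$max_rate), n = nrow(g))
    }))
    pts <- pts[order(pts$mg_mM), , drop = FALSE]
    rownames(pts) <- NULL
    if (nrow(pts) < 4L) {
      warning(sprintf("skipping %s at %g mM K (%s): only %d Mg concentration(s)",
                      grp$construct[1L], grp$k_mM[1L], grp$lysate[1L], nrow(pts)))
      next
    }
    curve <- structure(
      list(construct = grp$construct[1L], k_mM = grp$k_mM[1L],
           lysate = grp$lysate[1L], points = pts,
           bell = fit_bell(pts), normalized = FALSE, reference = NA_character_),
      class = "mg_response_curve"
    )
    out[[paste(curve$construct, curve$k_mM, curve$lysate, sep = "|")]] <- curve
  }
  out
}

#' @export
print.mg_response_curve <- function(x, ...) {
  cat(sprintf("<mg_response_curve> %s at %g mM K (%s)%s\n", x$construct,
              x$k_mM, x$lysate,
              if (x$normalized) sprintf(", normalized to %s", x$reference) else ""))
  print(x$bell)
  invisible(x)
}

#' @export
plot.mg_response_curve <- function(x, ...) {
  plot(x$bell, main = sprintf("%s, %g mM K", x$construct, x$k_mM), ...)
}

#' Calibrate an extract with a reference construct
#'
#' The basal free-Mg2+ level of an in vitro translation extract varies
#' between preparations, so added-Mg optima are only comparable after
#' anchoring each lysate to a reference mRNA translated over the full Mg
#' grid. The record holds the reference construct's fitted optimum and peak
#' rate for that lysate.
#'
#' @param curves [response_curves()] output (or a single curve) for one
#'   lysate.
#' @param reference Reference construct name.
#' @param k_mM Potassium level of the calibration series (default: the only
#'   K present for the reference).
#' @return Object of class `calibration_record`: `lysate`, `reference`,
#'   `k_mM`, `optimum` (mM added Mg), `peak_rate` (ALU/min).
#' @export
calibrate_extract <- function(curves, reference = "M7-Luc-M7", k_mM = NULL) {
  if (inherits(curves, "mg_response_curve")) curves <- list(curves)
  ref <- Filter(function(cv) cv$construct == reference &&
                  (is.null(k_mM) || cv$k_mM == k_mM), curves)
  if (length(ref) == 0L) {
    stop(sprintf("reference construct '%s' not found in curves", reference))
  }
  if (length(ref) > 1L) {
    stop("reference measured at several K levels; disambiguate with k_mM")
  }
  ref <- ref[[1L]]
  if (nrow(ref$points) < 4L) stop("reference curve covers too few Mg points")
  structure(
    list(lysate = ref$lysate, reference = reference, k_mM = ref$k_mM,
         optimum = mg_optimum(ref), peak_rate = ref$bell$amplitude),
    class = "calibration_record"
  )
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("<calibration_record> %s: %s optimum %.3f mM added Mg, peak %.4g ALU/min\n",
              x$lysate, x$reference, x$optimum, x$peak_rate))
  invisible(x)
}

#' Normalise response curves to a reference peak rate
#'
#' Divides every rate by the calibration record's reference peak rate, so
#' the reference construct's value at its magnesium optimum becomes 1.
#' Curves already normalised to the same reference are returned unchanged
#' (idempotent). Lysates must match.
#'
#' @param curves [response_curves()] output (a list) or a single curve.
#' @param calibration A [calibrate_extract()] record from the same lysate.
#' @return Curves with scaled points and refitted bells, `normalized = TRUE`.
#' @export
normalize_to_reference <- function(curves, calibration) {
  stopifnot(inherits(calibration, "calibration_record"))
  single <- inherits(curves, "mg_response_curve")
  if (single) curves <- list(curves)
  if (calibration$peak_rate <= 0) stop("reference peak rate must be positive")
  out <- lapply(curves, function(cv) {
    if (cv$lysate != calibration$lysate) {
      stop(sprintf("lysate mismatch: curve '%s' vs calibration '%s'",
                   cv$lysate, calibration$lysate))
    }
    if (isTRUE(cv$normalized) && identical(cv$reference, calibration$reference)) {
      return(cv)
    }
    cv$points$rate <- cv$points$rate / calibration$peak_rate
    cv$points$sd <- cv$points$sd / calibration$peak_rate
    cv$bell <- fit_bell(cv$points)
    cv$normalized <- TRUE
    cv$reference <- calibration$reference
    cv
  })
  if (single) out[[1L]] else out
}

#' Signed difference of two magnesium optima
#'
#' `mg_optimum(curve_a) - mg_optimum(curve_b)`. The assay design compares
#' optima only within a potassium level, so differing K is an error.
#'
#' @param curve_a,curve_b Fitted `mg_response_curve` objects.
#' @return Difference in mM added Mg2+ (a - b).
#' @export
compare_optima <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "mg_response_curve"),
            inherits(curve_b, "mg_response_curve"))
  if (curve_a$k_mM != curve_b$k_mM) {
    stop("optima comparison is undefined across different K levels")
  }
  mg_optimum(curve_a) - mg_optimum(curve_b)
}

#' Dual-luciferase normalisation
#'
#' Firefly reporter activity divided by the co-transfected Renilla activity
#' (transfection-efficiency control).
#'
#' @param firefly Firefly luciferase activity (vectorised).
#' @param renilla Renilla luciferase activity, strictly positive.
#' @return `firefly / renilla`.
#' @export
normalize_dual_reporter <- function(firefly, renilla) {
  if (any(renilla <= 0)) stop("renilla activity must be positive")
  firefly / renilla
}
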