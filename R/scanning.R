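#' Parameters of the leaky-scanning / reinitiation model
#'
#' Bundles every parameter of the cap-dependent loading + start-codon
#' selection model. The model factorises reporter synthesis flux as
#' `loading(Mg, K) * transmission(Mg)`:
#'
#' * **Loading**: the rate at which 43S subunits are loaded onto the cap is a
#'   bell-shaped function of added Mg2+ whose center moves with added K+
#'   (`center(K) = intercept + slope * K`). The bell is a two-sided Gaussian:
#'   `amp * exp(-(Mg - center)^2 / (2 * width^2))` with `width = width_lo`
#'   below the center and `width_hi` above it. The two widths let the profile
#'   fall faster on the high-Mg side, as the printed dose-response data
#'   require. Uncapped mRNAs load at a fraction `uncapped_scale` of the
#'   capped rate.
#' * **Start-codon selection**: each AUG's initiation probability depends on
#'   its Kozak context class through a logistic in added Mg,
#'   `p(Mg) = floor + (ceil - floor) * plogis((Mg - mid) / steep)`. Strong
#'   contexts are flat by construction (their probability varies by < 0.05
#'   over 0.2-1.4 mM); suboptimal contexts initiate more readily at high Mg.
#' * **Reinitiation**: after terminating a short uORF that does not overlap
#'   the reporter ORF, a ribosome resumes scanning with Mg-independent
#'   probability `reinit_prob`.
#'
#' @param loading_amp Positive rate scale (ALU/min equivalent).
#' @param loading_center Numeric `c(intercept, slope)`: affine map from added
#'   K (mM) to the loading-bell center (mM added Mg).
#' @param loading_width Numeric `c(lo, hi)`: bell widths (mM) below/above the
#'   center; a single value is used for both sides.
#' @param ctx Named list with elements `strong`, `adequate`, `weak`, each a
#'   numeric vector `c(floor, ceil, mid, steep)` of the class logistic.
#' @param reinit_prob Probability of reinitiation after a non-overlapping
#'   uORF, in \[0, 1\].
#' @param uncapped_scale Loading scale for uncapped mRNA, in \[0, 1\].
#' @return Object of class `scanning_params`.
#' @seealso [scanning_preset()] for the packaged fitted parameter set.
#' @export
scanning_params <- function(loading_amp = 100,
                            loading_center = c(intercept = 0.7, slope = 1 / 300),
                            loading_width = c(lo = 0.55, hi = 0.3),
                            ctx = list(
                              strong = c(floor = 0.6, ceil = 0.6, mid = 0.8, steep = 10),
                              adequate = c(floor = 0.02, ceil = 0.97, mid = 0.73, steep = 0.04),
                              weak = c(floor = 0.005, ceil = 0.4, mid = 0.9, steep = 0.2)
                            ),
                            reinit_prob = 0.15,
                            uncapped_scale = 0.05) {
  if (length(loading_width) == 1L) loading_width <- c(loading_width, loading_width)
  loading_width <- stats::setNames(as.numeric(loading_width), c("lo", "hi"))
  loading_center <- stats::setNames(as.numeric(loading_center), c("intercept", "slope"))
  if (!is.numeric(loading_amp) || loading_amp <= 0) {
    stop("loading_amp must be positive")
  }
  if (any(loading_width <= 0)) stop("loading widths must be positive")
  if (!all(c("strong", "adequate", "weak") %in% names(ctx))) {
    stop("ctx must define classes strong, adequate and weak")
  }
  for (cl in c("strong", "adequate", "weak")) {
    v <- stats::setNames(as.numeric(ctx[[cl]]), c("floor", "ceil", "mid", "steep"))
    if (v["floor"] < 0 || v["ceil"] > 1 || v["floor"] > v["ceil"]) {
      stop(sprintf("class '%s': need 0 <= floor <= ceil <= 1", cl))
    }
    if (v["steep"] <= 0) stop(sprintf("class '%s': steep must be positive", cl))
    ctx[[cl]] <- v
  }
  obj <- structure(
    list(loading_amp = as.numeric(loading_amp),
         loading_center = loading_center,
         loading_width = loading_width,
         ctx = ctx,
         reinit_prob = as.numeric(reinit_prob),
         uncapped_scale = as.numeric(uncapped_scale)),
    class = "scanning_params"
  )
  if (obj$reinit_prob < 0 || obj$reinit_prob > 1) {
    stop("reinit_prob must lie in [0, 1]")
  }
  if (obj$uncapped_scale < 0 || obj$uncapped_scale > 1) {
    stop("uncapped_scale must lie in [0, 1]")
  }
  ps <- site_init_prob(obj, "strong", seq(0.2, 1.4, by = 0.05))
  if (diff(range(ps)) >= 0.05) {
    stop("strong-class probability must vary by < 0.05 over 0.2-1.4 mM Mg")
  }
  obj
}

#' @export
print.scanning_params <- function(x, ...) {
  cat("<scanning_params>\n")
  cat(sprintf("  loading: amp %.4g, center(K) = %.4g + %.5g * K mM, width lo/hi %.3g/%.3g mM\n",
              x$loading_amp, x$loading_center["intercept"],
              x$loading_center["slope"], x$loading_width["lo"],
              x$loading_width["hi"]))
  for (cl in names(x$ctx)) {
    v <- x$ctx[[cl]]
    cat(sprintf("  p_%s(Mg): %.3g -> %.3g, mid %.3g mM, steep %.3g mM\n",
                cl, v["floor"], v["ceil"], v["mid"], v["steep"]))
  }
  cat(sprintf("  reinit_prob %.3g, uncapped_scale %.3g\n",
              x$reinit_prob, x$uncapped_scale))
  invisible(x)
}

#' Cap-dependent 43S loading rate
#'
#' Two-sided Gaussian bell in added Mg whose center is an affine function of
#' added K. At `Mg == center(K)` the capped rate equals `loading_amp`.
#'
#' @param params A [scanning_params()].
#' @param Mg Added Mg2+ (mM); vectorised.
#' @param K Added K+ (mM).
#' @param capped Is the mRNA capped? Uncapped mRNA loads at
#'   `uncapped_scale` times the capped rate.
#' @return Loading rate(s), same length as `Mg`.
#' @export
loading_rate <- function(params, Mg, K, capped = TRUE) {
  stopifnot(inherits(params, "scanning_params"))
  if (any(Mg <= 0)) stop("Mg must be positive")
  if (any(K < 0)) stop("K must be nonnegative")
  center <- params$loading_center["intercept"] + params$loading_center["slope"] * K
  w <- ifelse(Mg < center, params$loading_width["lo"], params$loading_width["hi"])
  r <- params$loading_amp * exp(-(Mg - center)^2 / (2 * w^2))
  if (!capped) r <- r * params$uncapped_scale
  unname(r)
}

#' Initiation probability at an AUG of a given context class
#'
#' Logistic in added Mg between the class floor and ceiling; monotone
#' nondecreasing in Mg.
#'
#' @param params A [scanning_params()].
#' @param context_cls `"strong"`, `"adequate"` or `"weak"`.
#' @param Mg Added Mg2+ (mM); vectorised.
#' @return Probability in \[floor, ceil\].
#' @export
site_init_prob <- function(params, context_cls, Mg) {
  stopifnot(inherits(params, "scanning_params"))
  if (any(Mg <= 0)) stop("Mg must be positive")
  if (!context_cls %in% names(params$ctx)) {
    stop(sprintf("unknown context class '%s'", context_cls))
  }
  v <- params$ctx[[context_cls]]
  unname(v["floor"] + (v["ceil"] - v["floor"]) *
           stats::plogis((Mg - v["mid"]) / v["steep"]))
}

#' Define a reporter construct over an annotated leader
#'
#' A construct is a leader annotation plus the mutations of the reporter
#' design: start-codon knockouts (AUG -> AUC), stop-codon knockouts
#' (UGA -> CGA, which extends the uORF into the reporter ORF), and the choice
#' of which AUG's downstream ORF carries the measured reporter (the main AUG
#' by default; an uAUG for uORF-fusion reporters).
#'
#' @param name Construct name.
#' @param annotation A [annotate_leader()] result.
#' @param knocked_out_augs Integer positions of knocked-out uAUGs.
#' @param knocked_out_stops Integer `stop_start` positions of knocked-out
#'   uORF stop codons.
#' @param reporter_at Position of the AUG initiating the measured reporter.
#' @param capped Is the mRNA capped?
#' @return Object of class `construct_spec`.
#' @export
construct_spec <- function(name, annotation, knocked_out_augs = integer(),
                           knocked_out_stops = integer(),
                           reporter_at = NULL, capped = TRUE) {
  stopifnot(inherits(annotation, "leader_annotation"))
  u <- annotation$uorfs
  if (is.null(reporter_at)) reporter_at <- annotation$leader$main_start
  reporter_at <- as.integer(reporter_at)
  knocked_out_augs <- as.integer(knocked_out_augs)
  knocked_out_stops <- as.integer(knocked_out_stops)
  if (!all(knocked_out_augs %in% u$start)) {
    stop("knocked_out_augs must be uAUG start positions of the annotation")
  }
  if (!all(knocked_out_stops %in% u$stop_start[!is.na(u$stop_start)])) {
    stop("knocked_out_stops must be uORF stop positions of the annotation")
  }
  if (!reporter_at %in% c(u$start, annotation$leader$main_start)) {
    stop("reporter_at must be an AUG of the annotation")
  }
  structure(
    list(name = as.character(name), annotation = annotation,
         knocked_out_augs = knocked_out_augs,
         knocked_out_stops = knocked_out_stops,
         reporter_at = reporter_at, capped = isTRUE(capped)),
    class = "construct_spec"
  )
}

#' @export
print.construct_spec <- function(x, ...) {
  cat(sprintf("<construct_spec> %s: reporter AUG at %d%s\n", x$name,
              x$reporter_at, if (x$capped) "" else " (uncapped)"))
  if (length(x$knocked_out_augs)) {
    cat("  uAUG knockouts:", paste(x$knocked_out_augs, collapse = ", "), "\n")
  }
  if (length(x$knocked_out_stops)) {
    cat("  stop knockouts:", paste(x$knocked_out_stops, collapse = ", "), "\n")
  }
  invisible(x)
}

# Scanning path of a construct: the uAUG sites upstream of the reporter AUG
# that remain after knockouts, each with context class and whether its uORF
# sequesters ribosomes from the reporter ORF (native overlap, or stop
# knockout, or no in-frame stop before the reporter AUG).
scan_path <- function(construct) {
  u <- construct$annotation$uorfs
  up <- u[u$start < construct$reporter_at &
            !(u$start %in% construct$knocked_out_augs), , drop = FALSE]
  if (nrow(up)) {
    up <- up[order(up$start), , drop = FALSE]
    up$sequesters <- is.na(up$stop_start) |
      (up$stop_start %in% construct$knocked_out_stops) |
      (!is.na(up$stop_start) & up$stop_start + 2L >= construct$reporter_at)
  } else {
    up$sequesters <- logical(0)
  }
  rep_cls <- if (construct$reporter_at == construct$annotation$leader$main_start) {
    construct$annotation$main_context$cls
  } else {
    u$cls[match(construct$reporter_at, u$start)]
  }
  list(sites = up, reporter_cls = rep_cls)
}

#' Closed-form reporter flux of the scanning model
#'
#' Propagates a unit mass of loaded 43S subunits 5'->3' across the construct's
#' active upstream AUGs. At each site the mass initiates with the site's
#' context- and Mg-dependent probability; initiation at a uORF that overlaps
#' the reporter ORF removes the ribosome, initiation at a non-overlapping
#' uORF returns it to scanning with probability `reinit_prob`. Mass reaching
#' the reporter AUG initiates there with that site's probability.
#' `reporter_flux = loading_rate * initiated mass`.
#'
#' @param construct A [construct_spec()].
#' @param params A [scanning_params()].
#' @param Mg Added Mg2+ (mM), scalar.
#' @param K Added K+ (mM), scalar.
#' @return Object of class `flux_result`: list with `construct`, `Mg`, `K`,
#'   `loading`, `reporter_flux` and `branch_probabilities` (named vector
#'   summing to 1: one sequestration/dissociation outcome per upstream uORF,
#'   `init_reporter`, `leaky_through`).
#' @export
closed_form_flux <- function(construct, params, Mg, K) {
  stopifnot(inherits(construct, "construct_spec"),
            inherits(params, "scanning_params"),
            length(Mg) == 1L, length(K) == 1L)
  path <- scan_path(construct)
  q <- params$reinit_prob
  mass <- 1
  branches <- numeric(0)
  if (nrow(path$sites)) {
    for (i in seq_len(nrow(path$sites))) {
      s <- path$sites[i, ]
      p <- site_init_prob(params, s$cls, Mg)
      init <- mass * p
      if (s$sequesters) {
        branches[sprintf("init_uORF_%d", s$start)] <- init
        mass <- mass - init
      } else {
        branches[sprintf("dissociate_after_uORF_%d", s$start)] <- init * (1 - q)
        mass <- mass - init * (1 - q)
      }
    }
  }
  p_rep <- site_init_prob(params, path$reporter_cls, Mg)
  init_rep <- mass * p_rep
  branches["init_reporter"] <- init_rep
  branches["leaky_through"] <- mass - init_rep
  loading <- loading_rate(params, Mg, K, capped = construct$capped)
  structure(
    list(construct = construct$name, Mg = Mg, K = K, loading = loading,
         reporter_flux = loading * init_rep,
         branch_probabilities = branches),
    class = "flux_result"
  )
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> %s at %.2f mM Mg, %g mM K: flux %.4g (loading %.4g)\n",
              x$construct, x$Mg, x$K, x$reporter_flux, x$loading))
  bp <- x$branch_probabilities
  for (nm in names(bp)) cat(sprintf("  %-28s %.4g\n", nm, bp[[nm]]))
  invisible(x)
}

#' Reporter flux over a grid of Mg concentrations
#'
#' Convenience wrapper around [closed_form_flux()].
#'
#' @inheritParams closed_form_flux
#' @param Mg Vector of added Mg2+ concentrations (mM).
#' @return data.frame with columns `construct`, `Mg`, `K`, `flux`.
#' @export
flux_profile <- function(construct, params, Mg, K) {
  path <- scan_path(construct)
  q <- params$reinit_prob
  mass <- rep(1, length(Mg))
  if (nrow(path$sites)) {
    for (i in seq_len(nrow(path$sites))) {
      s <- path$sites[i, ]
      p <- site_init_prob(params, s$cls, Mg)
      mass <- if (s$sequesters) mass * (1 - p) else mass * (1 - p * (1 - q))
    }
  }
  init_rep <- mass * site_init_prob(params, path$reporter_cls, Mg)
  flux <- loading_rate(params, Mg, K, capped = construct$capped) * init_rep
  data.frame(construct = construct$name, Mg = Mg, K = K, flux = flux,
             stringsAsFactors = FALSE)
}

#' Monte-Carlo twin of the closed-form flux
#'
#' Simulates individual 43S subunits along the scanning path with Bernoulli
#' draws at every decision point. The empirical branch frequencies converge
#' to the closed-form branch probabilities.
#'
#' @inheritParams closed_form_flux
#' @param n_ribosomes Number of simulated scanning subunits.
#' @param seed Integer RNG seed (local to the simulation).
#' @return A `flux_result` whose `branch_probabilities` are empirical
#'   frequencies; `n` records the simulation size.
#' @export
simulate_scanning <- function(construct, params, Mg, K, n_ribosomes = 10000L,
                              seed = 1L) {
  stopifnot(n_ribosomes >= 1L)
  path <- scan_path(construct)
  q <- params$reinit_prob
  n <- as.integer(n_ribosomes)
  counts <- numeric(0)
  res <- withr::with_seed(seed, {
    active <- rep(TRUE, n)
    if (nrow(path$sites)) {
      for (i in seq_len(nrow(path$sites))) {
        s <- path$sites[i, ]
        p <- site_init_prob(params, s$cls, Mg)
        init <- active & (stats::runif(n) < p)
        if (s$sequesters) {
          counts[sprintf("init_uORF_%d", s$start)] <- sum(init)
          active[init] <- FALSE
        } else {
          lost <- init & (stats::runif(n) >= q)
          counts[sprintf("dissociate_after_uORF_%d", s$start)] <- sum(lost)
          active[lost] <- FALSE
        }
      }
    }
    p_rep <- site_init_prob(params, path$reporter_cls, Mg)
    init_rep <- active & (stats::runif(n) < p_rep)
    counts["init_reporter"] <- sum(init_rep)
    counts["leaky_through"] <- sum(active & !init_rep)
    counts
  })
  loading <- loading_rate(params, Mg, K, capped = construct$capped)
  structure(
    list(construct = construct$name, Mg = Mg, K = K, loading = loading,
         reporter_flux = loading * res[["init_reporter"]] / n,
         branch_probabilities = res / n, n = n),
    class = "flux_result"
  )
}

#' Mutation operators for reporter constructs
#'
#' `aug_knockout(pos)` silences the uAUG at `pos` (AUG -> AUC);
#' `stop_knockout(pos)` removes the uORF stop codon starting at `pos`
#' (UGA -> CGA), extending the uORF into the reporter ORF;
#' `fuse_reporter(pos)` fuses the measured reporter to the AUG at `pos`.
#' Apply with [apply_mutation()].
#'
#' @param pos Target position (1-based, the first base of the codon).
#' @return Object of class `scan_mutation`.
#' @export
aug_knockout <- function(pos) {
  structure(list(pos = as.integer(pos)), class = c("aug_knockout", "scan_mutation"))
}

#' @rdname aug_knockout
#' @export
stop_knockout <- function(pos) {
  structure(list(pos = as.integer(pos)), class = c("stop_knockout", "scan_mutation"))
}

#' @rdname aug_knockout
#' @export
fuse_reporter <- function(pos) {
  structure(list(pos = as.integer(pos)), class = c("fuse_reporter", "scan_mutation"))
}

#' Apply a mutation operator to a construct
#'
#' Returns a new [construct_spec()]; the input is unchanged.
#'
#' @param construct A [construct_spec()].
#' @param mutation A [aug_knockout()], [stop_knockout()] or [fuse_reporter()].
#' @param name Optional new construct name; defaults to the old name with the
#'   mutation appended.
#' @return A new `construct_spec`.
#' @export
apply_mutation <- function(construct, mutation, name = NULL) {
  stopifnot(inherits(construct, "construct_spec"),
            inherits(mutation, "scan_mutation"))
  u <- construct$annotation$uorfs
  kind <- class(mutation)[1L]
  tag <- sprintf("%s(%d)", kind, mutation$pos)
  if (is.null(name)) name <- paste0(construct$name, "+", tag)
  args <- list(name = name, annotation = construct$annotation,
               knocked_out_augs = construct$knocked_out_augs,
               knocked_out_stops = construct$knocked_out_stops,
               reporter_at = construct$reporter_at, capped = construct$capped)
  if (kind == "aug_knockout") {
    if (!mutation$pos %in% u$start) {
      stop(sprintf("no uAUG at position %d", mutation$pos))
    }
    args$knocked_out_augs <- union(args$knocked_out_augs, mutation$pos)
  } else if (kind == "stop_knockout") {
    if (!mutation$pos %in% u$stop_start[!is.na(u$stop_start)]) {
      stop(sprintf("no uORF stop codon at position %d", mutation$pos))
    }
    args$knocked_out_stops <- union(args$knocked_out_stops, mutation$pos)
  } else if (kind == "fuse_reporter") {
    if (!mutation$pos %in% c(u$start, construct$annotation$leader$main_start)) {
      stop(sprintf("no AUG at position %d", mutation$pos))
    }
    args$reporter_at <- mutation$pos
  } else {
    stop("unknown mutation kind")
  }
  do.call(construct_spec, args)
}
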