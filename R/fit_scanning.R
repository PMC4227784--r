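#' Magnesium optimum of a construct's closed-form flux profile
#'
#' Evaluates the scanning model's reporter flux over an added-Mg grid and
#' returns the fitted bell center, i.e. the model's prediction of the
#' experimentally measured magnesium optimum. (Noise-free kinetic traces
#' processed by the full pipeline give exactly this value: the windowed-slope
#' statistic is proportional to flux, and the bell center is scale
#' invariant.)
#'
#' @param construct A [construct_spec()].
#' @param params A [scanning_params()].
#' @param K Added K+ (mM).
#' @param mg_grid Added-Mg grid (mM), default 0.2-1.4 by 0.2.
#' @return Optimum in mM added Mg.
#' @export
flux_optimum <- function(construct, params, K, mg_grid = seq(0.2, 1.4, by = 0.2)) {
  prof <- flux_profile(construct, params, mg_grid, K)
  fit_bell(mg = prof$Mg, rate = prof$flux)$optimum
}

#' The study's printed quantitative observations as a constraint set
#'
#' Encodes the observations the scanning model must reproduce jointly:
#'
#' * uAUG1 knockout relieves inhibition of main-ORF translation at least
#'   2-fold at the wild-type optimum;
#' * lowering added Mg from 1.4 to 0.6 mM (60 mM K) raises flux 2-fold for
#'   the leader without uAUGs but 10-fold for the wild-type leader;
#' * the uORF2 stop-codon knockout halves translation with an unshifted
#'   optimum;
#' * the uORF-free (beta-globin-like) leader's optimum exceeds the wild
#'   type's by 0.4 mM at 120 mM K and by 0.2 mM at 60 mM K;
#' * the wild-type optimum is 0.8 mM added Mg at 60 mM K;
#' * the wild-type optimum is potassium-invariant (spread <= 0.1 mM over
#'   60-150 mM K) while the uORF-free leader's optimum increases with K;
#' * the uORF2 fusion reporter has a higher optimum than the main ORF.
#'
#' @return List of constraint records for [fit_scanning_params()].
#' @export
paper_constraints <- function() {
  list(
    list(id = "uaug1-knockout-fold", type = "flux_ratio", cmp = "ge",
         target = 2, weight = 100,
         num = "1AUC-Luc-M7", den = "M7-Luc-M7",
         mg_num = "wt_optimum", mg_den = "wt_optimum", k = 60,
         description = "1AUC/WT flux at the WT optimum (>= 2)"),
    list(id = "no-uorf-lowmg-fold", type = "flux_ratio", cmp = "eq",
         target = 2, weight = 100,
         num = "1AUC2AUC-Luc-M7", den = "1AUC2AUC-Luc-M7",
         mg_num = 0.6, mg_den = 1.4, k = 60,
         description = "1AUC2AUC flux gain 1.4 -> 0.6 mM Mg (2x)"),
    list(id = "wt-lowmg-fold", type = "flux_ratio", cmp = "eq",
         target = 10, weight = 100,
         num = "M7-Luc-M7", den = "M7-Luc-M7",
         mg_num = 0.6, mg_den = 1.4, k = 60,
         description = "WT flux gain 1.4 -> 0.6 mM Mg (10x)"),
    list(id = "stop-knockout-fold", type = "flux_ratio", cmp = "eq",
         target = 2, weight = 100,
         num = "M7-Luc-M7", den = "2stopCGA-Luc-M7",
         mg_num = "wt_optimum", mg_den = "wt_optimum", k = 60,
         description = "WT/2stopCGA flux at the WT optimum (2x)"),
    list(id = "stop-knockout-optimum-match", type = "optima_match", cmp = "le",
         target = 0.05, weight = 4,
         a = "M7-Luc-M7", b = "2stopCGA-Luc-M7", k = 60,
         description = "|WT - 2stopCGA| optimum difference (<= 0.05 mM)"),
    list(id = "beta-delta-120K", type = "optimum_delta", cmp = "eq",
         target = 0.4, weight = 4,
         a = "beta-Luc-M7", b = "M7-Luc-M7", k = 120,
         description = "beta - WT optimum at 120 mM K (+0.4 mM)"),
    list(id = "beta-delta-60K", type = "optimum_delta", cmp = "eq",
         target = 0.2, weight = 4,
         a = "beta-Luc-M7", b = "M7-Luc-M7", k = 60,
         description = "beta - WT optimum at 60 mM K (+0.2 mM)"),
    list(id = "wt-optimum-60K", type = "optimum", cmp = "eq",
         target = 0.8, weight = 400,
         a = "M7-Luc-M7", k = 60,
         description = "WT optimum at 60 mM K (0.8 mM added Mg)"),
    list(id = "wt-optimum-K-invariance", type = "optimum_spread", cmp = "le",
         target = 0.1, weight = 4,
         a = "M7-Luc-M7", k_levels = c(60, 90, 120, 150),
         description = "WT optimum spread over K 60-150 mM (<= 0.1 mM)"),
    list(id = "beta-optimum-K-monotone", type = "optimum_monotone", cmp = "ge",
         target = 0.02, weight = 0.5,
         a = "beta-Luc-M7", k_levels = c(60, 90, 120, 150),
         description = "beta optimum strictly increasing in K"),
    list(id = "uorf2-higher-optimum", type = "optimum_delta", cmp = "ge",
         target = 0.1, weight = 0.5,
         a = "2ndLuc-M7", b = "M7-Luc-M7", k = 60,
         description = "uORF2 fusion optimum above the WT optimum")
  )
}

# evaluate the observable of one constraint; `opt` is a memoising accessor
# opt(construct_name, K) -> fitted optimum
eval_constraint_obs <- function(con, constructs, params, opt, mg_grid) {
  mg_at <- function(mg, k) {
    if (identical(mg, "wt_optimum")) opt("M7-Luc-M7", k) else as.numeric(mg)
  }
  switch(con$type,
    flux_ratio = {
      num <- closed_form_flux(constructs[[con$num]], params,
                              mg_at(con$mg_num, con$k), con$k)$reporter_flux
      den <- closed_form_flux(constructs[[con$den]], params,
                              mg_at(con$mg_den, con$k), con$k)$reporter_flux
      num / den
    },
    optimum_delta = opt(con$a, con$k) - opt(con$b, con$k),
    optimum = opt(con$a, con$k),
    optima_match = abs(opt(con$a, con$k) - opt(con$b, con$k)),
    optimum_spread = {
      os <- vapply(con$k_levels, function(k) opt(con$a, k), numeric(1L))
      diff(range(os))
    },
    optimum_monotone = {
      os <- vapply(con$k_levels, function(k) opt(con$a, k), numeric(1L))
      min(diff(os))
    },
    stop(sprintf("unknown constraint type '%s'", con$type))
  )
}

# signed/hinged residual on a comparable scale across constraint kinds:
# ratios on the log scale, optima in units of 0.1 mM
constraint_residual <- function(con, obs) {
  if (!is.finite(obs)) return(1e3)
  ratio_like <- con$type == "flux_ratio"
  if (con$cmp == "eq") {
    if (ratio_like) log(obs / con$target) else (obs - con$target) / 0.1
  } else if (con$cmp == "ge") {
    if (ratio_like) max(0, log(1.05 * con$target / obs))
    else max(0, (con$target + 0.02 - obs) / 0.1)
  } else {  # le
    if (ratio_like) max(0, log(obs / (0.95 * con$target)))
    else max(0, (obs - (con$target - 0.02)) / 0.1)
  }
}

#' Residual report of a parameter set against the printed observations
#'
#' @param params A [scanning_params()].
#' @param constraints Constraint set, default [paper_constraints()].
#' @param constructs Construct panel, default [paper_constructs()].
#' @param mg_grid Added-Mg grid used for fitted optima.
#' @return data.frame: constraint id, description, observed value, target,
#'   comparison, residual (0 means satisfied for one-sided constraints).
#' @export
constraint_residuals <- function(params, constraints = paper_constraints(),
                                 constructs = paper_constructs(),
                                 mg_grid = seq(0.2, 1.4, by = 0.2)) {
  cache <- new.env(parent = emptyenv())
  opt <- function(cn, k) {
    key <- paste(cn, k, sep = "@")
    if (is.null(cache[[key]])) {
      cache[[key]] <- flux_optimum(constructs[[cn]], params, k, mg_grid)
    }
    cache[[key]]
  }
  rows <- lapply(constraints, function(con) {
    obs <- tryCatch(
      eval_constraint_obs(con, constructs, params, opt, mg_grid),
      error = function(e) NA_real_)
    data.frame(id = con$id, description = con$description,
               observed = obs, target = con$target, cmp = con$cmp,
               weight = con$weight,
               residual = constraint_residual(con, if (is.na(obs)) Inf else obs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# theta <-> scanning_params mapping for the optimizer; fixed aspects:
# loading_amp 100, strong class flat, weak class at defaults, uncapped 0.05
theta_to_params <- function(th) {
  slope <- exp(th[["log_slope"]])
  wl <- exp(th[["log_wl"]])
  wh <- exp(th[["log_wh"]])
  q <- stats::plogis(th[["logit_q"]])
  p_strong <- stats::plogis(th[["logit_p_strong"]])
  u0 <- stats::plogis(th[["logit_u0"]])
  u1 <- u0 + (1 - u0) * stats::plogis(th[["logit_u1gap"]])
  scanning_params(
    loading_amp = 100,
    loading_center = c(intercept = th[["c60"]] - slope * 60, slope = slope),
    loading_width = c(lo = wl, hi = wh),
    ctx = list(
      strong = c(floor = p_strong, ceil = p_strong, mid = 0.8, steep = 10),
      adequate = c(floor = u0, ceil = u1, mid = th[["m_adequate"]],
                   steep = exp(th[["log_s_adequate"]])),
      weak = c(floor = 0.005, ceil = 0.4, mid = 0.9, steep = 0.2)
    ),
    reinit_prob = q,
    uncapped_scale = 0.05
  )
}

params_to_theta <- function(p) {
  a <- p$ctx$adequate
  u0 <- a[["floor"]]
  u1 <- a[["ceil"]]
  c(c60 = unname(p$loading_center[["intercept"]] + 60 * p$loading_center[["slope"]]),
    log_slope = log(unname(p$loading_center[["slope"]])),
    log_wl = log(unname(p$loading_width[["lo"]])),
    log_wh = log(unname(p$loading_width[["hi"]])),
    logit_q = stats::qlogis(p$reinit_prob),
    logit_p_strong = stats::qlogis(p$ctx$strong[["floor"]]),
    logit_u0 = stats::qlogis(u0),
    logit_u1gap = stats::qlogis((u1 - u0) / (1 - u0)),
    m_adequate = unname(a[["mid"]]),
    log_s_adequate = log(unname(a[["steep"]])))
}

#' Fit scanning-model parameters to the printed observations
#'
#' Minimises the weighted sum of squared residuals (log scale for flux
#' ratios, mM scale for optima; one-sided constraints enter as hinge
#' penalties) over the free parameters of the model: loading-bell center at
#' 60 mM K, its K slope, the two bell widths, the adequate-class logistic
#' (floor, ceiling, midpoint, steepness), the reinitiation probability and
#' the strong-class initiation probability. A coarse random multi-start
#' (Latin-style perturbations of `start`, fixed seed) is refined by
#' Nelder-Mead.
#'
#' @param constraints Constraint set, default [paper_constraints()].
#' @param constructs Construct panel, default [paper_constructs()].
#' @param start Starting [scanning_params()].
#' @param n_starts Number of random restarts around `start`.
#' @param seed RNG seed for the restarts.
#' @param maxit Nelder-Mead iteration budget per start.
#' @param mg_grid Added-Mg grid for fitted optima.
#' @return Object of class `scanning_fit`: `params` (fitted
#'   [scanning_params()]), `residuals` (as [constraint_residuals()]),
#'   `objective`, `convergence`.
#' @export
fit_scanning_params <- function(constraints = paper_constraints(),
                                constructs = paper_constructs(),
                                start = scanning_preset("paper2014"),
                                n_starts = 3L, seed = 1L, maxit = 1500L,
                                mg_grid = seq(0.2, 1.4, by = 0.2)) {
  if (!length(constraints)) stop("constraint set must be nonempty")
  objective <- function(th) {
    p <- tryCatch(theta_to_params(th), error = function(e) NULL)
    if (is.null(p)) return(1e6)
    res <- tryCatch(
      constraint_residuals(p, constraints, constructs, mg_grid),
      error = function(e) NULL)
    if (is.null(res) || anyNA(res$residual)) return(1e6)
    sum(res$weight * res$residual^2)
  }
  th0 <- params_to_theta(start)
  starts <- list(th0)
  if (n_starts > 1L) {
    extra <- withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i) {
        th0 + stats::rnorm(length(th0), 0, 0.15)
      })
    })
    starts <- c(starts, extra)
  }
  best <- NULL
  for (th in starts) {
    fit <- stats::optim(th, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish
  best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-14))
  params <- theta_to_params(best$par)
  structure(
    list(params = params,
         residuals = constraint_residuals(params, constraints, constructs,
                                          mg_grid),
         objective = best$value, convergence = best$convergence,
         counts = best$counts),
    class = "scanning_fit"
  )
}

#' @export
print.scanning_fit <- function(x, ...) {
  cat(sprintf("<scanning_fit> objective %.3g (%s)\n", x$objective,
              if (x$convergence == 0) "converged" else
                sprintf("optim convergence code %d", x$convergence)))
  print(x$params)
  invisible(x)
}

#' @export
summary.scanning_fit <- function(object, ...) {
  cat(sprintf("Scanning-model fit: objective %.4g, %d constraints\n",
              object$objective, nrow(object$residuals)))
  df <- object$residuals
  df$observed <- signif(df$observed, 4)
  print(df[, c("id", "observed", "target", "cmp", "residual")],
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.scanning_fit <- function(object, ...) {
  params_to_theta(object$params)
}
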