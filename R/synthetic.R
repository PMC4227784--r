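#' Specify the geometry of a synthetic 5'-leader
#'
#' A geometry specification pins down everything [make_leader_fixture()] must
#' reproduce exactly: the main-ORF start, the upstream AUG positions, each
#' uORF's length (AUG through stop codon, inclusive), the Kozak context class
#' to engineer at every AUG, and the GC content of the filler sequence.
#'
#' @param id Fixture identifier.
#' @param length Total sequence length (nt); must cover every uORF stop.
#' @param main_start 1-based position of the main-ORF AUG.
#' @param uaug_positions Ascending positions of the upstream AUGs (may be
#'   empty).
#' @param uorf_lengths uORF lengths in nt, one per uAUG, each divisible by 3.
#' @param uaug_contexts Context class per uAUG (`"strong"`, `"adequate"`,
#'   `"weak"`).
#' @param main_context Context class of the main AUG.
#' @param gc_target GC fraction of the filler bases.
#' @return Object of class `geometry_spec`.
#' @seealso [geometry_preset()] for packaged geometries.
#' @export
geometry_spec <- function(id, length, main_start, uaug_positions = integer(),
                          uorf_lengths = integer(),
                          uaug_contexts = rep("strong", length(uaug_positions)),
                          main_context = "strong", gc_target = 0.5) {
  length <- as.integer(length)
  main_start <- as.integer(main_start)
  uaug_positions <- as.integer(uaug_positions)
  uorf_lengths <- as.integer(uorf_lengths)
  if (length(uaug_positions) != length(uorf_lengths)) {
    stop("uaug_positions and uorf_lengths must have equal length")
  }
  if (length(uaug_contexts) != length(uaug_positions)) {
    stop("uaug_contexts must have one class per uAUG")
  }
  if (main_start < 1L || main_start > length - 2L) {
    stop("main_start must lie within the sequence")
  }
  if (any(uorf_lengths %% 3L != 0L) || any(uorf_lengths < 6L)) {
    stop("uORF lengths must be multiples of 3 and at least 6 nt")
  }
  if (is.unsorted(uaug_positions, strictly = TRUE)) {
    stop("uaug_positions must be strictly ascending")
  }
  if (any(uaug_positions >= main_start)) {
    stop("every uAUG must lie upstream of main_start")
  }
  stops <- uaug_positions + uorf_lengths - 3L
  if (any(stops + 2L > length)) {
    stop("a declared uORF stop codon falls beyond the sequence end")
  }
  cls_ok <- c("strong", "adequate", "weak")
  if (!all(uaug_contexts %in% cls_ok) || !main_context %in% cls_ok) {
    stop("context classes must be strong, adequate or weak")
  }
  # a declared stop codon of one uORF must not sit in-frame inside another
  # uORF's coding span before that uORF's own stop: unsatisfiable
  n_u <- length(uaug_positions)
  if (n_u > 1L) {
    for (i in seq_len(n_u)) {
      for (j in seq_len(n_u)) {
        if (i == j) next
        s <- stops[j]
        if (s > uaug_positions[i] && s < stops[i] &&
            (s - uaug_positions[i]) %% 3L == 0L) {
          stop(sprintf("uORF %d's stop codon is in-frame inside uORF %d: geometry unsatisfiable",
                       j, i))
        }
      }
    }
  }
  structure(
    list(id = as.character(id), length = length, main_start = main_start,
         uaug_positions = uaug_positions, uorf_lengths = uorf_lengths,
         uaug_contexts = as.character(uaug_contexts),
         main_context = main_context, gc_target = as.numeric(gc_target)),
    class = "geometry_spec"
  )
}

#' Packaged leader geometries
#'
#' * `"uorf1-paper"` / `"trpm7-mouse-like"`: a murine TRPM7-like leader read
#'   with the first uAUG 100 nt into the mRNA (position 101): uAUG1 at 101
#'   (strong context, 390-nt uORF overlapping the main ORF by 206 nt), uAUG2
#'   at 217 (adequate context, 63-nt uORF ending 5 nt upstream of the main
#'   AUG at 285), leader GC 67.5%.
#' * `"uorf2-paper"`: the same architecture shifted one base 3' (uAUG1 102,
#'   uAUG2 218, main AUG 286) -- the alternative reading of the printed
#'   offsets; uORF lengths, overlap and gap are identical.
#' * `"beta-globin-like"`: a short uORF-free leader (main AUG at 51, strong
#'   context), the classical efficient control leader.
#'
#' @param name Preset name.
#' @return A [geometry_spec()].
#' @export
geometry_preset <- function(name = c("trpm7-mouse-like", "uorf1-paper",
                                     "uorf2-paper", "beta-globin-like")) {
  name <- match.arg(name)
  switch(name,
    "uorf1-paper" = ,
    "trpm7-mouse-like" = geometry_spec(
      id = name, length = 510, main_start = 285,
      uaug_positions = c(101L, 217L), uorf_lengths = c(390L, 63L),
      uaug_contexts = c("strong", "adequate"), main_context = "strong",
      gc_target = 0.675
    ),
    "uorf2-paper" = geometry_spec(
      id = name, length = 510, main_start = 286,
      uaug_positions = c(102L, 218L), uorf_lengths = c(390L, 63L),
      uaug_contexts = c("strong", "adequate"), main_context = "strong",
      gc_target = 0.675
    ),
    "beta-globin-like" = geometry_spec(
      id = name, length = 160, main_start = 51,
      main_context = "strong", gc_target = 0.55
    )
  )
}

# context class -> engineered (-3, +4) bases
context_bases <- function(cls) {
  switch(cls,
         strong = c(minus3 = "A", plus4 = "A"),
         adequate = c(minus3 = "U", plus4 = "G"),
         weak = c(minus3 = "C", plus4 = "C"),
         stop("unknown context class"))
}

#' Generate a leader sequence with prescribed uORF geometry
#'
#' Draws filler bases at the requested GC content, writes the declared AUGs,
#' stop codons and context bases at their protected positions, then repairs
#' the filler until re-annotation reproduces the specification exactly: no
#' unintended AUG upstream of the main start, and no premature in-frame stop
#' codon inside any declared uORF. Deterministic under `seed`.
#'
#' @param spec A [geometry_spec()].
#' @param seed Integer RNG seed.
#' @return A [leader_sequence()] whose [annotate_leader()] result matches
#'   `spec`.
#' @export
make_leader_fixture <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "geometry_spec"))
  withr::with_seed(as.integer(seed), build_fixture(spec))
}

build_fixture <- function(spec) {
  n <- spec$length
  gc <- spec$gc_target
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  protected <- logical(n)
  place <- function(pos, what) {
    chars <- strsplit(what, "", fixed = TRUE)[[1L]]
    idx <- pos + seq_along(chars) - 1L
    clash <- protected[idx] & bases[idx] != chars
    if (any(clash)) {
      stop(sprintf("geometry '%s' unsatisfiable: motif clash at position %d",
                   spec$id, idx[clash][1L]))
    }
    bases[idx] <<- chars
    protected[idx] <<- TRUE
  }
  place(spec$main_start, "AUG")
  mc <- context_bases(spec$main_context)
  if (spec$main_start - 3L >= 1L) place(spec$main_start - 3L, mc[["minus3"]])
  if (spec$main_start + 3L <= n) place(spec$main_start + 3L, mc[["plus4"]])
  for (i in seq_along(spec$uaug_positions)) {
    p <- spec$uaug_positions[i]
    place(p, "AUG")
    place(p + spec$uorf_lengths[i] - 3L, "UGA")
    cb <- context_bases(spec$uaug_contexts[i])
    if (p - 3L >= 1L) place(p - 3L, cb[["minus3"]])
    if (p + 3L <= n) place(p + 3L, cb[["plus4"]])
  }

  mutate_free <- function(triplet_start, avoid) {
    idx <- triplet_start:(triplet_start + 2L)
    free <- idx[!protected[idx]]
    if (!length(free)) {
      stop(sprintf("geometry '%s' unsatisfiable: cannot repair codon at %d",
                   spec$id, triplet_start))
    }
    i <- free[1L]
    repl <- setdiff(c("C", "G", "A"), c(bases[i], avoid))
    bases[i] <<- repl[1L]
  }

  declared_stops <- spec$uaug_positions + spec$uorf_lengths - 3L
  for (iter in 1:300) {
    dirty <- FALSE
    seqstr <- paste(bases, collapse = "")
    # unintended upstream AUGs
    hits <- gregexpr("(?=AUG)", seqstr, perl = TRUE)[[1L]]
    hits <- as.integer(hits[hits > 0L])
    bad <- setdiff(hits[hits < spec$main_start], spec$uaug_positions)
    if (length(bad)) {
      # break the G (never protected unless part of a declared motif)
      mutate_free(bad[1L], avoid = c("U", "G"))
      dirty <- TRUE
    }
    if (!dirty) {
      # premature in-frame stops inside declared uORFs
      for (i in seq_along(spec$uaug_positions)) {
        p <- spec$uaug_positions[i]
        first_stop <- find_inframe_stop(seqstr, p)
        if (!is.na(first_stop) && first_stop < declared_stops[i]) {
          mutate_free(first_stop, avoid = c("U"))
          dirty <- TRUE
          break
        }
      }
    }
    if (!dirty) break
  }
  leader <- leader_sequence(paste(bases, collapse = ""), spec$main_start,
                            id = spec$id)
  verify_fixture(leader, spec)
  leader
}

# re-annotate and require exact agreement with the geometry spec
verify_fixture <- function(leader, spec) {
  ann <- annotate_leader(leader)
  u <- ann$uorfs
  ok <- nrow(u) == length(spec$uaug_positions) &&
    identical(u$start, spec$uaug_positions) &&
    identical(u$length_nt, spec$uorf_lengths) &&
    identical(u$cls, spec$uaug_contexts) &&
    ann$main_context$cls == spec$main_context
  if (!ok) {
    stop(sprintf("fixture '%s' failed re-annotation verification", spec$id))
  }
  invisible(ann)
}

#' The reporter construct panel of the packaged study design
#'
#' Builds the full panel of reporter constructs over the packaged leader
#' fixtures: the TRPM7-like wild type (`M7-Luc-M7`), the uORF-free
#' beta-globin-like control (`beta-Luc-M7`), the uAUG knockouts
#' (`1AUC-Luc-M7`, `2AUC-Luc-M7`, `1AUC2AUC-Luc-M7`), the uORF2
#' stop-codon knockout (`2stopCGA-Luc-M7`), and the uORF2 fusion reporter
#' (`2ndLuc-M7`).
#'
#' @param geometry Geometry preset name for the TRPM7-like leader.
#' @return Named list of [construct_spec()] objects.
#' @export
paper_constructs <- function(geometry = "trpm7-mouse-like") {
  m7 <- annotate_leader(make_leader_fixture(geometry_preset(geometry),
                                            seed = 1401L))
  beta <- annotate_leader(make_leader_fixture(geometry_preset("beta-globin-like"),
                                              seed = 1402L))
  uaug1 <- m7$uorfs$start[1L]
  uaug2 <- m7$uorfs$start[2L]
  stop2 <- m7$uorfs$stop_start[2L]
  wt <- construct_spec("M7-Luc-M7", m7)
  list(
    "M7-Luc-M7" = wt,
    "beta-Luc-M7" = construct_spec("beta-Luc-M7", beta),
    "1AUC-Luc-M7" = apply_mutation(wt, aug_knockout(uaug1), name = "1AUC-Luc-M7"),
    "2AUC-Luc-M7" = apply_mutation(wt, aug_knockout(uaug2), name = "2AUC-Luc-M7"),
    "1AUC2AUC-Luc-M7" = apply_mutation(
      apply_mutation(wt, aug_knockout(uaug1)), aug_knockout(uaug2),
      name = "1AUC2AUC-Luc-M7"),
    "2stopCGA-Luc-M7" = apply_mutation(wt, stop_knockout(stop2),
                                       name = "2stopCGA-Luc-M7"),
    "2ndLuc-M7" = apply_mutation(wt, fuse_reporter(uaug2), name = "2ndLuc-M7")
  )
}

#' Design of a synthetic in vitro translation experiment
#'
#' Captures the layout the simulator realises: constructs, the added-Mg grid
#' (default 0.2-1.4 mM in 0.2 mM steps), added-K levels (default 60, 90,
#' 120, 150 mM), replicates, lysates with basal-Mg offsets, the kinetic
#' sampling scheme (1-min reads for 60 min) and the noise model.
#'
#' @param constructs Character vector of construct names resolvable by
#'   [paper_constructs()], or a named list of [construct_spec()] objects.
#' @param mg_grid Added Mg2+ concentrations (mM).
#' @param k_levels Added K+ concentrations (mM).
#' @param replicates Replicates per condition (>= 1).
#' @param lysates data.frame with columns `lysate`, `mg_offset` (mM basal-Mg
#'   offset of each extract), or an integer count: offsets are then drawn
#'   uniformly in +/- 0.1 mM at simulation time.
#' @param sampling_interval Minutes between reads.
#' @param duration Total kinetic read time (minutes).
#' @param noise_sd Multiplicative Gaussian read noise (sd as a fraction of
#'   signal; 0 disables noise).
#' @param onset_tau Onset lag time constant (min) of the cumulative curve.
#' @param slowdown_tau Late-phase slowdown time constant (min).
#' @param seed Integer RNG seed, recorded in the output.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(constructs = c("M7-Luc-M7", "beta-Luc-M7"),
                              mg_grid = seq(0.2, 1.4, by = 0.2),
                              k_levels = c(60, 90, 120, 150),
                              replicates = 3L,
                              lysates = data.frame(lysate = "lysate1",
                                                   mg_offset = 0),
                              sampling_interval = 1,
                              duration = 60,
                              noise_sd = 0.03,
                              onset_tau = 5,
                              slowdown_tau = 150,
                              seed = 1L) {
  if (!length(mg_grid) || !length(k_levels)) {
    stop("mg_grid and k_levels must be nonempty")
  }
  if (replicates < 1L) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (is.numeric(lysates) && length(lysates) == 1L) {
    lysates <- as.integer(lysates)
  } else {
    stopifnot(is.data.frame(lysates),
              all(c("lysate", "mg_offset") %in% names(lysates)))
  }
  structure(
    list(constructs = constructs, mg_grid = as.numeric(mg_grid),
         k_levels = as.numeric(k_levels), replicates = as.integer(replicates),
         lysates = lysates, sampling_interval = as.numeric(sampling_interval),
         duration = as.numeric(duration), noise_sd = as.numeric(noise_sd),
         onset_tau = as.numeric(onset_tau),
         slowdown_tau = as.numeric(slowdown_tau), seed = as.integer(seed)),
    class = "experiment_design"
  )
}

# cumulative kinetic shape: unit synthesis rate, onset lag onset_tau,
# late-phase slowdown slowdown_tau; f(0) = 0, f'(t) < 1
kinetic_shape <- function(t, onset_tau, slowdown_tau) {
  (t - onset_tau * (1 - exp(-t / onset_tau))) * exp(-t / slowdown_tau)
}

# maximal instantaneous slope of the kinetic shape (numeric, per design)
peak_shape_slope <- function(design) {
  f <- function(t) kinetic_shape(t, design$onset_tau, design$slowdown_tau)
  opt <- stats::optimize(function(t) {
    (f(t + 1e-4) - f(t - 1e-4)) / 2e-4
  }, interval = c(0, design$duration), maximum = TRUE)
  opt$objective
}

#' Simulate a full in vitro translation dataset
#'
#' For every well (construct x Mg x K x replicate x lysate) the true synthesis
#' rate is the scanning model's closed-form reporter flux evaluated at the
#' effective Mg (added Mg plus the lysate's basal offset). The cumulative
#' luminescence curve is `rate * kinetic_shape(t)` -- an onset lag followed by
#' a gradual late-phase slowdown -- with optional multiplicative Gaussian
#' read noise. A ground-truth table of true rates and per-construct true
#' optima (the bell-fit center of the noise-free flux over the design grid)
#' is returned alongside; reproducible under the design seed.
#'
#' @param design An [experiment_design()].
#' @param params A [scanning_params()], e.g. `scanning_preset("paper2014")`.
#' @return Object of class `synthetic_experiment`: list with `traces` (long
#'   data.frame: time_min, signal_alu, construct, mg_mM, k_mM, replicate,
#'   lysate), `truth` (list with `rates`, `optima`, `lysates`,
#'   `peak_slope_factor`), `design`.
#' @export
simulate_experiment <- function(design, params) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "scanning_params"))
  constructs <- design$constructs
  if (!is.list(constructs)) {
    panel <- paper_constructs()
    unknown <- setdiff(constructs, names(panel))
    if (length(unknown)) {
      stop(sprintf("unknown construct preset(s): %s (available: %s)",
                   paste(unknown, collapse = ", "),
                   paste(names(panel), collapse = ", ")))
    }
    constructs <- panel[constructs]
  }
  withr::with_seed(design$seed, {
    lys <- design$lysates
    if (is.integer(lys) && !is.data.frame(lys)) {
      lys <- data.frame(lysate = sprintf("lysate%d", seq_len(lys)),
                        mg_offset = stats::runif(lys, -0.1, 0.1))
    }
    times <- seq(0, design$duration, by = design$sampling_interval)
    shape <- kinetic_shape(times, design$onset_tau, design$slowdown_tau)
    traces <- list()
    truth_rates <- list()
    truth_optima <- list()
    for (li in seq_len(nrow(lys))) {
      for (cn in names(constructs)) {
        con <- constructs[[cn]]
        for (k in design$k_levels) {
          flux <- vapply(design$mg_grid + lys$mg_offset[li], function(m) {
            closed_form_flux(con, params, m, k)$reporter_flux
          }, numeric(1L))
          truth_rates[[length(truth_rates) + 1L]] <- data.frame(
            construct = cn, k_mM = k, lysate = lys$lysate[li],
            mg_mM = design$mg_grid, true_rate = flux)
          opt <- tryCatch(fit_bell(mg = design$mg_grid, rate = flux)$optimum,
                          error = function(e) NA_real_)
          truth_optima[[length(truth_optima) + 1L]] <- data.frame(
            construct = cn, k_mM = k, lysate = lys$lysate[li],
            true_optimum = opt)
          for (mi in seq_along(design$mg_grid)) {
            for (r in seq_len(design$replicates)) {
              sig <- flux[mi] * shape
              if (design$noise_sd > 0) {
                sig <- sig * (1 + stats::rnorm(length(sig), 0, design$noise_sd))
                sig <- pmax(sig, 0)
              }
              traces[[length(traces) + 1L]] <- data.frame(
                time_min = times, signal_alu = sig, construct = cn,
                mg_mM = design$mg_grid[mi], k_mM = k, replicate = r,
                lysate = lys$lysate[li])
            }
          }
        }
      }
    }
    structure(
      list(traces = do.call(rbind, traces),
           truth = list(rates = do.call(rbind, truth_rates),
                        optima = do.call(rbind, truth_optima),
                        lysates = lys,
                        peak_slope_factor = peak_shape_slope(design)),
           design = design),
      class = "synthetic_experiment"
    )
  })
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  d <- x$design
  cat(sprintf("<synthetic_experiment> %d wells, %d reads each (seed %d)\n",
              nrow(x$traces) / length(seq(0, d$duration, by = d$sampling_interval)),
              length(seq(0, d$duration, by = d$sampling_interval)), d$seed))
  cat(sprintf("  constructs: %s\n", paste(unique(x$traces$construct),
                                          collapse = ", ")))
  cat(sprintf("  Mg %s mM; K %s mM; %d replicate(s); noise sd %.3g\n",
              paste(range(d$mg_grid), collapse = "-"),
              paste(d$k_levels, collapse = "/"), d$replicates, d$noise_sd))
  invisible(x)
}
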