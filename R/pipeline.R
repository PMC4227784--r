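#' Read leader sequences from a FASTA file
#'
#' Plain FASTA; the main-ORF start is taken from a `main_start=<int>` tag in
#' each header, or from a sidecar TSV with columns `id` and `main_start`.
#'
#' @param path FASTA file path.
#' @param main_start_tsv Optional sidecar TSV path.
#' @return Named list of [leader_sequence()] objects.
#' @export
read_leader_fasta <- function(path, main_start_tsv = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop(sprintf("no FASTA records in '%s'", path))
  sidecar <- NULL
  if (!is.null(main_start_tsv)) {
    sidecar <- utils::read.table(main_start_tsv, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    if (!all(c("id", "main_start") %in% names(sidecar))) {
      stop("sidecar TSV needs columns id and main_start")
    }
  }
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- list()
  for (i in seq_along(hdr)) {
    header <- sub("^>", "", lines[hdr[i]])
    id <- strsplit(trimws(header), "\\s+")[[1L]][1L]
    seq <- paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    ms <- NA_integer_
    m <- regmatches(header, regexpr("main_start=\\d+", header))
    if (length(m)) ms <- as.integer(sub("main_start=", "", m))
    if (is.na(ms) && !is.null(sidecar)) {
      hit <- match(id, sidecar$id)
      if (!is.na(hit)) ms <- as.integer(sidecar$main_start[hit])
    }
    if (is.na(ms)) {
      stop(sprintf("no main_start for record '%s' (header tag or sidecar TSV required)", id))
    }
    out[[id]] <- leader_sequence(seq, ms, id = id)
  }
  out
}

#' Write leader sequences to FASTA
#'
#' Headers carry the `main_start=` tag that [read_leader_fasta()] parses.
#'
#' @param leaders A [leader_sequence()] or list of them.
#' @param path Output path.
#' @export
write_leader_fasta <- function(leaders, path) {
  if (inherits(leaders, "leader_sequence")) leaders <- list(leaders)
  con <- file(path, "w")
  on.exit(close(con))
  for (led in leaders) {
    writeLines(sprintf(">%s main_start=%d", led$id, led$main_start), con)
    writeLines(substring(led$bases, seq(1, led$length, 70),
                         pmin(seq(1, led$length, 70) + 69, led$length)), con)
  }
  invisible(path)
}

#' Write uORF annotations as TSV
#'
#' One row per uORF: id, start, stop_start, length_nt, frame, overlap_nt,
#' gap_to_main, minus3, plus4, cls.
#'
#' @param annotations A `leader_annotation` or list of them.
#' @param path Output path.
#' @return The combined data.frame, invisibly.
#' @export
write_annotation_tsv <- function(annotations, path) {
  if (inherits(annotations, "leader_annotation")) {
    annotations <- list(annotations)
  }
  tab <- do.call(rbind, lapply(annotations, as.data.frame))
  if (is.null(tab)) tab <- data.frame()
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Write uORF intervals as a BED-like table
#'
#' 1-based inclusive intervals, one row per uORF (and one for the main ORF
#' start codon), with the context class as the feature name.
#'
#' @param annotations A `leader_annotation` or list of them.
#' @param path Output path.
#' @return The interval data.frame, invisibly.
#' @export
write_annotation_bed <- function(annotations, path) {
  if (inherits(annotations, "leader_annotation")) {
    annotations <- list(annotations)
  }
  rows <- lapply(annotations, function(ann) {
    u <- ann$uorfs
    led <- ann$leader
    uorf_rows <- if (nrow(u)) {
      data.frame(id = led$id, start = u$start,
                 end = ifelse(is.na(u$stop_start), led$length,
                              u$stop_start + 2L),
                 name = sprintf("uORF_%s", u$cls), stringsAsFactors = FALSE)
    }
    rbind(uorf_rows,
          data.frame(id = led$id, start = led$main_start,
                     end = led$main_start + 2L,
                     name = sprintf("mainAUG_%s", ann$main_context$cls),
                     stringsAsFactors = FALSE))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Full analysis of a kinetic-trace dataset
#'
#' Runs the measurement pipeline end to end: per-well maximal synthesis
#' rates (windowed OLS slope), per-construct Mg-response curves with bell
#' fits, the per-construct/per-K magnesium optima, and -- when the reference
#' construct is present -- per-lysate calibration and normalisation.
#'
#' @param traces Long-format trace table (data.frame or CSV/TSV path; see
#'   [read_trace_table()]) or a [simulate_experiment()] result.
#' @param window_minutes Slope window for [max_synthesis_rate()].
#' @param reference Reference construct for calibration/normalisation, or
#'   `NULL` to skip.
#' @param reference_k K level of the calibration series (default: lowest K
#'   present).
#' @return Object of class `mg_analysis`: list with `rates`, `curves`,
#'   `optima` (data.frame construct/k_mM/lysate/optimum/amplitude/width),
#'   `calibrations`.
#' @export
analyze_traces <- function(traces, window_minutes = 5, reference = "M7-Luc-M7",
                           reference_k = NULL) {
  if (inherits(traces, "synthetic_experiment")) traces <- traces$traces
  rates <- rate_table(traces, window_minutes)
  curves <- response_curves(rates)
  calibrations <- list()
  if (!is.null(reference) &&
      any(vapply(curves, function(cv) cv$construct == reference, logical(1L)))) {
    if (is.null(reference_k)) {
      ks <- vapply(Filter(function(cv) cv$construct == reference, curves),
                   function(cv) cv$k_mM, numeric(1L))
      reference_k <- min(ks)
    }
    for (lys in unique(vapply(curves, function(cv) cv$lysate, character(1L)))) {
      lys_curves <- Filter(function(cv) cv$lysate == lys, curves)
      cal <- tryCatch(
        calibrate_extract(lys_curves, reference = reference, k_mM = reference_k),
        error = function(e) NULL)
      if (is.null(cal)) next
      calibrations[[lys]] <- cal
      curves[names(lys_curves)] <- normalize_to_reference(lys_curves, cal)
    }
  }
  optima <- do.call(rbind, lapply(unname(curves), function(cv) {
    data.frame(construct = cv$construct, k_mM = cv$k_mM, lysate = cv$lysate,
               optimum = mg_optimum(cv), amplitude = cv$bell$amplitude,
               width = cv$bell$width, extrapolated = cv$bell$extrapolated,
               stringsAsFactors = FALSE)
  }))
  rownames(optima) <- NULL
  structure(list(rates = rates, curves = curves, optima = optima,
                 calibrations = calibrations),
            class = "mg_analysis")
}

#' @export
print.mg_analysis <- function(x, ...) {
  cat(sprintf("<mg_analysis> %d wells, %d fitted curves\n",
              nrow(x$rates), length(x$curves)))
  cat("Magnesium optima (mM added Mg):\n")
  print(x$optima, row.names = FALSE, digits = 3)
  invisible(x)
}

write_provenance <- function(path, config, seed) {
  rec <- list(
    package = "magscan",
    version = as.character(utils::packageVersion("magscan")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Annotate a FASTA of leaders and write a TSV (pipeline entry point)
#'
#' @param fasta Input FASTA path (headers with `main_start=` tags, or use
#'   `main_start_tsv`).
#' @param out Output TSV path.
#' @param main_start_tsv Optional sidecar TSV.
#' @return The annotation table, invisibly.
#' @export
run_annotate <- function(fasta, out, main_start_tsv = NULL) {
  leaders <- read_leader_fasta(fasta, main_start_tsv)
  anns <- lapply(leaders, annotate_leader)
  write_annotation_tsv(anns, out)
}

#' Simulate a dataset and write it to disk (pipeline entry point)
#'
#' Writes `traces.csv`, `ground_truth_rates.tsv`, `ground_truth_optima.tsv`,
#' `leaders.fasta` and a `provenance.json` record into `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param design An [experiment_design()]; its seed is overridden by `seed`
#'   when that is supplied.
#' @param preset Scanning-parameter preset name, or a [scanning_params()].
#' @param seed Optional integer seed overriding the design's.
#' @return The [simulate_experiment()] result, invisibly.
#' @export
run_simulate <- function(out_dir, design = experiment_design(),
                         preset = "paper2014", seed = NULL) {
  params <- if (inherits(preset, "scanning_params")) preset
            else scanning_preset(preset)
  if (!is.null(seed)) design$seed <- as.integer(seed)
  sim <- simulate_experiment(design, params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$traces, file.path(out_dir, "traces.csv"),
                   row.names = FALSE)
  utils::write.table(sim$truth$rates,
                     file.path(out_dir, "ground_truth_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$optima,
                     file.path(out_dir, "ground_truth_optima.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.list(design$constructs)) {
    fixtures <- list(
      make_leader_fixture(geometry_preset("trpm7-mouse-like"), seed = 1401L),
      make_leader_fixture(geometry_preset("beta-globin-like"), seed = 1402L))
    write_leader_fasta(fixtures, file.path(out_dir, "leaders.fasta"))
  }
  cfg <- design
  cfg$constructs <- if (is.list(design$constructs)) names(design$constructs)
                    else design$constructs
  class(cfg) <- NULL
  write_provenance(file.path(out_dir, "provenance.json"), cfg, design$seed)
  invisible(sim)
}

#' Analyse a trace table and write result tables (pipeline entry point)
#'
#' Writes `rate_table.tsv`, `curves.tsv` (one row per fitted bell) and
#' `optima.tsv` into `out_dir`.
#'
#' @param traces CSV/TSV path or data.frame of long-format traces.
#' @param out_dir Output directory (created if needed).
#' @param window_minutes Slope window (minutes).
#' @param reference Reference construct for normalisation (NULL to skip).
#' @return The [analyze_traces()] result, invisibly.
#' @export
run_analyze <- function(traces, out_dir, window_minutes = 5,
                        reference = "M7-Luc-M7") {
  res <- analyze_traces(traces, window_minutes, reference)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$rates, file.path(out_dir, "rate_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$optima, file.path(out_dir, "optima.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  curves_tab <- do.call(rbind, lapply(unname(res$curves), function(cv) {
    cbind(data.frame(construct = cv$construct, k_mM = cv$k_mM,
                     lysate = cv$lysate, normalized = cv$normalized,
                     stringsAsFactors = FALSE),
          as.data.frame(t(coef(cv$bell))))
  }))
  utils::write.table(curves_tab, file.path(out_dir, "curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(file.path(out_dir, "provenance.json"),
                   list(window_minutes = window_minutes,
                        reference = reference),
                   seed = NA)
  invisible(res)
}
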