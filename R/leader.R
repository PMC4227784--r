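#' Construct a 5'-leader sequence object
#'
#' A `leader_sequence` holds an mRNA sequence (or its 5' portion) together
#' with the declared position of the main open reading frame's AUG. All
#' coordinates in magscan are 1-based and inclusive; the position of an AUG is
#' the position of its A.
#'
#' Input may be DNA- or RNA-alphabet; `T` is normalised to `U` and case is
#' folded to upper. The sequence must contain `AUG` starting at `main_start`.
#'
#' @param bases Single string over A/C/G/U (or T), any case.
#' @param main_start 1-based position of the A of the main-ORF AUG.
#' @param id Sequence identifier.
#' @return An object of class `leader_sequence` with fields `id`, `bases`,
#'   `main_start` and `length`.
#' @examples
#' leader_sequence("GGAUGCCAUGG", main_start = 8)
#' @export
leader_sequence <- function(bases, main_start, id = "leader") {
  stopifnot(is.character(bases), length(bases) == 1L)
  b <- chartr("acgut", "ACGUT", bases)
  b <- gsub("T", "U", b, fixed = TRUE)
  bad <- regexpr("[^ACGU]", b)
  if (bad > 0L) {
    stop(sprintf("invalid base '%s' at position %d of '%s'",
                 substr(b, bad, bad), bad, id))
  }
  n <- nchar(b)
  main_start <- as.integer(main_start)
  if (length(main_start) != 1L || is.na(main_start) ||
      main_start < 1L || main_start > n - 2L) {
    stop("main_start must satisfy 1 <= main_start <= length - 2")
  }
  if (substr(b, main_start, main_start + 2L) != "AUG") {
    stop(sprintf("no AUG at declared main_start %d of '%s'", main_start, id))
  }
  structure(
    list(id = as.character(id), bases = b, main_start = main_start, length = n),
    class = "leader_sequence"
  )
}

#' @export
print.leader_sequence <- function(x, ...) {
  cat(sprintf("<leader_sequence> %s: %d nt, main AUG at %d\n",
              x$id, x$length, x$main_start))
  invisible(x)
}

codon_at <- function(bases, pos) substr(bases, pos, pos + 2L)

STOP_CODONS <- c("UAA", "UAG", "UGA")

#' Find upstream AUG codons
#'
#' Locates every AUG whose A lies upstream of the main-ORF start codon.
#'
#' @param leader A [leader_sequence()].
#' @return Integer vector of 1-based uAUG positions, ascending (possibly
#'   empty).
#' @examples
#' find_uaugs(leader_sequence("GGAUGCCAUGG", main_start = 8))
#' @export
find_uaugs <- function(leader) {
  stopifnot(inherits(leader, "leader_sequence"))
  hits <- gregexpr("(?=AUG)", leader$bases, perl = TRUE)[[1L]]
  hits <- as.integer(hits[hits > 0L])
  hits[hits < leader$main_start]
}

#' Classify the Kozak context of an AUG
#'
#' Extracts the 10-nt window spanning positions -6..+4 around an AUG (the A is
#' +1, Kozak numbering) and classifies initiation-context strength from the
#' two critical positions: -3 and +4. A purine (A/G) at a critical position
#' matches the optimal consensus; `strong` means both positions match, `weak`
#' neither, `adequate` exactly one. Positions falling outside the sequence are
#' padded with `N`, which never matches.
#'
#' @param leader A [leader_sequence()].
#' @param aug_pos Position of the A of an AUG in `leader`.
#' @return Object of class `kozak_context`: list with `window` (10-nt string),
#'   `minus3`, `plus4`, and `cls` (one of `"strong"`, `"adequate"`, `"weak"`).
#' @examples
#' classify_context(leader_sequence("GGAUGCCAUGG", main_start = 8), 8)
#' @export
classify_context <- function(leader, aug_pos) {
  stopifnot(inherits(leader, "leader_sequence"))
  aug_pos <- as.integer(aug_pos)
  if (codon_at(leader$bases, aug_pos) != "AUG") {
    stop(sprintf("no AUG at position %d", aug_pos))
  }
  at <- function(p) {
    if (p < 1L || p > leader$length) "N" else substr(leader$bases, p, p)
  }
  window <- paste(vapply((aug_pos - 6L):(aug_pos + 3L), at, character(1L)),
                  collapse = "")
  minus3 <- at(aug_pos - 3L)
  plus4 <- at(aug_pos + 3L)
  m3 <- minus3 %in% c("A", "G")
  p4 <- plus4 %in% c("A", "G")
  cls <- if (m3 && p4) "strong" else if (!m3 && !p4) "weak" else "adequate"
  structure(list(window = window, minus3 = minus3, plus4 = plus4, cls = cls),
            class = "kozak_context")
}

#' @export
print.kozak_context <- function(x, ...) {
  cat(sprintf("<kozak_context> %s (-3 = %s, +4 = %s): %s\n",
              x$window, x$minus3, x$plus4, x$cls))
  invisible(x)
}

#' GC content of the leader region
#'
#' Fraction of G+C over positions 1..main_start-1 (the 5'-leader proper).
#'
#' @param leader A [leader_sequence()].
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(leader) {
  stopifnot(inherits(leader, "leader_sequence"))
  if (leader$main_start == 1L) {
    stop("leader region is empty (main_start == 1); GC content undefined")
  }
  region <- substr(leader$bases, 1L, leader$main_start - 1L)
  chars <- strsplit(region, "", fixed = TRUE)[[1L]]
  mean(chars %in% c("G", "C"))
}

# First in-frame stop codon at or after `from`, searched over the full
# sequence; NA if the reading frame runs off the 3' end without a stop.
find_inframe_stop <- function(bases, from) {
  n <- nchar(bases)
  p <- from
  while (p + 2L <= n) {
    if (codon_at(bases, p) %in% STOP_CODONS) return(p)
    p <- p + 3L
  }
  NA_integer_
}

#' Annotate the uORF architecture of a 5'-leader
#'
#' Builds one uORF record per upstream AUG. Stop codons are searched by
#' in-frame scan over the full sequence (a uORF may terminate inside the main
#' ORF); overlap with the main ORF and the gap to the main AUG are computed
#' against `main_start`. A uORF overlaps the main ORF when its in-frame stop
#' is absent or ends at/after the main AUG. `gap_to_main` is the number of
#' bases strictly between the last base of the stop codon and the A of the
#' main AUG ("ends N bases upstream").
#'
#' @param leader A [leader_sequence()].
#' @return Object of class `leader_annotation`: list with `leader`, `uorfs`
#'   (data.frame: start, stop_start, length_nt, frame_vs_main, overlaps_main,
#'   overlap_nt, gap_to_main, minus3, plus4, cls), `gc_fraction` and
#'   `main_context`.
#' @examples
#' led <- leader_sequence("GGAUGCCAUGG", main_start = 8)
#' annotate_leader(led)
#' @export
annotate_leader <- function(leader) {
  stopifnot(inherits(leader, "leader_sequence"))
  starts <- find_uaugs(leader)
  rows <- lapply(starts, function(p) {
    stop_start <- find_inframe_stop(leader$bases, p)
    end_nt <- if (is.na(stop_start)) leader$length else stop_start + 2L
    overlaps <- is.na(stop_start) || stop_start + 2L >= leader$main_start
    data.frame(
      start = p,
      stop_start = stop_start,
      length_nt = if (is.na(stop_start)) NA_integer_ else stop_start + 2L - p + 1L,
      frame_vs_main = ((p - leader$main_start) %% 3L),
      overlaps_main = overlaps,
      overlap_nt = if (overlaps) end_nt - leader$main_start + 1L else 0L,
      gap_to_main = if (overlaps) NA_integer_
                    else leader$main_start - (stop_start + 2L) - 1L,
      minus3 = classify_context(leader, p)$minus3,
      plus4 = classify_context(leader, p)$plus4,
      cls = classify_context(leader, p)$cls,
      stringsAsFactors = FALSE
    )
  })
  uorfs <- if (length(rows)) do.call(rbind, rows) else data.frame(
    start = integer(), stop_start = integer(), length_nt = integer(),
    frame_vs_main = integer(), overlaps_main = logical(),
    overlap_nt = integer(), gap_to_main = integer(),
    minus3 = character(), plus4 = character(), cls = character(),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      leader = leader,
      uorfs = uorfs,
      gc_fraction = if (leader$main_start > 1L) gc_content(leader) else NA_real_,
      main_context = classify_context(leader, leader$main_start)
    ),
    class = "leader_annotation"
  )
}

#' @export
print.leader_annotation <- function(x, ...) {
  cat(sprintf("<leader_annotation> %s: %d uORF(s), leader GC %.1f%%, main AUG context %s\n",
              x$leader$id, nrow(x$uorfs), 100 * x$gc_fraction,
              x$main_context$cls))
  if (nrow(x$uorfs)) print(x$uorfs, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.leader_annotation <- function(x, ...) {
  if (nrow(x$uorfs) == 0L) {
    return(cbind(data.frame(id = character()), x$uorfs))
  }
  cbind(data.frame(id = x$leader$id, stringsAsFactors = FALSE), x$uorfs)
}
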