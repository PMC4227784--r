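# shared fixtures, built in code at load time

m7_fixture <- function(seed = 7L) {
  make_leader_fixture(geometry_preset("uorf1-paper"), seed = seed)
}

# independent triplet-scan oracle for AUG discovery
scan_aug_oracle <- function(bases, main_start) {
  n <- nchar(bases)
  hits <- integer(0)
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(bases, i, i + 2L) == "AUG" && i < main_start) {
      hits <- c(hits, i)
    }
  }
  hits
}

# independent in-frame stop-codon scan (first stop at/after `from`)
find_stop_oracle <- function(bases, from) {
  n <- nchar(bases)
  p <- from
  while (p + 2L <= n) {
    if (substr(bases, p, p + 2L) %in% c("UAA", "UAG", "UGA")) return(p)
    p <- p + 3L
  }
  NA_integer_
}

# a leader with an arbitrary base at -3 and +4 of an AUG at position 7
context_probe <- function(minus3, plus4) {
  bases <- paste0("GG", "C", minus3, "CC", "AUG", plus4, "CC", "AUGGCC")
  leader_sequence(bases, main_start = 13L, id = "probe")
}

# random valid geometry specification for round-trip property tests
random_geometry <- function() {
  n_u <- sample(0:2, 1L)
  main_start <- sample(120:200, 1L)
  repeat {
    starts <- sort(sample(10:(main_start - 25L), n_u))
    if (n_u < 2L || diff(starts) >= 12L) break
  }
  lens <- integer(0)
  ok <- TRUE
  for (i in seq_len(n_u)) {
    # uORF either ends well before main_start or overlaps it
    if (stats::runif(1) < 0.5) {
      max_len <- main_start - starts[i] - 4L
      if (max_len < 6L) { ok <- FALSE; break }
      lens[i] <- 3L * sample(2:(max_len %/% 3L), 1L)
    } else {
      lens[i] <- 3L * sample(((main_start - starts[i]) %/% 3L + 2L):60L, 1L)
    }
  }
  if (!ok) return(random_geometry())
  ctxs <- sample(c("strong", "adequate", "weak"), n_u, replace = TRUE)
  spec <- tryCatch(
    geometry_spec(id = "rand", length = max(main_start + 60L,
                                            if (n_u) max(starts + lens) + 6L else 0L),
                  main_start = main_start, uaug_positions = starts,
                  uorf_lengths = lens, uaug_contexts = ctxs,
                  main_context = sample(c("strong", "adequate", "weak"), 1L),
                  gc_target = stats::runif(1, 0.35, 0.7)),
    error = function(e) NULL)
  if (is.null(spec)) random_geometry() else spec
}

# random geometry whose protected motifs do not collide: retries until the
# generator accepts it
random_fixture <- function(seed) {
  repeat {
    spec <- random_geometry()
    led <- tryCatch(make_leader_fixture(spec, seed = seed),
                    error = function(e) NULL)
    if (!is.null(led)) return(list(spec = spec, leader = led))
  }
}

# parameter set with hand-set probabilities for algebraic checks
algebra_params <- function(p_strong = 0.6, u0 = 0.1, u1 = 0.9, mid = 0.8,
                           steep = 0.2, q = 0.3) {
  scanning_params(
    loading_amp = 50,
    loading_center = c(intercept = 0.8, slope = 1 / 500),
    loading_width = c(lo = 0.5, hi = 0.35),
    ctx = list(strong = c(floor = p_strong, ceil = p_strong, mid = 0.8, steep = 10),
               adequate = c(floor = u0, ceil = u1, mid = mid, steep = steep),
               weak = c(floor = 0.01, ceil = 0.3, mid = 0.9, steep = 0.2)),
    reinit_prob = q, uncapped_scale = 0.05)
}
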