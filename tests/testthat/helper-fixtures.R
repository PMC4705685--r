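# Shared fixtures: the lambda-scale tether and pulley used across tests.

lambda_wlc <- function() wlc_params(contour_length = 16200)

default_geometry <- function() {
  pulley_geometry(l0 = 13800, d = 2800, P0 = 0, thetaF = pi / 4,
                  origin = c(0, 0), extension_fraction = 0.85)
}

# brute-force IUPAC sliding-window motif scan (independent oracle for
# find_sites): forward strand plus reverse complement for non-palindromes
oracle_find_sites <- function(sequence, motif) {
  code <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  match_at <- function(seqc, patc, pos) {
    all(vapply(seq_along(patc), function(j) {
      s <- seqc[pos + j - 1L]
      s %in% code[[patc[j]]] || (s == "N" && length(code[[patc[j]]]) >= 1)
    }, logical(1)))
  }
  scan <- function(seqc, patc) {
    m <- length(patc)
    which(vapply(seq_len(length(seqc) - m + 1L),
                 function(p) match_at(seqc, patc, p), logical(1)))
  }
  seqc <- strsplit(toupper(sequence), "")[[1]]
  patc <- strsplit(toupper(motif), "")[[1]]
  hits <- scan(seqc, patc)
  rc <- rev(unname(comp[patc]))
  if (!identical(rc, patc)) hits <- union(hits, scan(seqc, rc))
  sort(unique(hits))
}

# pulley geometry fitted to protein-free calibration scans of the same
# pulley (apex-covering piezo range, parameters averaged over scans) — the
# standard workflow before protein incubation
fitted_clean_geometry <- function(g = default_geometry(), n_scans = 3) {
  fits <- lapply(seq_len(n_scans), function(s) {
    clean <- simulate_scan(scan_config(g, scan_start = -2000,
                                       scan_span = 14000, seed = 900 + s))
    fit_geometry(clean$trajectory, origin = g$origin)
  })
  avg <- function(f) mean(vapply(fits, function(x) x$geometry[[f]],
                                 numeric(1)))
  out <- pulley_geometry(l0 = avg("l0"), d = avg("d"), P0 = avg("P0"),
                         thetaF = avg("thetaF"), origin = g$origin,
                         extension_fraction = g$extension_fraction)
  # residual noise scale (bp) measured on the calibration scans, as the
  # detector expects it from calibration rather than from a protein-laden
  # scan
  attr(out, "sigma_residual_bp") <- contour_nm_to_bp(
    mean(vapply(fits, `[[`, numeric(1), "sigma_r")),
    g$extension_fraction)
  out
}

clean_sigma_residual <- function(gfit) attr(gfit, "sigma_residual_bp")

# score which planted pause events have an overlapping detected event
planted_event_detected <- function(truth_events, detected) {
  vapply(truth_events, function(e) {
    any(detected$t_start <= e$t_end & detected$t_end >= e$t_start)
  }, logical(1))
}
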