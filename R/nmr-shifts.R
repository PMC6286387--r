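## Secondary Ca chemical-shift analysis: deviations from random coil,
## helix-segment calling, and free-vs-bound state comparison.
##
## Residue numbering follows the full-length protein (1-based)
## throughout, including for truncated constructs.

#' Per-residue Ca chemical-shift table
#'
#' @param residue_number integer residue indices in full-length
#'   numbering; unique, will be sorted.
#' @param residue_type one-letter amino-acid codes.
#' @param ca_shift Ca chemical shift, ppm; NA for unobserved residues.
#' @param observed logical; defaults to `!is.na(ca_shift)`.
#' @param reference free-text referencing metadata (e.g. "HDO 4.64 ppm
#'   at 30 C").
#' @return Object of class `shift_table`: a data.frame with the four
#'   columns plus a `reference` attribute.
#' @export
shift_table <- function(residue_number, residue_type, ca_shift,
                        observed = !is.na(ca_shift), reference = NULL) {
  residue_number <- as.integer(residue_number)
  if (anyDuplicated(residue_number))
    stop("residue numbers must be unique")
  ord <- order(residue_number)
  df <- data.frame(residue_number = residue_number[ord],
                   residue_type = as.character(residue_type)[ord],
                   ca_shift = as.numeric(ca_shift)[ord],
                   observed = as.logical(observed)[ord],
                   stringsAsFactors = FALSE)
  attr(df, "reference") <- reference
  class(df) <- c("shift_table", "data.frame")
  df
}

#' Random-coil Ca chemical shifts
#'
#' Standard random-coil reference values (ppm) per residue type, of the
#' kind tabulated in the coil-shift literature.  Shipped as an editable
#' table so an alternative coil set can be swapped in; no
#' neighbour-correction is applied.
#'
#' @return Named numeric vector, one delta(Ca)/ppm per one-letter code.
#' @export
random_coil_ca <- function() {
  c(A = 52.5, R = 56.0, N = 52.8, D = 54.2, C = 58.2, Q = 55.7,
    E = 56.6, G = 45.1, H = 55.0, I = 61.1, L = 55.1, K = 56.2,
    M = 55.4, F = 57.7, P = 63.3, S = 58.3, T = 61.8, W = 57.5,
    Y = 57.9, V = 62.2)
}

#' Coil shift table for a sequence
#'
#' @param residue_number integer vector of positions.
#' @param residue_type one-letter codes at those positions.
#' @param coil_values named vector of coil shifts; default
#'   [random_coil_ca()].
#' @return A [shift_table()] of coil values.
#' @export
coil_table <- function(residue_number, residue_type,
                       coil_values = random_coil_ca()) {
  shifts <- unname(coil_values[residue_type])
  if (any(is.na(shifts)))
    stop("no coil value for residue type(s): ",
         paste(unique(residue_type[is.na(shifts)]), collapse = ", "))
  shift_table(residue_number, residue_type, shifts)
}

#' Secondary chemical shifts (observed minus random coil)
#'
#' @param observed,random_coil [shift_table()] objects; residue types
#'   must agree wherever both tables carry a residue.
#' @return Object of class `secondary_shift_profile`: data.frame with
#'   `residue_number`, `residue_type`, `delta` (ppm; NA if unobserved),
#'   `observed`; attributes `missing_residues` and `segments` (NULL
#'   until [call_helices()] is run).
#' @export
secondary_shifts <- function(observed, random_coil) {
  stopifnot(inherits(observed, "shift_table"),
            inherits(random_coil, "shift_table"))
  m <- merge(as.data.frame(observed), as.data.frame(random_coil),
             by = "residue_number", suffixes = c("", ".rc"))
  bad <- m$residue_type != m$residue_type.rc
  if (any(bad))
    stop("residue type mismatch at position(s): ",
         paste(m$residue_number[bad], collapse = ", "))
  delta <- ifelse(m$observed, m$ca_shift - m$ca_shift.rc, NA_real_)
  out <- data.frame(residue_number = m$residue_number,
                    residue_type = m$residue_type,
                    delta = delta,
                    observed = m$observed,
                    stringsAsFactors = FALSE)
  out <- out[order(out$residue_number), ]
  rownames(out) <- NULL
  attr(out, "missing_residues") <- out$residue_number[!out$observed]
  attr(out, "segments") <- NULL
  class(out) <- c("secondary_shift_profile", "data.frame")
  out
}

## Maximal runs of qualifying residue numbers, allowing internal gaps of
## at most max_gap positions; runs start and end on qualifying residues.
runs_with_gaps <- function(positions, max_gap) {
  if (!length(positions)) return(list())
  positions <- sort(positions)
  breaks <- which(diff(positions) > max_gap + 1)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(positions))
  Map(function(s, e) c(positions[s], positions[e]), starts, ends)
}

#' Call helical segments from secondary shifts
#'
#' Residues with secondary shift at or above `stable_threshold` seed
#' stable-helix segments; residues reaching only `marginal_threshold`
#' seed marginal-helix segments.  Runs may bridge up to `max_gap`
#' unobserved or sub-threshold residues and must span at least
#' `min_len` residues.  Marginal segments never overlap stable ones.
#'
#' @param profile a [secondary_shifts()] result.
#' @param stable_threshold,marginal_threshold ppm cutoffs on the
#'   downfield Ca deviation (defaults 3.0 and 2.0).
#' @param min_len minimum segment length, residues (default 4).
#' @param max_gap maximum bridged gap, residues (default 1).
#' @return The profile with attribute `segments` set: a data.frame of
#'   `start`, `end`, `class` (`"stable_helix"`/`"marginal_helix"`).
#' @export
call_helices <- function(profile, stable_threshold = 3.0,
                         marginal_threshold = 2.0, min_len = 4,
                         max_gap = 1) {
  stopifnot(inherits(profile, "secondary_shift_profile"))
  if (marginal_threshold > stable_threshold)
    stop("`marginal_threshold` must not exceed `stable_threshold`")
  ok <- profile$observed & !is.na(profile$delta)
  seg_df <- function(runs, cls) {
    runs <- Filter(function(r) r[2] - r[1] + 1 >= min_len, runs)
    if (!length(runs))
      return(data.frame(start = integer(), end = integer(),
                        class = character(), stringsAsFactors = FALSE))
    data.frame(start = vapply(runs, `[`, 1L, 1),
               end = vapply(runs, `[`, 1L, 2),
               class = cls, stringsAsFactors = FALSE)
  }
  stable_pos <- profile$residue_number[ok & profile$delta >= stable_threshold]
  stable <- seg_df(runs_with_gaps(stable_pos, max_gap), "stable_helix")
  in_stable <- function(pos)
    any(pos >= stable$start & pos <= stable$end)
  marg_pos <- profile$residue_number[ok & profile$delta >= marginal_threshold]
  marg_pos <- marg_pos[!vapply(marg_pos, in_stable, logical(1))]
  marginal <- seg_df(runs_with_gaps(marg_pos, max_gap), "marginal_helix")
  segs <- rbind(stable, marginal)
  segs <- segs[order(segs$start), ]
  rownames(segs) <- NULL
  attr(profile, "segments") <- segs
  profile
}

#' Segments attribute accessor
#'
#' @param profile a profile processed by [call_helices()].
#' @return Data.frame of called segments.
#' @export
helix_segments <- function(profile) {
  segs <- attr(profile, "segments")
  if (is.null(segs)) stop("run call_helices() first")
  segs
}

overlaps <- function(a_start, a_end, b) {
  any(b$start <= a_end & b$end >= a_start)
}

classify_state <- function(profile) {
  segs <- helix_segments(profile)
  obs <- profile$residue_number[profile$observed]
  stable <- segs[segs$class == "stable_helix", , drop = FALSE]
  in_stable <- vapply(obs, function(p)
    nrow(stable) > 0 && any(p >= stable$start & p <= stable$end), logical(1))
  coverage <- mean(in_stable)
  if (coverage >= 0.5) "folded"
  else if (any(segs$class == "marginal_helix")) "molten-globule-like"
  else "disordered"
}

#' Compare helix content of two conformational states
#'
#' Tabulates segments gained and lost between a free-state and a
#' bound-state profile (segments match when same-class segments
#' overlap), and classifies each state: `folded` when at least half of
#' the observed residues lie in stable segments; `molten-globule-like`
#' when marginal segments exist below that coverage; otherwise
#' `disordered`.
#'
#' @param free,bound profiles processed by [call_helices()], covering
#'   the same residue range.
#' @return Object of class `state_comparison`: `free_class`,
#'   `bound_class`, `gained` (segments present in `bound` only),
#'   `lost` (present in `free` only), `stable_coverage` (named numeric).
#' @export
compare_states <- function(free, bound) {
  stopifnot(inherits(free, "secondary_shift_profile"),
            inherits(bound, "secondary_shift_profile"))
  if (!identical(range(free$residue_number), range(bound$residue_number)))
    stop("free and bound profiles must cover the same residue range")
  fs <- helix_segments(free)
  bs <- helix_segments(bound)
  unmatched <- function(a, b) {
    keep <- vapply(seq_len(nrow(a)), function(i) {
      same <- b[b$class == a$class[i], , drop = FALSE]
      !overlaps(a$start[i], a$end[i], same)
    }, logical(1))
    a[keep, , drop = FALSE]
  }
  stable_cov <- function(p) {
    segs <- helix_segments(p)
    st <- segs[segs$class == "stable_helix", , drop = FALSE]
    obs <- p$residue_number[p$observed]
    mean(vapply(obs, function(x)
      nrow(st) > 0 && any(x >= st$start & x <= st$end), logical(1)))
  }
  structure(list(free_class = classify_state(free),
                 bound_class = classify_state(bound),
                 gained = unmatched(bs, fs),
                 lost = unmatched(fs, bs),
                 stable_coverage = c(free = stable_cov(free),
                                     bound = stable_cov(bound))),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat("State comparison: free =", x$free_class, "| bound =", x$bound_class, "\n")
  cat(sprintf("  gained on binding: %d segment(s); lost: %d\n",
              nrow(x$gained), nrow(x$lost)))
  invisible(x)
}

#' Amide proton dispersion statistic
#'
#' Range of amide 1H shifts, with the common heuristic that a spread
#' under 1 ppm suggests a disordered protein.  Reported for context
#' only; helix calling never uses it.
#'
#' @param hn_shifts numeric vector of amide 1H shifts, ppm.
#' @return List with `range_ppm` and logical `disorder_hint`.
#' @export
amide_dispersion <- function(hn_shifts) {
  hn_shifts <- hn_shifts[is.finite(hn_shifts)]
  if (!length(hn_shifts)) stop("no finite amide shifts supplied")
  r <- diff(range(hn_shifts))
  list(range_ppm = r, disorder_hint = r < 1)
}
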