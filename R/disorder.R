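AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_AMBIGUOUS <- c("X", "B", "Z", "U")

#' Per-residue disorder probability track
#'
#' Pairs an amino-acid sequence with a per-residue disorder probability
#' (e.g. a DISOPRED3 prediction). Validation enforces equal lengths,
#' probabilities in \[0, 1\] and known residue codes.
#'
#' @param sequence Amino-acid string (one-letter codes), or a character
#'   vector of single letters.
#' @param probabilities Numeric vector of disorder probabilities, one per
#'   residue.
#' @param strict_residues Reject ambiguity codes X/B/Z/U.
#' @return An object of class `"disorder_track"`: a list with elements
#'   `sequence` (string) and `probabilities`.
#' @examples
#' disorder_track("MKVLA", c(0.9, 0.8, 0.2, 0.1, 0.7))
#' @export
disorder_track <- function(sequence, probabilities, strict_residues = FALSE) {
  if (length(sequence) > 1L) sequence <- paste(sequence, collapse = "")
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  if (n == 0L) stop("disorder_track: empty sequence")
  check_residues(sequence, strict_residues)
  probabilities <- as.numeric(probabilities)
  if (length(probabilities) != n)
    stop(sprintf(
      "disorder_track: %d probabilities for a %d-residue sequence",
      length(probabilities), n))
  if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1))
    stop("disorder_track: probabilities must lie in [0, 1]")
  structure(list(sequence = sequence, probabilities = probabilities),
            class = "disorder_track")
}

check_residues <- function(sequence, strict = FALSE) {
  letters_seq <- strsplit(sequence, "", fixed = TRUE)[[1]]
  allowed <- if (strict) AA_STANDARD else c(AA_STANDARD, AA_AMBIGUOUS)
  bad <- setdiff(unique(letters_seq), allowed)
  if (length(bad))
    stop(sprintf("invalid residue code(s): %s", paste(bad, collapse = ", ")))
  invisible(sequence)
}

#' @export
print.disorder_track <- function(x, ...) {
  cat(sprintf("Disorder track: %d residues, %d above threshold 0.5\n",
              nchar(x$sequence), sum(x$probabilities >= 0.5)))
  invisible(x)
}

#' Ordered/disordered segment annotation
#'
#' A contiguous, exhaustive partition of residues 1..N into alternating
#' ordered and disordered segments (1-based inclusive coordinates).
#'
#' @param start,end Integer vectors of segment bounds.
#' @param kind Character vector, `"ordered"` or `"disordered"`.
#' @return A data frame of class `"segment_annotation"` with columns
#'   `start`, `end`, `kind`.
#' @export
segment_annotation <- function(start, end, kind) {
  ann <- data.frame(start = as.integer(start), end = as.integer(end),
                    kind = as.character(kind), stringsAsFactors = FALSE)
  class(ann) <- c("segment_annotation", "data.frame")
  validate_segment_annotation(ann)
  ann
}

validate_segment_annotation <- function(ann) {
  if (nrow(ann) == 0L) stop("segment_annotation: no segments")
  if (!all(ann$kind %in% c("ordered", "disordered")))
    stop("segment_annotation: kind must be 'ordered' or 'disordered'")
  if (any(ann$end < ann$start))
    stop("segment_annotation: segment end before start")
  if (ann$start[1] != 1L)
    stop("segment_annotation: first segment must start at residue 1")
  if (nrow(ann) > 1L) {
    if (!all(ann$start[-1] == ann$end[-nrow(ann)] + 1L))
      stop("segment_annotation: segments must be contiguous and ordered")
    if (any(ann$kind[-1] == ann$kind[-nrow(ann)]))
      stop("segment_annotation: adjacent segments must differ in kind")
  }
  invisible(ann)
}

annotation_length <- function(ann) ann$end[nrow(ann)]

#' Annotate ordered segments from a disorder track
#'
#' A residue run is called ordered when its disorder probability is below
#' `disorder_threshold` (strictly) for at least `min_ordered_run`
#' consecutive residues; all remaining residues are disordered. This is
#' the domain-boundary selection stage of the globule-linker pipeline;
#' follow with [merge_loops()] to absorb short loops between ordered
#' stretches into single folded domains.
#'
#' @param track A [disorder_track()].
#' @param params A [glm_params()].
#' @return A [segment_annotation()].
#' @examples
#' tr <- disorder_track("AAAAAAA", c(0.8, 0.8, 0.3, 0.3, 0.3, 0.8, 0.8))
#' segments_from_track(tr)
#' @export
segments_from_track <- function(track, params = glm_params()) {
  stopifnot(inherits(track, "disorder_track"))
  p <- track$probabilities
  n <- length(p)
  if (n == 0L) stop("segments_from_track: empty track")
  below <- p < params$disorder_threshold
  runs <- rle(below)
  ordered <- logical(n)
  at <- 1L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    if (runs$values[i] && len >= params$min_ordered_run)
      ordered[at:(at + len - 1L)] <- TRUE
    at <- at + len
  }
  runs2 <- rle(ordered)
  ends <- cumsum(runs2$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  segment_annotation(starts, ends,
                     ifelse(runs2$values, "ordered", "disordered"))
}

#' Absorb short loops into folded domains
#'
#' Any disordered segment of length at most `max_loop` that is flanked by
#' ordered segments on both sides is fused with its neighbours into a
#' single ordered segment (one folded domain). Merging is repeated
#' left-to-right until a fixed point; terminal disordered tails are never
#' absorbed.
#'
#' @inheritParams segments_from_track
#' @param annotation A [segment_annotation()].
#' @return A [segment_annotation()].
#' @export
merge_loops <- function(annotation, params = glm_params()) {
  validate_segment_annotation(annotation)
  repeat {
    n <- nrow(annotation)
    fuse <- which(
      annotation$kind == "disordered" &
        seq_len(n) > 1L & seq_len(n) < n &
        (annotation$end - annotation$start + 1L) <= params$max_loop
    )
    if (length(fuse) == 0L) return(annotation)
    i <- fuse[1]  # neighbours of a disordered segment are ordered by construction
    merged_rows <- (i - 1L):(i + 1L)
    keep_before <- if (i - 2L >= 1L) annotation[seq_len(i - 2L), ] else annotation[0, ]
    keep_after <- if (i + 2L <= n) annotation[(i + 2L):n, ] else annotation[0, ]
    fused <- data.frame(start = annotation$start[i - 1L],
                        end = annotation$end[i + 1L],
                        kind = "ordered", stringsAsFactors = FALSE)
    ann <- rbind(keep_before, fused, keep_after)
    # fusing can create adjacent ordered segments only via keep rows that
    # were themselves ordered; collapse them
    annotation <- collapse_same_kind(ann)
  }
}

collapse_same_kind <- function(ann) {
  out <- ann[1, , drop = FALSE]
  for (i in seq_len(nrow(ann))[-1]) {
    j <- nrow(out)
    if (ann$kind[i] == out$kind[j]) {
      out$end[j] <- ann$end[i]
    } else {
      out <- rbind(out, ann[i, ])
    }
  }
  rownames(out) <- NULL
  segment_annotation(out$start, out$end, out$kind)
}

#' Build an annotation from explicit folded-domain intervals
#'
#' Bypasses the disorder-probability rules: the given 1-based inclusive
#' intervals become ordered segments and everything else is disordered.
#'
#' @param n_residues Chain length.
#' @param domains Data frame (or matrix) with columns `start` and `end`.
#' @return A [segment_annotation()].
#' @export
segments_from_domains <- function(n_residues, domains) {
  n_residues <- as.integer(n_residues)
  if (n_residues < 1L) stop("segments_from_domains: n_residues must be >= 1")
  ordered <- logical(n_residues)
  if (!is.null(domains) && nrow(domains) > 0L) {
    for (i in seq_len(nrow(domains))) {
      s <- as.integer(domains$start[i]); e <- as.integer(domains$end[i])
      if (is.na(s) || is.na(e) || s < 1L || e > n_residues || e < s)
        stop(sprintf("segments_from_domains: invalid interval [%s, %s] for chain of %d residues",
                     domains$start[i], domains$end[i], n_residues))
      ordered[s:e] <- TRUE
    }
  }
  runs <- rle(ordered)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  segment_annotation(starts, ends, ifelse(runs$values, "ordered", "disordered"))
}

#' Annotation treating the whole chain as disordered
#'
#' The "no domain information" (ND) variant: every residue is a linker
#' bead regardless of the disorder track.
#'
#' @param n_residues Chain length.
#' @return A [segment_annotation()] with a single disordered segment.
#' @export
annotation_all_disordered <- function(n_residues) {
  segment_annotation(1L, as.integer(n_residues), "disordered")
}
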