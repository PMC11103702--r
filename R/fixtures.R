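#' Generate a synthetic annotated protein
#'
#' Emits a random sequence with a prescribed layout of ordered and
#' disordered segments, a disorder-probability track consistent with the
#' layout (probabilities centred at 0.1 for ordered and 0.9 for
#' disordered residues, jittered uniformly by `disorder_noise`), the
#' ground-truth segment annotation, and the true domain masses. Every
#' output is reproducible from the seed. These fixtures let the whole
#' pipeline be exercised without any external disorder predictor.
#'
#' @param layout List of `c(kind, length)` pairs (or a 2-column data
#'   frame), kinds `"ordered"`/`"disordered"`, lengths in residues.
#' @param seed Integer seed.
#' @param disorder_noise Jitter half-width in \[0, 0.4\]: keeps every
#'   probability on the correct side of the 0.5 threshold.
#' @return List of class `"glm_fixture"`: `sequence`, `track`
#'   ([disorder_track()]), `annotation` ([segment_annotation()]),
#'   `domain_masses` (Da, one per ordered segment), `seed`.
#' @examples
#' fx <- generate_fixture(list(c("disordered", 30), c("ordered", 50),
#'                             c("disordered", 30)), seed = 1)
#' fx$annotation
#' @export
generate_fixture <- function(layout, seed = 0L, disorder_noise = 0.05) {
  if (is.data.frame(layout))
    layout <- lapply(seq_len(nrow(layout)), function(i)
      c(layout[[1]][i], layout[[2]][i]))
  kinds <- vapply(layout, function(x) as.character(x[[1]]), character(1))
  lens <- vapply(layout, function(x) as.integer(x[[2]]), integer(1))
  if (!all(kinds %in% c("ordered", "disordered")))
    stop("generate_fixture: layout kinds must be 'ordered' or 'disordered'")
  if (any(lens < 1L)) stop("generate_fixture: layout lengths must be >= 1")
  if (disorder_noise < 0 || disorder_noise > 0.4)
    stop("generate_fixture: disorder_noise must lie in [0, 0.4]")

  with_rng_seed(seed, {
    n <- sum(lens)
    aa <- sample(AA_STANDARD, n, replace = TRUE)
    probs <- numeric(n)
    at <- 1L
    for (i in seq_along(lens)) {
      span <- at:(at + lens[i] - 1L)
      centre <- if (kinds[i] == "ordered") 0.1 else 0.9
      probs[span] <- pmin(1, pmax(0, centre + stats::runif(lens[i], -disorder_noise,
                                                           disorder_noise)))
      at <- at + lens[i]
    }
    sequence <- paste(aa, collapse = "")
    track <- disorder_track(sequence, probs)
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1L) + 1L)
    # collapse layout runs of equal kind so the annotation alternates
    ann <- collapse_same_kind(data.frame(start = starts, end = ends,
                                         kind = kinds,
                                         stringsAsFactors = FALSE))
    ord <- ann[ann$kind == "ordered", , drop = FALSE]
    masses <- if (nrow(ord)) vapply(seq_len(nrow(ord)), function(i)
      fragment_mass(substr(sequence, ord$start[i], ord$end[i])), numeric(1))
      else numeric(0)
    structure(list(sequence = sequence, track = track, annotation = ann,
                   domain_masses = masses, seed = as.integer(seed)),
              class = "glm_fixture")
  })
}

#' Write a fixture to disk
#'
#' Emits `<id>.fasta`, `<id>.diso` (disorder track) and `<id>.domains.tsv`
#' (ordered segments) under `dir`.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if missing).
#' @param id Basename for the three files.
#' @return Named character vector of the paths written.
#' @export
write_fixture <- function(fixture, dir, id = "fixture") {
  stopifnot(inherits(fixture, "glm_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, paste0(id, ".fasta"))
  diso <- file.path(dir, paste0(id, ".diso"))
  dom <- file.path(dir, paste0(id, ".domains.tsv"))
  seqs <- stats::setNames(fixture$sequence, id)
  write_fasta(seqs, fasta)
  write_disorder_track(fixture$track, diso)
  ord <- fixture$annotation[fixture$annotation$kind == "ordered", , drop = FALSE]
  write_domain_tsv(ord, dom)
  c(fasta = fasta, track = diso, domains = dom)
}
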