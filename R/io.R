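#' Read amino-acid sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a named
#' character vector of uppercase sequences.
#'
#' @param path FASTA file (single- or multi-record).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_fasta: no such file: %s", path))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L) stop(sprintf("read_fasta: %s: no FASTA records", path))
    bounds <- c(hdr, length(lines) + 1L)
    seqs <- vapply(seq_along(hdr), function(i) {
      toupper(paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = ""))
    }, character(1))
    names(seqs) <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  }
  if (any(nchar(seqs) == 0L))
    stop(sprintf("read_fasta: %s: empty sequence record", path))
  seqs
}

write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(sprintf(">%s", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a DISOPRED3-style disorder track
#'
#' Parses whitespace-separated columns `index residue mark probability`;
#' lines starting with `#` (and blank lines) are ignored; indices are
#' 1-based and must be consecutive from 1. If `sequence` is supplied it is
#' cross-validated against the residue column.
#'
#' @param path Track file.
#' @param sequence Optional sequence to validate against.
#' @return A [disorder_track()].
#' @export
read_disorder_track <- function(path, sequence = NULL) {
  if (!file.exists(path)) stop(sprintf("read_disorder_track: no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    stop(sprintf("read_disorder_track: %s: no data lines", path))
  fields <- strsplit(trimws(lines), "\\s+")
  n <- length(fields)
  idx <- integer(n); res <- character(n); prob <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 4L)
      stop(sprintf("%s:%d: expected 4 fields 'index residue mark probability', got %d",
                   path, lineno[i], length(f)))
    idx[i] <- suppressWarnings(as.integer(f[1]))
    res[i] <- f[2]
    prob[i] <- suppressWarnings(as.numeric(f[4]))
    if (is.na(idx[i]))
      stop(sprintf("%s:%d: field 'index' is not an integer: '%s'", path, lineno[i], f[1]))
    if (is.na(prob[i]))
      stop(sprintf("%s:%d: field 'probability' is not numeric: '%s'", path, lineno[i], f[4]))
    if (prob[i] < 0 || prob[i] > 1)
      stop(sprintf("%s:%d: field 'probability' outside [0, 1]: %s", path, lineno[i], f[4]))
  }
  if (!identical(idx, seq_len(n)))
    stop(sprintf("read_disorder_track: %s: indices must run 1..%d consecutively", path, n))
  seq_from_file <- paste(res, collapse = "")
  if (!is.null(sequence) && toupper(sequence) != toupper(seq_from_file))
    stop(sprintf("read_disorder_track: %s: residue column disagrees with the supplied sequence",
                 path))
  disorder_track(seq_from_file, prob)
}

write_disorder_track <- function(track, path) {
  aa <- strsplit(track$sequence, "", fixed = TRUE)[[1]]
  mark <- ifelse(track$probabilities >= 0.5, "*", ".")
  writeLines(c("# index residue mark probability",
               sprintf("%d %s %s %.4f", seq_along(aa), aa, mark,
                       track$probabilities)),
             path)
  invisible(path)
}

#' Read folded-domain intervals from TSV
#'
#' Two tab- (or whitespace-) separated columns `start end`, 1-based
#' inclusive, one folded domain per line; an optional header line is
#' detected and skipped.
#'
#' @param path TSV file.
#' @return Data frame with integer columns `start`, `end`.
#' @export
read_domain_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_domain_tsv: no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) && grepl("[A-Za-z]", lines[1])) {
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  if (length(lines) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  out <- data.frame(start = integer(length(lines)), end = integer(length(lines)))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 2L)
      stop(sprintf("%s:%d: expected two fields 'start end'", path, lineno[i]))
    s <- suppressWarnings(as.integer(f[1])); e <- suppressWarnings(as.integer(f[2]))
    if (is.na(s) || is.na(e) || s < 1L || e < s)
      stop(sprintf("%s:%d: invalid interval '%s %s'", path, lineno[i], f[1], f[2]))
    out$start[i] <- s; out$end[i] <- e
  }
  out
}

write_domain_tsv <- function(domains, path) {
  writeLines(c("start\tend",
               sprintf("%d\t%d", domains$start, domains$end)), path)
  invisible(path)
}

#' Read a benchmark table
#'
#' CSV with columns `id, name, n_residues, experimental_rh_A,
#' experimental_uncertainty_A, method, fasta_path, annotation_path`.
#' Relative file paths are resolved against the CSV's directory.
#'
#' @param path CSV file.
#' @return Data frame of benchmark records.
#' @export
read_benchmark_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_benchmark_csv: no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "n_residues", "experimental_rh_A",
            "experimental_uncertainty_A", "method", "fasta_path",
            "annotation_path")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("read_benchmark_csv: %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) stop(sprintf("read_benchmark_csv: %s: no records", path))
  bad <- which(!is.finite(df$experimental_rh_A) | df$experimental_rh_A <= 0)
  if (length(bad))
    stop(sprintf("read_benchmark_csv: %s: non-positive experimental_rh_A in row(s) %s",
                 path, paste(bad, collapse = ", ")))
  base <- dirname(path)
  rel <- function(p) ifelse(p == "" | grepl("^/", p), p, file.path(base, p))
  df$fasta_path <- rel(df$fasta_path)
  df$annotation_path <- rel(df$annotation_path)
  df
}

#' Write per-protein prediction results
#'
#' One row per prediction: `id, N_residues, n_beads, n_conformers, seed,
#' rh_mda_A, sem_rh_mda_A, rh_kirkwood_full_A, rh_kirkwood_simplified_A`.
#'
#' @param results Data frame with (at least) those columns.
#' @param path Output CSV.
#' @export
write_results_csv <- function(results, path) {
  need <- c("id", "N_residues", "n_beads", "n_conformers", "seed",
            "rh_mda_A", "sem_rh_mda_A", "rh_kirkwood_full_A",
            "rh_kirkwood_simplified_A")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols))
    stop(sprintf("write_results_csv: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")))
  utils::write.csv(results[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an ensemble as extended XYZ
#'
#' One frame per conformation. Each frame: a bead-count line, a comment
#' line `seed=<seed> frame=<k>`, then one line per bead with fields
#' `kind x y z steric_radius hydro_radius` (coordinates and radii in A).
#'
#' @param ensemble A [sample_ensemble()] result.
#' @param path Output file.
#' @export
write_xyz <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "sarws_ensemble"))
  b <- ensemble$chain$beads
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(ensemble$n)) {
    x <- ensemble$conformations[[k]]
    writeLines(as.character(nrow(x)), con)
    writeLines(sprintf("seed=%d frame=%d", ensemble$seed, k), con)
    writeLines(sprintf("%s %.6f %.6f %.6f %.6f %.6f", b$kind,
                       x[, 1], x[, 2], x[, 3],
                       b$steric_radius, b$hydro_radius), con)
  }
  invisible(path)
}

#' Read an extended XYZ ensemble file
#'
#' Inverse of [write_xyz()]; returns the frames and per-bead fields.
#'
#' @param path File written by [write_xyz()].
#' @return List with `frames` (list of coordinate matrices), `kind`,
#'   `steric_radius`, `hydro_radius`, `seed`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_xyz: no such file: %s", path))
  lines <- readLines(path)
  frames <- list(); kind <- NULL; rs <- NULL; rhyd <- NULL; seed <- NA_integer_
  i <- 1L
  while (i <= length(lines)) {
    nb <- suppressWarnings(as.integer(lines[i]))
    if (is.na(nb)) stop(sprintf("%s:%d: expected a bead count", path, i))
    cm <- lines[i + 1L]
    sd <- regmatches(cm, regexec("seed=(-?[0-9]+)", cm))[[1]]
    if (length(sd) == 2L) seed <- as.integer(sd[2])
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + nb)]), "\\s+")
    if (any(lengths(rows) < 6L))
      stop(sprintf("%s: frame at line %d: expected 6 fields per bead", path, i))
    m <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), nb, 3, byrow = TRUE)
    frames[[length(frames) + 1L]] <- m
    kind <- vapply(rows, `[`, character(1), 1L)
    rs <- as.numeric(vapply(rows, `[`, character(1), 5L))
    rhyd <- as.numeric(vapply(rows, `[`, character(1), 6L))
    i <- i + 2L + nb
  }
  list(frames = frames, kind = kind, steric_radius = rs,
       hydro_radius = rhyd, seed = seed)
}

#' Read model parameters from a key = value file
#'
#' Plain-text configuration mirroring [glm_params()]: one `key = value`
#' per line, `#` comments allowed; unknown keys are an error.
#'
#' @param path Configuration file.
#' @return A [glm_params()].
#' @export
read_params_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_params_file: no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  args <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("%s:%d: expected 'key = value'", path, lineno[i]))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(glm_params)))
      stop(sprintf("%s:%d: unknown parameter '%s'", path, lineno[i], key))
    args[[key]] <- if (key == "strict_residues") as.logical(val) else as.numeric(val)
  }
  do.call(glm_params, args)
}
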