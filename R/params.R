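#' Physical parameters of the globule-linker model
#'
#' Collects all tunable constants of the coarse-grained model in a single
#' validated object. The defaults are the values used throughout: folded
#' domains are spheres of bulk protein density `rho_globular` plus a
#' single hydration layer `a_hydration`; disordered residues are beads
#' whose steric diameter is the trans-peptide C-alpha spacing
#' `ca_ca_distance` and whose hydrodynamic radius is inflated to
#' `r_disordered`, the median residue hydrodynamic size.
#'
#' @param rho_globular Mass density of folded domains, Da/A^3.
#' @param a_hydration Hydration-shell thickness added to globule radii, A.
#' @param r_disordered Hydrodynamic radius of a disordered-residue bead, A.
#' @param ca_ca_distance Consecutive C-alpha distance, A; the steric
#'   diameter of a linker bead.
#' @param disorder_threshold Disorder probability below which a residue
#'   counts as ordered (strict inequality; ties are disordered).
#' @param min_ordered_run Minimum length (residues) of a sub-threshold run
#'   for it to be annotated as ordered.
#' @param max_loop Maximum length (residues) of a disordered loop that is
#'   absorbed into a folded domain when flanked by ordered segments.
#' @param overlap_tolerance Relative tolerance on the self-avoidance
#'   criterion; guards against floating-point false positives where
#'   consecutive beads touch exactly.
#' @param strict_residues If `TRUE`, ambiguity codes (X, B, Z, U) in a
#'   sequence raise an error instead of being assigned the mean standard
#'   residue mass.
#'
#' @return An object of class `"glm_params"` (a named list).
#' @examples
#' p <- glm_params()
#' p$rho_globular
#' @export
glm_params <- function(rho_globular = 0.52,
                       a_hydration = 3.0,
                       r_disordered = 4.2,
                       ca_ca_distance = 3.8,
                       disorder_threshold = 0.5,
                       min_ordered_run = 3L,
                       max_loop = 14L,
                       overlap_tolerance = 1e-9,
                       strict_residues = FALSE) {
  p <- list(
    rho_globular = as.numeric(rho_globular),
    a_hydration = as.numeric(a_hydration),
    r_disordered = as.numeric(r_disordered),
    ca_ca_distance = as.numeric(ca_ca_distance),
    disorder_threshold = as.numeric(disorder_threshold),
    min_ordered_run = as.integer(min_ordered_run),
    max_loop = as.integer(max_loop),
    overlap_tolerance = as.numeric(overlap_tolerance),
    strict_residues = isTRUE(strict_residues)
  )
  class(p) <- "glm_params"
  validate_glm_params(p)
  p
}

validate_glm_params <- function(p) {
  stopifnot(inherits(p, "glm_params"))
  for (f in c("rho_globular", "a_hydration", "r_disordered", "ca_ca_distance")) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("glm_params: '%s' must be strictly positive, got %s", f, p[[f]]))
  }
  if (!is.finite(p$disorder_threshold) ||
      p$disorder_threshold <= 0 || p$disorder_threshold >= 1)
    stop("glm_params: 'disorder_threshold' must lie in (0, 1)")
  if (p$min_ordered_run < 1L) stop("glm_params: 'min_ordered_run' must be >= 1")
  if (p$max_loop < 0L) stop("glm_params: 'max_loop' must be >= 0")
  if (!is.finite(p$overlap_tolerance) || p$overlap_tolerance < 0 ||
      p$overlap_tolerance >= 1)
    stop("glm_params: 'overlap_tolerance' must lie in [0, 1)")
  invisible(p)
}

#' @export
print.glm_params <- function(x, ...) {
  cat("Globule-linker model parameters:\n")
  cat(sprintf("  rho_globular       %.3f Da/A^3\n", x$rho_globular))
  cat(sprintf("  a_hydration        %.2f A\n", x$a_hydration))
  cat(sprintf("  r_disordered       %.2f A\n", x$r_disordered))
  cat(sprintf("  ca_ca_distance     %.2f A\n", x$ca_ca_distance))
  cat(sprintf("  disorder_threshold %.2f\n", x$disorder_threshold))
  cat(sprintf("  min_ordered_run    %d residues\n", x$min_ordered_run))
  cat(sprintf("  max_loop           %d residues\n", x$max_loop))
  cat(sprintf("  overlap_tolerance  %g\n", x$overlap_tolerance))
  invisible(x)
}
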