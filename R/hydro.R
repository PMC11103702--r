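#' Trace-contracted GRPY pair mobility
#'
#' The generalized Rotne-Prager-Yamakawa translational mobility between
#' two spheres of hydrodynamic radii `a_i`, `a_j` at centre distance `r`,
#' trace-contracted and scaled by 2*pi*eta so viscosity cancels (units
#' 1/A). Beyond contact it is the Oseen-level `1/r`; when one sphere is
#' fully contained in the other it saturates at `1/max(a_i, a_j)`; for
#' partial overlap the polydisperse RPY closed form interpolates, and the
#' three branches meet continuously.
#'
#' @param a_i,a_j Hydrodynamic radii, A (recycled to the length of `r`).
#' @param r Centre-centre distance(s), A.
#' @return Numeric vector, units 1/A.
#' @examples
#' pair_trace(1, 1, 10)       # 0.1 (1/r branch)
#' pair_trace(2, 1, 3)        # 1/3: contact, both branches agree
#' pair_trace(2, 1, 0.5)      # 0.5 = 1/max(a_i, a_j): containment
#' @export
pair_trace <- function(a_i, a_j, r) {
  k <- max(length(a_i), length(a_j), length(r))
  a_i <- rep_len(as.numeric(a_i), k)
  a_j <- rep_len(as.numeric(a_j), k)
  r <- rep_len(as.numeric(r), k)
  if (any(!is.finite(a_i)) || any(!is.finite(a_j)) || any(a_i <= 0) || any(a_j <= 0))
    stop("pair_trace: radii must be strictly positive")
  if (any(r < 0)) stop("pair_trace: distance must be >= 0")
  vapply(seq_len(k), function(i) cpp_pair_trace(a_i[i], a_j[i], r[i]),
         numeric(1))
}

# Ensemble means of the bare inverse distance and the GRPY pair trace,
# computed in one pass (diagonals zero).
mean_pair_matrices <- function(ensemble) {
  stopifnot(inherits(ensemble, "sarws_ensemble"))
  cpp_mean_pair_matrices(ensemble$conformations,
                         ensemble$chain$beads$hydro_radius)
}

#' Ensemble-averaged trace mobility matrix
#'
#' Builds the matrix A with off-diagonal entries the ensemble mean of the
#' GRPY pair trace [pair_trace()] over conformers and diagonal entries
#' `1/a_i`. The ensemble average is taken before any inversion: A itself
#' carries the equilibrium average, and the minimum dissipation estimate
#' performs a single inversion of it.
#'
#' @param ensemble A [sample_ensemble()] result.
#' @return An object of class `"mobility_trace_matrix"`: list with `A`
#'   (symmetric matrix, units 1/A) and `n_conformers_averaged`.
#' @export
build_A <- function(ensemble) {
  mats <- mean_pair_matrices(ensemble)
  A <- mats$grpy
  diag(A) <- 1 / ensemble$chain$beads$hydro_radius
  structure(list(A = A, n_conformers_averaged = ensemble$n),
            class = "mobility_trace_matrix")
}

#' Kirkwood-Riseman hydrodynamic radius
#'
#' The full form estimates `1/R_h = N^-2 (sum_i 1/a_i + sum_{i!=j}
#' <1/r_ij>)`; the simplified form drops the single-bead terms `1/a_i`,
#' whose contribution vanishes in the large-N limit. Both use the bare
#' inverse distance (Oseen level) even where linker beads overlap; set
#' `use_grpy = TRUE` to replace `<1/r_ij>` with the regularized
#' [pair_trace()] average for sensitivity analysis.
#'
#' @param ensemble A [sample_ensemble()] result.
#' @param variant `"full"` or `"simplified"`.
#' @param use_grpy Use the GRPY-regularized pair term instead of `<1/r>`.
#' @return Hydrodynamic radius, A.
#' @export
kirkwood_rh <- function(ensemble, variant = c("full", "simplified"),
                        use_grpy = FALSE) {
  variant <- match.arg(variant)
  a <- ensemble$chain$beads$hydro_radius
  n <- length(a)
  if (variant == "simplified" && n < 2L)
    stop("kirkwood_rh: the simplified form needs at least 2 beads")
  mats <- mean_pair_matrices(ensemble)
  pair_sum <- sum(if (use_grpy) mats$grpy else mats$inv_r)  # diagonals zero
  self_sum <- if (variant == "full") sum(1 / a) else 0
  inv_rh <- (self_sum + pair_sum) / n^2
  1 / inv_rh
}

#' Minimum dissipation approximation for the hydrodynamic radius
#'
#' Inverts the ensemble-averaged trace mobility, `B = A^-1`, and returns
#' `R_h = sum_ij B_ij` together with the diffusion-centre weights
#' `x_i = sum_j B_ij / sum_kj B_kj`. Equivalently, `1/R_h` is the minimum
#' of the quadratic form `x' A x` over weight vectors summing to one: the
#' short-time diffusivity of the diffusion centre, the tightest
#' single-point bound on the long-time diffusion coefficient.
#'
#' @param A A [build_A()] result or a symmetric positive-definite matrix
#'   in units 1/A.
#' @return List with `rh` (A) and `weights` (summing to 1).
#' @export
mda_rh <- function(A) {
  M <- if (inherits(A, "mobility_trace_matrix")) A$A else as.matrix(A)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "mda_rh: mobility matrix is not positive definite (smallest eigenvalue %.3e)",
      ev))
  }
  B <- chol2inv(ch)
  tot <- sum(B)
  list(rh = tot, weights = rowSums(B) / tot)
}

#' Predict the hydrodynamic radius of an annotated chain
#'
#' End-to-end composition of the pipeline: builds the globule-linker bead
#' chain, samples a seeded SARWS ensemble, and computes the minimum
#' dissipation and both Kirkwood-Riseman estimates. The Monte Carlo
#' standard error of the MDA estimate is obtained by batch means: the
#' ensemble is split into at least 4 disjoint batches, A is rebuilt and
#' inverted per batch, and the standard error of the per-batch estimates
#' is reported (per-conformer MDA values do not exist, since a single
#' inversion follows the ensemble average).
#'
#' @param track A [disorder_track()].
#' @param annotation A [segment_annotation()]; defaults to the track rules
#'   ([segments_from_track()] + [merge_loops()]).
#' @param params A [glm_params()].
#' @param n Ensemble size (conformations).
#' @param seed Integer seed.
#' @return An object of class `"hydro_result"`: list with `rh_mda`,
#'   `rh_kirkwood_full`, `rh_kirkwood_simplified` (NA for a single bead),
#'   `sem_rh_mda`, `diffusion_center_weights`, `n_conformers`, `seed`,
#'   `chain`.
#' @export
predict_rh <- function(track, annotation = NULL, params = glm_params(),
                       n = 100L, seed = 0L) {
  if (is.null(annotation))
    annotation <- merge_loops(segments_from_track(track, params), params)
  chain <- build_bead_chain(track, annotation, params)
  ens <- sample_ensemble(chain, n, seed)
  mats <- mean_pair_matrices(ens)
  a <- chain$beads$hydro_radius
  nb <- length(a)

  A <- mats$grpy
  diag(A) <- 1 / a
  mda <- mda_rh(A)

  rh_full <- nb^2 / (sum(1 / a) + sum(mats$inv_r))
  rh_simp <- if (nb >= 2L) nb^2 / sum(mats$inv_r) else NA_real_

  sem <- batch_sem_mda(ens)

  structure(list(
    rh_mda = mda$rh,
    rh_kirkwood_full = rh_full,
    rh_kirkwood_simplified = rh_simp,
    sem_rh_mda = sem,
    diffusion_center_weights = mda$weights,
    n_conformers = ens$n,
    seed = ens$seed,
    chain = chain
  ), class = "hydro_result")
}

# Standard error of the MDA estimate by batch means over >= 4 disjoint
# batches; NA when the ensemble is too small to batch.
batch_sem_mda <- function(ensemble, min_batches = 4L) {
  n <- ensemble$n
  if (n < min_batches) return(NA_real_)
  nbatch <- max(min_batches, min(10L, n %/% 10L))
  idx <- split(seq_len(n), cut(seq_len(n), nbatch, labels = FALSE))
  a <- ensemble$chain$beads$hydro_radius
  vals <- vapply(idx, function(i) {
    sub <- ensemble
    sub$conformations <- ensemble$conformations[i]
    sub$n <- length(i)
    mats <- mean_pair_matrices(sub)
    A <- mats$grpy
    diag(A) <- 1 / a
    mda_rh(A)$rh
  }, numeric(1))
  stats::sd(vals) / sqrt(length(vals))
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf("R_h (minimum dissipation): %.2f A", x$rh_mda))
  if (is.finite(x$sem_rh_mda)) cat(sprintf(" +/- %.2f (SEM)", x$sem_rh_mda))
  cat("\n")
  cat(sprintf("R_h (Kirkwood, full):      %.2f A\n", x$rh_kirkwood_full))
  if (is.finite(x$rh_kirkwood_simplified))
    cat(sprintf("R_h (Kirkwood, simplified): %.2f A\n", x$rh_kirkwood_simplified))
  cat(sprintf("ensemble: %d conformers, seed %d\n", x$n_conformers, x$seed))
  invisible(x)
}

#' Stokes-Einstein translational diffusion coefficient
#'
#' `D = k_B T / (6 pi eta R_h)` with `R_h` in A converted to metres.
#'
#' @param rh Hydrodynamic radius, A.
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return Diffusion coefficient, m^2/s.
#' @examples
#' stokes_einstein(10, 293.15, 1.002e-3) # ~2.14e-10 m^2/s
#' @export
stokes_einstein <- function(rh, temperature = 293.15, viscosity = 1.002e-3) {
  if (any(rh <= 0) || any(temperature <= 0) || any(viscosity <= 0))
    stop("stokes_einstein: all inputs must be strictly positive")
  kB <- 1.380649e-23
  kB * temperature / (6 * pi * viscosity * rh * 1e-10)
}
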