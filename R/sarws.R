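#' @useDynLib glmrh, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom utils head
#' @importFrom stats simulate coef predict
NULL

#' Auxiliary random walk of touching spheres
#'
#' Draws one unconditioned chain configuration: bead 1 at the origin and
#' each subsequent centre displaced by the sum of the adjacent steric
#' radii along an independent, uniformly distributed direction. Consecutive
#' beads touch exactly; self-avoidance is NOT enforced. This is the
#' proposal distribution of the self-avoiding random walk of spheres
#' (SARWS) and the reference arm of the rejection-sampling oracle.
#'
#' Uses the current R random-number stream.
#'
#' @param chain A [build_bead_chain()] result (or any object with
#'   `beads$steric_radius`).
#' @return Numeric matrix, one row per bead, columns x/y/z in A.
#' @export
sample_auxiliary_walk <- function(chain) {
  r <- chain$beads$steric_radius
  n <- length(r)
  if (n < 1L) stop("sample_auxiliary_walk: chain has no beads")
  x <- matrix(0, n, 3)
  if (n == 1L) return(x)
  u <- matrix(stats::rnorm(3L * (n - 1L)), n - 1L, 3L)
  u <- u / sqrt(rowSums(u^2))
  d <- r[-n] + r[-1L]
  x[-1L, ] <- apply(u * d, 2L, cumsum)
  x
}

#' Test a candidate conformation for steric self-intersection
#'
#' TRUE iff some non-adjacent bead pair (|i - j| >= 2) is closer than the
#' sum of its steric radii, up to the relative `overlap_tolerance` of the
#' chain parameters. Adjacent pairs are exempt: they touch by construction.
#'
#' @param candidate Coordinate matrix (one row per bead).
#' @param chain The [build_bead_chain()] the candidate belongs to.
#' @return Logical scalar.
#' @export
has_overlap <- function(candidate, chain) {
  r <- chain$beads$steric_radius
  n <- length(r)
  if (nrow(candidate) != n)
    stop("has_overlap: coordinate count does not match bead count")
  if (n < 3L) return(FALSE)
  d2 <- as.matrix(stats::dist(candidate))^2
  thr <- outer(r, r, "+") * (1 - chain$params$overlap_tolerance)
  sep <- abs(row(d2) - col(d2)) >= 2L
  any(d2[sep] < thr[sep]^2)
}

#' Draw one self-avoiding random walk of spheres
#'
#' Samples from the auxiliary-walk distribution conditioned on the absence
#' of self-intersections, via exact recursive dimerization: the bead list
#' is split in half, each half is sampled recursively as a valid SARWS,
#' the halves are joined with a fresh uniform bond direction, and the join
#' is accepted iff no inter-half overlap occurs; on rejection both halves
#' are redrawn. This reproduces the exact conditional distribution while
#' being far faster than one-by-one rejection for long chains. Chains of
#' at most `base` beads are sampled by one-shot rejection.
#'
#' Uses the current R random-number stream; see [sample_ensemble()] for
#' seeded, reproducible ensembles.
#'
#' @param chain A [build_bead_chain()] result.
#' @param base Base-case size of the recursion.
#' @param max_attempts Attempt budget per recursion level before a
#'   sampling-failure error is raised (pathological bead geometries).
#' @return Coordinate matrix, one row per bead, columns x/y/z in A.
#' @export
sample_sarws <- function(chain, base = 8L, max_attempts = 1e6) {
  cpp_sample_sarws(chain$beads$steric_radius, as.integer(base),
                   chain$params$overlap_tolerance, max_attempts)
}

#' One-by-one rejection sampler (reference implementation)
#'
#' Draws full auxiliary walks and rejects until one passes
#' [has_overlap()]. Exact but exponentially slow in chain length; kept as
#' the independent oracle against which the dimerization sampler is
#' validated, and as the base case of small-chain sampling.
#'
#' @inheritParams sample_sarws
#' @export
sample_sarws_rejection <- function(chain, max_attempts = 1e6) {
  for (att in seq_len(max_attempts)) {
    x <- sample_auxiliary_walk(chain)
    if (!has_overlap(x, chain)) return(x)
  }
  stop(sprintf("SARWS rejection sampling failed after %d attempts", max_attempts))
}

#' Sample a seeded conformational ensemble
#'
#' Draws `n` independent SARWS conformations from a generator seeded with
#' `seed`; the same chain, `n` and seed reproduce bit-identical
#' coordinates. The caller's random-number state is left untouched.
#'
#' @param chain A [build_bead_chain()] result.
#' @param n Number of conformations (>= 1).
#' @param seed Integer seed.
#' @param base,max_attempts Passed to [sample_sarws()].
#' @return An object of class `"sarws_ensemble"`: list with `chain`,
#'   `conformations` (list of coordinate matrices), `n`, `seed`.
#' @export
sample_ensemble <- function(chain, n, seed = 0L, base = 8L, max_attempts = 1e6) {
  n <- as.integer(n)
  if (n < 1L) stop("sample_ensemble: n must be >= 1")
  confs <- with_rng_seed(seed, {
    cpp_sample_ensemble(chain$beads$steric_radius, n, as.integer(base),
                        chain$params$overlap_tolerance, max_attempts)
  })
  structure(list(chain = chain, conformations = confs, n = n,
                 seed = as.integer(seed)),
            class = "sarws_ensemble")
}

#' @export
print.sarws_ensemble <- function(x, ...) {
  cat(sprintf("SARWS ensemble: %d conformations of %d beads (seed %d)\n",
              x$n, n_beads(x$chain), x$seed))
  invisible(x)
}

# Evaluate `expr` under a seeded RNG without disturbing the caller's
# random-number state.
with_rng_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
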