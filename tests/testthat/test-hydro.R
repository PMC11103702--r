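test_that("GRPY pair trace has the right branches and is continuous", {
  expect_equal(pair_trace(1, 1, 10), 0.1, tolerance = 1e-14)
  # contact: both branch formulas give 1/(a_i + a_j)
  expect_equal(pair_trace(2, 1, 3), 1 / 3, tolerance = 1e-12)
  # containment: 1/max
  expect_equal(pair_trace(2, 1, 0.5), 0.5, tolerance = 1e-14)
  expect_equal(pair_trace(2, 1, 1), 0.5, tolerance = 1e-12)
  # equal spheres, r -> 0: self-mobility limit 1/a
  expect_equal(pair_trace(3, 3, 1e-12), 1 / 3, tolerance = 1e-9)
  # continuity at both boundaries for assorted radius pairs
  for (a in list(c(1, 1), c(2, 1), c(4.2, 1.9), c(10, 3))) {
    s <- a[1] + a[2]; d <- abs(a[1] - a[2])
    eps <- 1e-9
    expect_equal(pair_trace(a[1], a[2], s - eps),
                 pair_trace(a[1], a[2], s + eps), tolerance = 1e-7)
    if (d > 0)
      expect_equal(pair_trace(a[1], a[2], d - eps),
                   pair_trace(a[1], a[2], d + eps), tolerance = 1e-7)
  }
  # overlap branch stays below the unregularized Oseen term
  r <- seq(0.1, 2.9, by = 0.1)
  expect_true(all(pair_trace(2, 1, r) <= 1 / r + 1e-12))
  expect_error(pair_trace(0, 1, 1), "positive")
  expect_error(pair_trace(1, 1, -1), ">= 0")
})

test_that("A matrix averages pair mobilities before inversion", {
  a <- 1.5
  ch <- chain_from_radii(c(a, a))
  # single bead
  ch1 <- chain_from_radii(a)
  A1 <- build_A(rigid_ensemble(ch1, matrix(0, 1, 3)))
  expect_equal(A1$A, matrix(1 / a, 1, 1))
  # rigid touching dimer
  X <- matrix(c(0, 0, 0, 2 * a, 0, 0), 2, 3, byrow = TRUE)
  A2 <- build_A(rigid_ensemble(ch, X))
  expect_equal(A2$A, matrix(c(1 / a, 1 / (2 * a), 1 / (2 * a), 1 / a), 2, 2),
               tolerance = 1e-12)
  # two conformations: off-diagonal is the arithmetic mean of pair traces
  X2 <- matrix(c(0, 0, 0, 4 * a, 0, 0), 2, 3, byrow = TRUE)
  ens <- rigid_ensemble(ch, X)
  ens$conformations <- list(X, X2); ens$n <- 2L
  A3 <- build_A(ens)
  expect_equal(A3$A[1, 2], (1 / (2 * a) + 1 / (4 * a)) / 2, tolerance = 1e-12)
})

test_that("Kirkwood formulas reproduce closed forms on rigid bodies", {
  a <- 2
  ch1 <- chain_from_radii(a)
  e1 <- rigid_ensemble(ch1, matrix(0, 1, 3))
  expect_equal(kirkwood_rh(e1, "full"), a)
  expect_error(kirkwood_rh(e1, "simplified"), "at least 2")
  ch <- chain_from_radii(c(a, a))
  e2 <- rigid_ensemble(ch, matrix(c(0, 0, 0, 2 * a, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(kirkwood_rh(e2, "full"), 4 * a / 3, tolerance = 1e-12)
  expect_equal(kirkwood_rh(e2, "simplified"), 4 * a, tolerance = 1e-12)
})

test_that("MDA inverts the mobility matrix and minimizes the quadratic form", {
  a <- 2.5
  expect_equal(mda_rh(matrix(1 / a, 1, 1)),
               list(rh = a, weights = 1), tolerance = 1e-12)
  A2 <- matrix(c(1 / a, 1 / (2 * a), 1 / (2 * a), 1 / a), 2, 2)
  res <- mda_rh(A2)
  expect_equal(res$rh, 4 * a / 3, tolerance = 1e-12)
  expect_equal(res$weights, c(0.5, 0.5), tolerance = 1e-12)
  # 3-bead rigid body: agree with dense minimization of x'Ax over the
  # constraint sum(x) = 1 (independent optimization oracle)
  ch3 <- chain_from_radii(c(1, 2, 1.5))
  X <- matrix(c(0, 0, 0, 3, 0, 0, 3, 3.5, 0), 3, 3, byrow = TRUE)
  A3 <- build_A(rigid_ensemble(ch3, X))$A
  qform <- function(x12) {
    x <- c(x12, 1 - sum(x12))
    drop(t(x) %*% A3 %*% x)
  }
  opt <- optim(c(1 / 3, 1 / 3), qform, method = "BFGS",
               control = list(reltol = 1e-14))
  res3 <- mda_rh(A3)
  expect_equal(res3$rh, 1 / opt$value, tolerance = 1e-7)
  expect_equal(res3$weights[1:2], opt$par, tolerance = 1e-4)
  expect_equal(sum(res3$weights), 1, tolerance = 1e-12)
  # non-positive-definite input fails loudly with the smallest eigenvalue
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(mda_rh(bad), "not positive definite")
})

test_that("MDA dominates the full Kirkwood estimate on sampled ensembles", {
  set.seed(21)
  for (k in 1:12) {
    layout <- if (k %% 2) list(c("disordered", sample(20:60, 1)))
              else list(c("disordered", sample(5:20, 1)),
                        c("ordered", sample(20:60, 1)),
                        c("disordered", sample(5:20, 1)))
    fx <- generate_fixture(layout, seed = 100 + k)
    ch <- build_bead_chain(fx$track, fx$annotation)
    ens <- sample_ensemble(ch, 15, seed = k)
    rh_mda <- mda_rh(build_A(ens))$rh
    rh_kf <- kirkwood_rh(ens, "full")
    expect_gte(rh_mda, rh_kf)
  }
})

test_that("estimators are scale covariant and permutation invariant", {
  ch <- chain_from_radii(c(1, 2, 1.5, 0.8), hydro = c(1.2, 2.5, 1.5, 1))
  set.seed(5)
  ens <- sample_ensemble(ch, 10, seed = 2)
  lam <- 2.7
  ch_s <- chain_from_radii(lam * ch$beads$steric_radius,
                           hydro = lam * ch$beads$hydro_radius)
  ens_s <- ens
  ens_s$chain <- ch_s
  ens_s$conformations <- lapply(ens$conformations, function(x) lam * x)
  expect_equal(mda_rh(build_A(ens_s))$rh, lam * mda_rh(build_A(ens))$rh,
               tolerance = 1e-10)
  expect_equal(kirkwood_rh(ens_s, "full"), lam * kirkwood_rh(ens, "full"),
               tolerance = 1e-10)
  expect_equal(kirkwood_rh(ens_s, "simplified"),
               lam * kirkwood_rh(ens, "simplified"), tolerance = 1e-10)
  # permutation of bead labels (with matching coordinates)
  perm <- c(3, 1, 4, 2)
  ch_p <- chain_from_radii(ch$beads$steric_radius[perm],
                           hydro = ch$beads$hydro_radius[perm])
  ens_p <- ens
  ens_p$chain <- ch_p
  ens_p$conformations <- lapply(ens$conformations, function(x) x[perm, ])
  expect_equal(mda_rh(build_A(ens_p))$rh, mda_rh(build_A(ens))$rh,
               tolerance = 1e-10)
  expect_equal(kirkwood_rh(ens_p, "full"), kirkwood_rh(ens, "full"),
               tolerance = 1e-10)
})

test_that("build_A and mda_rh agree with an independent R-side route", {
  # reference route: per-conformer pair distances computed with dist(),
  # mobilities assembled and averaged in R, inverted with solve()
  set.seed(9)
  ch <- chain_from_radii(runif(5, 0.5, 2), hydro = runif(5, 0.5, 2.5))
  ens <- sample_ensemble(ch, 7, seed = 3)
  a <- ch$beads$hydro_radius
  Aref <- matrix(0, 5, 5)
  for (x in ens$conformations) {
    D <- as.matrix(dist(x))
    M <- matrix(pair_trace(rep(a, each = 5), rep(a, times = 5), as.vector(D)),
                5, 5)
    diag(M) <- 0
    Aref <- Aref + M
  }
  Aref <- Aref / ens$n
  diag(Aref) <- 1 / a
  A <- build_A(ens)
  expect_equal(A$A, Aref, tolerance = 1e-10)
  expect_equal(mda_rh(A)$rh, sum(solve(Aref)), tolerance = 1e-10)
})

test_that("predict_rh composes the pipeline deterministically", {
  # a single fully ordered domain is one bead: every estimator equals the
  # globule radius, independent of ensemble size and seed
  tr <- disorder_track(strrep("A", 80), rep(0.1, 80))
  r_glob <- globule_radius(fragment_mass(strrep("A", 80)))
  for (sd in c(1, 99)) {
    res <- predict_rh(tr, n = 5, seed = sd)
    expect_equal(res$rh_mda, r_glob, tolerance = 1e-12)
    expect_equal(res$rh_kirkwood_full, r_glob, tolerance = 1e-12)
    expect_true(is.na(res$rh_kirkwood_simplified))
  }
  # same inputs and seed reproduce the result exactly
  fx <- generate_fixture(list(c("disordered", 40)), seed = 2)
  r1 <- predict_rh(fx$track, n = 24, seed = 7)
  r2 <- predict_rh(fx$track, n = 24, seed = 7)
  expect_identical(r1$rh_mda, r2$rh_mda)
  expect_identical(r1$sem_rh_mda, r2$sem_rh_mda)
  expect_true(r1$rh_mda >= r1$rh_kirkwood_full)
  expect_equal(sum(r1$diffusion_center_weights), 1, tolerance = 1e-12)
  expect_gt(r1$sem_rh_mda, 0)
})

test_that("Stokes-Einstein conversion round-trips and scales inversely", {
  D <- stokes_einstein(10, 293.15, 1.002e-3)
  expect_equal(D, 2.143e-10, tolerance = 1e-3)
  expect_equal(stokes_einstein(20, 293.15, 1.002e-3), D / 2, tolerance = 1e-12)
  # round trip through the same relation
  kB <- 1.380649e-23
  rh_back <- kB * 293.15 / (6 * pi * 1.002e-3 * D) * 1e10
  expect_equal(rh_back, 10, tolerance = 1e-12)
  expect_error(stokes_einstein(-1), "positive")
})
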