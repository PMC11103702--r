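# Builders for small bead chains and rigid ensembles used across tests.

# A bead chain with explicit radii, bypassing sequence/annotation plumbing.
chain_from_radii <- function(steric, hydro = steric, params = glm_params()) {
  n <- length(steric)
  beads <- data.frame(kind = rep("linker", n), steric_radius = steric,
                      hydro_radius = hydro, start = seq_len(n),
                      end = seq_len(n), mass = NA_real_,
                      stringsAsFactors = FALSE)
  structure(list(beads = beads, params = params), class = "bead_chain")
}

# Fully disordered chain of N glycines.
linker_chain <- function(N, params = glm_params()) {
  tr <- disorder_track(strrep("G", N), rep(0.9, N))
  build_bead_chain(tr, annotation_all_disordered(N), params)
}

# A one-conformation "ensemble" around fixed coordinates (rigid body).
rigid_ensemble <- function(chain, coords) {
  structure(list(chain = chain, conformations = list(coords), n = 1L,
                 seed = 0L),
            class = "sarws_ensemble")
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed_local <- function(seed, expr) glmrh:::with_rng_seed(seed, expr)

# A small on-disk benchmark of synthetic proteins with pseudo-experimental
# radii (ground truth is unknown; the scoring machinery is what is tested).
make_toy_benchmark <- function(dir, n_prot = 5, seed = 1) {
  set.seed(seed)
  rows <- character(0)
  for (i in seq_len(n_prot)) {
    layout <- if (i %% 2) list(c("disordered", 20 + 10 * i))
              else list(c("disordered", 10), c("ordered", 20 + 10 * i),
                        c("disordered", 10))
    fx <- generate_fixture(layout, seed = seed + i)
    id <- sprintf("p%d", i)
    write_fixture(fx, dir, id = id)
    nres <- nchar(fx$sequence)
    rh_exp <- round(2.5 * nres^0.55 + runif(1, -2, 2), 2)
    rows <- c(rows, sprintf("%s,prot%d,%d,%.2f,0.5,FCS,%s.fasta,%s.diso",
                            id, i, nres, rh_exp, id, id))
  }
  csv <- file.path(dir, "bench.csv")
  writeLines(c(paste("id,name,n_residues,experimental_rh_A",
                     "experimental_uncertainty_A,method,fasta_path",
                     "annotation_path", sep = ","), rows), csv)
  csv
}

# Consecutive-contact invariant: each bond length equals the sum of the
# adjacent steric radii to relative tolerance.
expect_touching <- function(coords, chain, tol = 1e-9) {
  r <- chain$beads$steric_radius
  n <- length(r)
  if (n < 2L) return(invisible(TRUE))
  bond <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                          coords[-n, , drop = FALSE])^2))
  expect_equal(bond, r[-n] + r[-1], tolerance = tol)
}
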