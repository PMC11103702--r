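test_that("ordered segments require a sub-threshold run of min_ordered_run", {
  seqN <- function(n) strrep("A", n)
  # no sub-threshold run at all
  ann <- segments_from_track(disorder_track(seqN(10), rep(0.9, 10)))
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$kind, "disordered")
  expect_equal(c(ann$start, ann$end), c(1L, 10L))
  # a 3-residue run becomes ordered, flanks stay disordered
  ann <- segments_from_track(
    disorder_track(seqN(7), c(0.8, 0.8, 0.3, 0.3, 0.3, 0.8, 0.8)))
  expect_equal(ann$kind, c("disordered", "ordered", "disordered"))
  expect_equal(ann$start, c(1L, 3L, 6L))
  expect_equal(ann$end, c(2L, 5L, 7L))
  # a 2-residue run is too short
  ann <- segments_from_track(disorder_track(seqN(5), c(0.3, 0.3, 0.8, 0.8, 0.8)))
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$kind, "disordered")
  # ties (P = threshold) count as disordered: strict inequality
  ann <- segments_from_track(disorder_track(seqN(4), c(0.5, 0.5, 0.5, 0.5)))
  expect_equal(ann$kind, "disordered")
  expect_error(disorder_track("", numeric(0)), "empty")
})

test_that("short loops between ordered segments are absorbed, long ones kept", {
  ann <- segment_annotation(c(1L, 21L, 31L), c(20L, 30L, 50L),
                            c("ordered", "disordered", "ordered"))
  merged <- merge_loops(ann)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$kind, "ordered")
  expect_equal(c(merged$start, merged$end), c(1L, 50L))
  # 15-residue loop exceeds max_loop = 14: unchanged
  ann <- segment_annotation(c(1L, 21L, 36L), c(20L, 35L, 50L),
                            c("ordered", "disordered", "ordered"))
  expect_equal(merge_loops(ann), ann)
  # nothing to merge without ordered segments
  ann <- segment_annotation(1L, 40L, "disordered")
  expect_equal(merge_loops(ann), ann)
  # terminal disordered tails are never absorbed
  ann <- segment_annotation(c(1L, 6L, 26L, 31L, 51L),
                            c(5L, 25L, 30L, 50L, 60L),
                            c("disordered", "ordered", "disordered",
                              "ordered", "disordered"))
  merged <- merge_loops(ann)
  expect_equal(merged$kind, c("disordered", "ordered", "disordered"))
  expect_equal(merged$start, c(1L, 6L, 51L))
})

test_that("merge_loops iterates to a fixed point and is idempotent", {
  # cascading case: fusing the inner loop creates a new flanked loop
  ann <- segment_annotation(c(1L, 11L, 21L, 31L, 45L),
                            c(10L, 20L, 30L, 44L, 80L),
                            c("ordered", "disordered", "ordered",
                              "disordered", "ordered"))
  merged <- merge_loops(ann)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$kind, "ordered")
  # idempotence on random tracks
  set.seed(42)
  for (k in 1:20) {
    n <- sample(30:120, 1)
    tr <- disorder_track(strrep("A", n), runif(n))
    m1 <- merge_loops(segments_from_track(tr))
    expect_identical(merge_loops(m1), m1)
  }
})

test_that("fragment masses sum standard average residue masses", {
  expect_equal(fragment_mass(strrep("G", 10)), 570.519, tolerance = 1e-6)
  expect_equal(fragment_mass("W"), 186.2132, tolerance = 1e-6)
  expect_error(fragment_mass(""), "non-empty")
  expect_error(fragment_mass("G1G"), "invalid residue")
  # ambiguity codes: mean standard mass unless strict
  expect_equal(fragment_mass("X"), mean(glmrh:::RESIDUE_MASS))
  expect_error(fragment_mass("X", strict = TRUE), "invalid residue")
})

test_that("globule radius follows the mass-density formula", {
  p <- glm_params()
  # mass chosen so the cube-root term is exactly 10 A
  m10 <- p$rho_globular * (4 * pi / 3) * 1000
  expect_equal(globule_radius(m10, p), 13, tolerance = 1e-12)
  expect_equal(globule_radius(20000, p), 23.94, tolerance = 1e-3)
  # limiting case: radius -> a_hydration as mass -> 0+
  expect_equal(globule_radius(1e-12, p), p$a_hydration, tolerance = 1e-3)
  expect_error(globule_radius(0), "positive")
  expect_error(globule_radius(-5), "positive")
  # strictly increasing; log-log slope -> 1/3 at large mass
  masses <- 10^seq(3, 10, by = 0.5)
  r <- globule_radius(masses, p)
  expect_true(all(diff(r) > 0))
  slope_hi <- diff(log(r))[length(r) - 1] / diff(log(masses))[1]
  expect_equal(slope_hi, 1 / 3, tolerance = 0.01)
})

test_that("bead chain construction follows the globule-linker rules", {
  p <- glm_params()
  # fully disordered: one linker bead per residue with the stated radii
  ch <- linker_chain(100)
  expect_equal(nrow(ch$beads), 100L)
  expect_true(all(ch$beads$kind == "linker"))
  expect_true(all(ch$beads$steric_radius == p$ca_ca_distance / 2))
  expect_true(all(ch$beads$hydro_radius == p$r_disordered))
  # single ordered domain: one globule bead sized by the fragment mass
  tr <- disorder_track(strrep("A", 60), rep(0.1, 60))
  ann <- segments_from_track(tr)
  ch <- build_bead_chain(tr, ann, p)
  expect_equal(nrow(ch$beads), 1L)
  expect_equal(ch$beads$kind, "globule")
  expect_equal(ch$beads$steric_radius,
               globule_radius(fragment_mass(strrep("A", 60)), p))
  expect_equal(ch$beads$steric_radius, ch$beads$hydro_radius)
  # 30 disordered + 50 ordered + 30 disordered -> 61 beads in order
  fx <- generate_fixture(list(c("disordered", 30), c("ordered", 50),
                              c("disordered", 30)), seed = 3)
  ch <- build_bead_chain(fx$track, fx$annotation, p)
  expect_equal(nrow(ch$beads), 61L)
  expect_equal(ch$beads$kind,
               c(rep("linker", 30), "globule", rep("linker", 30)))
  # residue coverage is conserved and ordered
  spans <- ch$beads$end - ch$beads$start + 1L
  expect_equal(sum(spans), 110L)
  expect_equal(ch$beads$start[1], 1L)
  expect_equal(ch$beads$end[nrow(ch$beads)], 110L)
  # length mismatch caught
  expect_error(build_bead_chain(fx$track, annotation_all_disordered(50), p),
               "covers 50")
})

test_that("bead count equals disordered residues plus merged domains", {
  set.seed(11)
  for (k in 1:15) {
    n <- sample(40:200, 1)
    tr <- disorder_track(strrep("A", n), runif(n))
    ann <- merge_loops(segments_from_track(tr))
    ch <- build_bead_chain(tr, ann)
    n_dis <- sum(ann$end[ann$kind == "disordered"] -
                   ann$start[ann$kind == "disordered"] + 1L)
    n_dom <- sum(ann$kind == "ordered")
    expect_equal(nrow(ch$beads), n_dis + n_dom)
    expect_equal(sum(ch$beads$end - ch$beads$start + 1L), n)
  }
})
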