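# Average residue masses, Da (monomer minus water); ExPASy values.
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

#' Mass of a sequence fragment
#'
#' Sum of average residue masses (monomer minus water) over the fragment.
#' No terminal water is added: fragments are interior pieces of a chain.
#' Ambiguity codes X/B/Z/U are assigned the unweighted mean standard
#' residue mass unless `strict = TRUE`.
#'
#' @param fragment Amino-acid string.
#' @param strict Error on ambiguity codes instead of using the mean mass.
#' @return Mass in Da.
#' @examples
#' fragment_mass("GGGGGGGGGG") # ~570.5 Da
#' @export
fragment_mass <- function(fragment, strict = FALSE) {
  fragment <- toupper(as.character(fragment))
  if (length(fragment) != 1L || nchar(fragment) == 0L)
    stop("fragment_mass: fragment must be a non-empty string")
  check_residues(fragment, strict)
  aa <- strsplit(fragment, "", fixed = TRUE)[[1]]
  m <- RESIDUE_MASS[aa]
  m[is.na(m)] <- mean(RESIDUE_MASS)  # ambiguity codes
  sum(m)
}

#' Steric/hydrodynamic radius of a folded domain
#'
#' A folded domain of mass m is modelled as a sphere of bulk density
#' `rho_globular` with a hydration layer: R = (3 m / (4 pi rho))^(1/3) +
#' a_hydration.
#'
#' @param mass Domain mass, Da.
#' @param params A [glm_params()].
#' @return Radius in A.
#' @examples
#' globule_radius(20000) # ~23.94 A
#' @export
globule_radius <- function(mass, params = glm_params()) {
  mass <- as.numeric(mass)
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("globule_radius: mass must be strictly positive")
  (3 * mass / (4 * pi * params$rho_globular))^(1 / 3) + params$a_hydration
}

#' Coarse-grained bead chain of the globule-linker model
#'
#' Converts a sequence plus segment annotation into the bead chain: each
#' ordered segment becomes one globule bead whose steric and hydrodynamic
#' radii both equal [globule_radius()] of the segment mass; each
#' disordered residue becomes one linker bead with steric radius
#' `ca_ca_distance / 2` and hydrodynamic radius `r_disordered`.
#'
#' @param track A [disorder_track()] (the sequence supplies domain masses).
#' @param annotation A [segment_annotation()] covering the same residues.
#' @param params A [glm_params()].
#' @return An object of class `"bead_chain"`: list with `beads` (data
#'   frame with columns `kind`, `steric_radius`, `hydro_radius`, `start`,
#'   `end`, `mass`) and `params`.
#' @export
build_bead_chain <- function(track, annotation, params = glm_params()) {
  stopifnot(inherits(track, "disorder_track"))
  validate_segment_annotation(annotation)
  n <- nchar(track$sequence)
  if (annotation_length(annotation) != n)
    stop(sprintf("build_bead_chain: annotation covers %d residues but sequence has %d",
                 annotation_length(annotation), n))
  rows <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    s <- annotation$start[i]; e <- annotation$end[i]
    if (annotation$kind[i] == "ordered") {
      frag <- substr(track$sequence, s, e)
      m <- fragment_mass(frag, strict = params$strict_residues)
      r <- globule_radius(m, params)
      rows[[i]] <- data.frame(kind = "globule", steric_radius = r,
                              hydro_radius = r, start = s, end = e,
                              mass = m, stringsAsFactors = FALSE)
    } else {
      res <- s:e
      rows[[i]] <- data.frame(kind = "linker",
                              steric_radius = params$ca_ca_distance / 2,
                              hydro_radius = params$r_disordered,
                              start = res, end = res, mass = NA_real_,
                              stringsAsFactors = FALSE)
    }
  }
  beads <- do.call(rbind, rows)
  rownames(beads) <- NULL
  structure(list(beads = beads, params = params), class = "bead_chain")
}

n_beads <- function(chain) nrow(chain$beads)

#' @export
print.bead_chain <- function(x, ...) {
  b <- x$beads
  cat(sprintf("Bead chain: %d beads (%d globules, %d linkers), %d residues\n",
              nrow(b), sum(b$kind == "globule"), sum(b$kind == "linker"),
              max(b$end)))
  glob <- b[b$kind == "globule", , drop = FALSE]
  if (nrow(glob))
    for (i in seq_len(nrow(glob)))
      cat(sprintf("  globule %d: residues %d-%d, mass %.0f Da, radius %.2f A\n",
                  i, glob$start[i], glob$end[i], glob$mass[i],
                  glob$steric_radius[i]))
  invisible(x)
}
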