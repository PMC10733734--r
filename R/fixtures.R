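## Synthetic fixtures: reference chains with canonical secondary-structure
## torsions, segment deletion (emulating missing electron density),
## environment slabs for clash-context tests, and miniature torsion
## libraries. Everything is reproducible bit-for-bit from (spec, seed).

#' Build a synthetic reference chain
#'
#' Backbone chain with canonical torsions per secondary-structure letter:
#' H (helix) phi = -57, psi = -47; E (strand) phi = -120, psi = 130;
#' C (coil) per-residue jittered draws (phi ~ -75 + N(0, 25), psi ~ 145 +
#' N(0, 30), clamped to (-180, 180]). Omega is 180 throughout. Ideal
#' covalent geometry; poly-ALA unless `sequence` is supplied. Deterministic
#' for a given seed.
#'
#' @param length Number of residues (ignored when `pattern` given).
#' @param pattern String over {H, E, C}, one letter per residue (default:
#'   all H of `length`).
#' @param sequence Optional one-letter sequence (default poly-A).
#' @param seed Integer seed for the coil draws.
#' @param chain Chain id (default "A").
#' @param bfactor Per-residue B-factor values (recycled); holds pLDDT for
#'   synthetic predicted structures.
#' @param method,resolution Structure metadata (default "xray", 1.5).
#' @param geometry Covalent geometry used for building (default ideal).
#' @param omegaJitterSd Standard deviation (degrees) of per-residue jitter
#'   around omega = 180 (default 0, exactly planar peptides).
#' @return A \linkS4class{StructureModel}.
#' @export
makeReferenceChain <- function(length = 10L, pattern = NULL, sequence = NULL,
                               seed = 1L, chain = "A", bfactor = 0,
                               method = "xray", resolution = 1.5,
                               geometry = defaultBuildGeometry(),
                               omegaJitterSd = 0) {
  if (is.null(pattern)) pattern <- strrep("H", length)
  n <- nchar(pattern)
  if (is.null(sequence)) sequence <- strrep("A", n)
  if (nchar(sequence) != n) stop("sequence and pattern lengths differ")
  set.seed(seed)
  pat <- strsplit(pattern, "")[[1]]
  tor <- data.frame(phi = numeric(n), psi = numeric(n), omega = 180)
  for (i in seq_len(n)) {
    if (pat[i] == "H") { tor$phi[i] <- -57; tor$psi[i] <- -47 }
    else if (pat[i] == "E") { tor$phi[i] <- -120; tor$psi[i] <- 130 }
    else if (pat[i] == "C") {
      tor$phi[i] <- max(-179.9, min(179.9, -75 + stats::rnorm(1, 0, 25)))
      tor$psi[i] <- max(-179.9, min(179.9, 145 + stats::rnorm(1, 0, 30)))
    } else stop("pattern letters must be H, E or C")
  }
  if (omegaJitterSd > 0) {
    tor$omega <- 180 + stats::rnorm(n, 0, omegaJitterSd)
    tor$omega <- ifelse(tor$omega > 180, tor$omega - 360, tor$omega)
  }
  frag <- buildBackbone(sequence, tor, geometry)
  at <- atomTable(frag)
  at$chain <- chain
  at$b <- rep_len(bfactor, nrow(at))
  StructureModel(at, method = method, resolution = resolution)
}

#' Delete a residue range from a structure
#'
#' Removes residues `start:end` of `chain`; the original structure is kept
#' in the `original` attribute of the result so reconstruction oracles can
#' compare rebuilt coordinates against the deleted ones.
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param start,end Inclusive author residue numbers.
#' @param chain Chain id (default first chain).
#' @return The reduced \linkS4class{StructureModel} with attribute
#'   `original`.
#' @export
deleteSegment <- function(structure, start, end, chain = NULL) {
  at <- atomTable(structure)
  if (is.null(chain)) chain <- chainIds(structure)[1]
  present <- at$resnum[at$chain == chain]
  if (!length(present) || start < min(present) || end > max(present) || start > end) {
    stop(sprintf("range %d-%d outside chain %s (%d-%d)", start, end, chain,
                 if (length(present)) min(present) else NA,
                 if (length(present)) max(present) else NA))
  }
  keep <- !(at$chain == chain & at$resnum >= start & at$resnum <= end)
  out <- StructureModel(at[keep, , drop = FALSE], method = structure@method,
                        resolution = structure@resolution,
                        modelNumber = structure@modelNumber)
  attr(out, "original") <- structure
  out
}

#' Regular pseudo-atom slab for environment clash tests
#'
#' A cubic lattice of carbon pseudo-atoms filling `[zMin, zMax]` in z over a
#' square lateral extent, standing in for environment coordinates such as a
#' lipid bilayer in clash checks.
#'
#' @param zMin,zMax Slab bounds in Angstrom.
#' @param spacing Lattice spacing in Angstrom.
#' @param xyExtent Half-width of the lateral square (default 10); the
#'   lattice covers `[-xyExtent, xyExtent]` in x and y.
#' @param element Element symbol (default "C").
#' @return Atom table of the slab (chain "Z", resname "ENV").
#' @export
makeEnvironmentSlab <- function(zMin, zMax, spacing, xyExtent = 10,
                                element = "C") {
  if (zMin >= zMax) stop("zMin must be below zMax")
  if (spacing <= 0) stop("spacing must be positive")
  xs <- seq(-xyExtent, xyExtent, by = spacing)
  zs <- seq(zMin, zMax, by = spacing)
  grid <- expand.grid(x = xs, y = xs, z = zs)
  data.frame(serial = seq_len(nrow(grid)), name = element, altloc = "",
             resname = "ENV", chain = "Z", resnum = 1L, icode = "",
             x = grid$x, y = grid$y, z = grid$z, occ = 1, b = 0,
             element = element, stringsAsFactors = FALSE)
}

#' Build a miniature torsion library from synthetic chains
#'
#' Generates `nChains` fixture chains with mixed H/E/C patterns over several
#' residue letters, tags them as 1.5 Angstrom X-ray structures, and runs
#' [buildTorsionLibrary()]. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param nChains Number of source chains (default 3).
#' @param chainLength Residues per source chain (default 24).
#' @param geometryNoise Scale factor on the natural covalent-geometry
#'   spread emulated across source chains (0 = every chain at the ideal
#'   constants, as real refinement restraints never are; 1 = one standard
#'   deviation of the Engh-Huber restraint widths: 0.014-0.021 Angstrom on
#'   bond lengths, about 2 degrees on bond angles, 5.8 degrees per-residue
#'   on omega). Use 0 for exactness oracles; use 1 when the library must
#'   behave like one harvested from real crystal structures, e.g. to give
#'   gap closure a non-degenerate criteria band.
#' @return A \linkS4class{TorsionLibrary}.
#' @export
makeMiniLibrary <- function(seed = 1L, nChains = 3L, chainLength = 24L,
                            geometryNoise = 0) {
  if (nChains < 1L) stop("nChains must be >= 1")
  set.seed(seed)
  letters20 <- c("A", "G", "P", "S", "T", "V", "L", "K", "E", "D",
                 "N", "Q", "R", "I", "F", "Y", "W", "M", "H", "C")
  gIdeal <- defaultBuildGeometry()
  ## alanine-rich composition: the fixture templates this library serves are
  ## poly-ALA, and sequence-matched sampling needs multiple A-runs to draw
  ## from at every chunk length
  letterProb <- c(0.35, rep(0.65 / (length(letters20) - 1),
                            length(letters20) - 1))
  structures <- list()
  for (ci in seq_len(nChains)) {
    pat <- paste(sample(c("H", "E", "C"), chainLength, replace = TRUE,
                        prob = c(0.4, 0.25, 0.35)), collapse = "")
    sq <- paste(sample(letters20, chainLength, replace = TRUE,
                       prob = letterProb), collapse = "")
    g <- gIdeal
    if (geometryNoise > 0) {
      s <- geometryNoise
      g$bNCA <- gIdeal$bNCA + stats::rnorm(1, 0, 0.019 * s)
      g$bCAC <- gIdeal$bCAC + stats::rnorm(1, 0, 0.021 * s)
      g$bCN <- gIdeal$bCN + stats::rnorm(1, 0, 0.014 * s)
      g$aNCAC <- gIdeal$aNCAC + stats::rnorm(1, 0, 2.8 * s)
      g$aCACN <- gIdeal$aCACN + stats::rnorm(1, 0, 2.0 * s)
      g$aCNCA <- gIdeal$aCNCA + stats::rnorm(1, 0, 1.8 * s)
    }
    structures[[sprintf("mini_%02d", ci)]] <-
      makeReferenceChain(pattern = pat, sequence = sq,
                         seed = seed * 1000L + ci, geometry = g,
                         omegaJitterSd = 5.8 * geometryNoise)
  }
  buildTorsionLibrary(structures, maxResolution = 1.8)
}
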