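## Sequential internal-to-Cartesian backbone construction. Torsions are the
## only sampled degrees of freedom; covalent geometry is fixed at
## Engh-Huber-like constants supplied by defaultBuildGeometry().

#' Fixed covalent geometry used by the backbone builder
#'
#' Bond lengths (Angstrom) and bond angles (degrees) for the peptide
#' backbone, plus carbonyl-O and amide-H placement constants. Only torsion
#' angles are sampled during building; covalent geometry is held at these
#' constants.
#'
#' @return A named list: `bNCA`, `bCAC`, `bCN` (bond lengths), `aNCAC`,
#'   `aCACN`, `aCNCA` (backbone bond angles), `bCO`, `aCACO` (carbonyl O),
#'   `bNH`, `aCNH` (amide H).
#' @export
defaultBuildGeometry <- function() {
  list(bNCA = 1.458, bCAC = 1.525, bCN = 1.329,
       aNCAC = 111.0, aCACN = 116.2, aCNCA = 121.7,
       bCO = 1.231, aCACO = 120.1,
       bNH = 1.010, aCNH = 119.3)
}

.checkBuildGeometry <- function(g) {
  lens <- c(g$bNCA, g$bCAC, g$bCN, g$bCO, g$bNH)
  angs <- c(g$aNCAC, g$aCACN, g$aCNCA, g$aCACO, g$aCNH)
  if (any(lens <= 0.8 | lens >= 2.0)) stop("bond lengths must lie in (0.8, 2.0) Angstrom")
  if (any(angs <= 90 | angs >= 140)) stop("bond angles must lie in (90, 140) degrees")
  invisible(g)
}

## One-letter -> three-letter residue codes (backbone-only scope).
.aa123 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
            E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
            M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
            Y = "TYR", V = "VAL", X = "UNK")

## Three-letter -> one-letter, including phospho/modified parents.
.aa321 <- c(stats::setNames(names(.aa123), .aa123),
            SEP = "S", TPO = "T", PTR = "Y", MSE = "M", HSD = "H", HSE = "H")

#' Build an isolated backbone chain from a torsion path
#'
#' Places N, CA, C sequentially from internal coordinates (natural extension
#' reference frame), then adds the carbonyl oxygen in the peptide plane
#' opposite the next residue's amide nitrogen (psi-based placement for the
#' final residue) and the amide hydrogen anti to the preceding carbonyl
#' oxygen (no H for proline, none for the first residue of the isolated
#' chain). The first residue sits in a canonical frame: N at the origin,
#' CA on +x, C in the xy-plane.
#'
#' Per-residue torsion conventions: phi(i) = C(i-1)-N(i)-CA(i)-C(i) (unused
#' for the first residue), psi(i) = N(i)-CA(i)-C(i)-N(i+1), omega(i) =
#' CA(i)-C(i)-N(i+1)-CA(i+1) (psi of the last residue orients the terminal
#' O; its omega is unused).
#'
#' @param sequence One-letter sequence string.
#' @param torsions data.frame with columns phi, psi, omega (degrees), one
#'   row per residue.
#' @param geometry Covalent geometry, see [defaultBuildGeometry()].
#' @return A \linkS4class{BackboneFragment} with residues numbered 1..n.
#' @export
buildBackbone <- function(sequence, torsions, geometry = defaultBuildGeometry()) {
  .checkBuildGeometry(geometry)
  n <- nchar(sequence)
  if (n < 1L) stop("sequence must be non-empty")
  if (nrow(torsions) != n) {
    stop(sprintf("torsion path length (%d) does not match sequence length (%d)",
                 nrow(torsions), n))
  }
  letters1 <- strsplit(sequence, "")[[1]]
  g <- geometry

  bb <- .backboneNCAC(n, torsions, g)
  N <- bb$N; CA <- bb$CA; C <- bb$C
  O <- matrix(NA_real_, n, 3)
  H <- matrix(NA_real_, n, 3)

  ## carbonyl O: anti to N(i+1) about the CA-C axis, i.e. torsion
  ## N-CA-C-O = psi - 180; the same rule with the supplied terminal psi
  ## orients the final residue's O.
  for (i in seq_len(n)) {
    psi <- torsions$psi[i]
    if (!is.finite(psi)) psi <- 180
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], g$bCO, g$aCACO, psi - 180)
  }
  ## amide H: in the peptide plane, anti to the preceding carbonyl O
  for (i in seq_len(n)[-1]) {
    if (letters1[i] == "P") next
    H[i, ] <- placeAtom(O[i - 1, ], C[i - 1, ], N[i, ], g$bNH, g$aCNH, 180)
  }

  hasH <- c(FALSE, letters1[-1] != "P")
  counts <- 4L + hasH
  total <- sum(counts)
  name <- unlist(lapply(seq_len(n), function(i) {
    if (hasH[i]) c("N", "CA", "C", "O", "H") else c("N", "CA", "C", "O")
  }), use.names = FALSE)
  xyz <- matrix(NA_real_, total, 3)
  offs <- cumsum(c(0L, counts[-n]))
  for (i in seq_len(n)) {
    o <- offs[i]
    xyz[o + 1L, ] <- N[i, ]; xyz[o + 2L, ] <- CA[i, ]
    xyz[o + 3L, ] <- C[i, ]; xyz[o + 4L, ] <- O[i, ]
    if (hasH[i]) xyz[o + 5L, ] <- H[i, ]
  }
  atoms <- data.frame(
    serial = seq_len(total), name = name, altloc = "",
    resname = rep(unname(.aa123[letters1]), counts), chain = "A",
    resnum = rep(seq_len(n), counts), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
    element = substr(name, 1, 1), stringsAsFactors = FALSE)
  new("BackboneFragment", atoms = atoms,
      torsions = as.data.frame(torsions)[, c("phi", "psi", "omega")],
      segment = list())
}

## Sequential N/CA/C placement from a torsion path (canonical first-residue
## frame); the coordinate core shared by buildBackbone and the gap-closure
## pool sampler, which scans junction geometry without atom tables.
.backboneNCAC <- function(n, torsions, g) {
  N <- matrix(NA_real_, n, 3)
  CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3)
  ## canonical first residue: N origin, CA on +x, C in the xy-plane
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$bNCA, 0, 0)
  th <- .deg2rad(g$aNCAC)
  C[1, ] <- CA[1, ] + g$bCAC * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                        g$bCN, g$aCACN, torsions$psi[i - 1])
    CA[i, ] <- placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                         g$bNCA, g$aCNCA, torsions$omega[i - 1])
    C[i, ] <- placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                        g$bCAC, g$aNCAC, torsions$phi[i])
  }
  list(N = N, CA = CA, C = C)
}

#' Measure the torsion path of a backbone atom table
#'
#' Back-computes phi/psi/omega per residue from N/CA/C coordinates, the
#' inverse of [buildBackbone()]. Undefined angles at chain ends are NA.
#'
#' @param atoms Atom table containing N, CA, C per residue of one chain.
#' @return data.frame with columns resnum, phi, psi, omega (degrees).
#' @export
measureTorsions <- function(atoms) {
  bb <- .backboneArray(atoms)
  n <- nrow(bb$N)
  out <- data.frame(resnum = bb$resnum, phi = NA_real_, psi = NA_real_,
                    omega = NA_real_)
  for (i in seq_len(n)) {
    if (i > 1L) {
      out$phi[i] <- dihedralAngle(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    }
    if (i < n) {
      out$psi[i] <- dihedralAngle(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
      out$omega[i] <- dihedralAngle(bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ], bb$CA[i + 1, ])
    }
  }
  out
}

## Extract per-residue backbone coordinate matrices (N/CA/C, ordered by
## residue) from an atom table restricted to a single chain.
.backboneArray <- function(atoms) {
  key <- paste(atoms$resnum, atoms$icode)
  resk <- unique(key)
  n <- length(resk)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  resnum <- integer(n)
  for (i in seq_len(n)) {
    sub <- atoms[key == resk[i], ]
    resnum[i] <- sub$resnum[1]
    for (nm in c("N", "CA", "C")) {
      row <- sub[sub$name == nm, , drop = FALSE]
      if (nrow(row)) {
        m <- switch(nm, N = "N", CA = "CA", C = "C")
        coords <- c(row$x[1], row$y[1], row$z[1])
        if (nm == "N") N[i, ] <- coords
        if (nm == "CA") CA[i, ] <- coords
        if (nm == "C") C[i, ] <- coords
      }
    }
  }
  if (anyNA(N) || anyNA(CA) || anyNA(C)) {
    stop("backbone atoms (N, CA, C) missing from atom table")
  }
  list(N = N, CA = CA, C = C, resnum = resnum)
}
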