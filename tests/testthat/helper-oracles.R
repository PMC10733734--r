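# Independent oracles used to cross-check the package's own geometry,
# superposition, clash and builder code. These deliberately use different
# algorithms from the implementation they verify.

# Horn's quaternion method for least-squares superposition: the optimal
# rotation is the eigenvector of the 4x4 key matrix with the largest
# eigenvalue; the residual gives the RMSD in closed form.
quaternionRmsd <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  n <- nrow(mobile)
  M <- sweep(mobile, 2, colMeans(mobile))
  T <- sweep(target, 2, colMeans(target))
  S <- t(M) %*% T
  key <- matrix(0, 4, 4)
  key[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  key[1, 2] <- key[2, 1] <- S[2, 3] - S[3, 2]
  key[1, 3] <- key[3, 1] <- S[3, 1] - S[1, 3]
  key[1, 4] <- key[4, 1] <- S[1, 2] - S[2, 1]
  key[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  key[2, 3] <- key[3, 2] <- S[1, 2] + S[2, 1]
  key[2, 4] <- key[4, 2] <- S[1, 3] + S[3, 1]
  key[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  key[3, 4] <- key[4, 3] <- S[2, 3] + S[3, 2]
  key[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(M^2) + sum(T^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# All-pairs O(n^2) clash count, the brute-force reference for the cell-list
# neighbour search.
bruteClashCount <- function(fragAtoms, contextAtoms, params, exclude = NULL) {
  radius <- function(el) {
    el <- toupper(trimws(el))
    el[el == "NA"] <- "NA."
    r <- unname(params$radii[el])
    r[is.na(r)] <- params$fallbackRadius
    r
  }
  rf <- radius(fragAtoms$element)
  rc <- radius(contextAtoms$element)
  exKey <- if (!is.null(exclude) && NROW(exclude)) {
    paste(exclude[, 1], exclude[, 2])
  } else character(0)
  count <- 0L
  for (i in seq_len(nrow(fragAtoms))) {
    d <- sqrt((contextAtoms$x - fragAtoms$x[i])^2 +
              (contextAtoms$y - fragAtoms$y[i])^2 +
              (contextAtoms$z - fragAtoms$z[i])^2)
    hit <- d < rf[i] + rc - params$tolerance
    if (length(exKey)) hit <- hit & !(paste(i, seq_along(d)) %in% exKey)
    count <- count + sum(hit)
  }
  count
}

# Textbook two-plane-normal dihedral: angle between the plane normals with
# the sign taken from the triple product. A different formulation from the
# atan2 expression used in the package.
referenceDihedral <- function(a, b, c, d) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b - a, c - b)
  n2 <- cross(c - b, d - c)
  cosphi <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  phi <- acos(max(-1, min(1, cosphi))) * 180 / pi
  if (sum(cross(n1, n2) * (c - b)) < 0) phi <- -phi
  if (phi <= -180) phi <- phi + 360
  phi
}

# Independent internal-to-Cartesian builder: places each backbone atom by
# explicit axis-angle (Rodrigues) rotations instead of the local-frame
# construction used by the package.
rodriguesBackbone <- function(torsions, g = defaultBuildGeometry()) {
  rot <- function(axis, theta) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  }
  place <- function(a, b, c, bond, angDeg, dihDeg) {
    # start from the extension of b -> c, bend by (180 - angle) about the
    # normal of (a, b, c), then twist about b -> c by the dihedral
    u <- (c - b); u <- u / sqrt(sum(u^2))
    nrm <- c((b - a)[2] * u[3] - (b - a)[3] * u[2],
             (b - a)[3] * u[1] - (b - a)[1] * u[3],
             (b - a)[1] * u[2] - (b - a)[2] * u[1])
    v <- rot(nrm, (180 - angDeg) * pi / 180) %*% u
    v <- rot(u, dihDeg * pi / 180) %*% v
    c + bond * as.numeric(v)
  }
  n <- nrow(torsions)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$bNCA, 0, 0)
  th <- g$aNCAC * pi / 180
  C[1, ] <- CA[1, ] + g$bCAC * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                    g$bCN, g$aCACN, torsions$psi[i - 1])
    CA[i, ] <- place(CA[i - 1, ], C[i - 1, ], N[i, ],
                     g$bNCA, g$aCNCA, torsions$omega[i - 1])
    C[i, ] <- place(C[i - 1, ], N[i, ], CA[i, ],
                    g$bCAC, g$aNCAC, torsions$phi[i])
  }
  list(N = N, CA = CA, C = C)
}

# Shared fixture: ideal reference chain + full-length sequence set.
helixFixture <- function(n = 14, seed = 2) {
  list(structure = makeReferenceChain(length = n, seed = seed),
       sequences = SequenceSet(stats::setNames(strrep("A", n), "A")))
}

# Backbone coordinates of one residue from an atom table, as a named list.
residueAtoms <- function(atoms, resnum, chain = "A") {
  sub <- atoms[atoms$chain == chain & atoms$resnum == resnum, , drop = FALSE]
  out <- list()
  for (nm in unique(sub$name)) {
    r <- sub[sub$name == nm, ][1, ]
    out[[nm]] <- c(r$x, r$y, r$z)
  }
  out
}
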