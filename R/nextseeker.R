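## Geometric closure of internal gaps: fragment pools grown from both
## anchors, junction screening against library-derived criteria, and
## remodelling of the carbonyl O / amide H at the accepted junction.

.circularMeanDeg <- function(x) {
  m <- .rad2deg(atan2(mean(sin(.deg2rad(x))), mean(cos(.deg2rad(x)))))
  if (m <= -180) m + 360 else m
}

.circularSdDeg <- function(x, mu = .circularMeanDeg(x)) {
  if (length(x) < 2L) return(0)
  d <- ((x - mu + 180) %% 360) - 180  # signed deviation on the circle
  sqrt(sum(d^2) / (length(d) - 1L))
}

#' Derive gap-closure criteria from library geometry statistics
#'
#' Means are taken from the library's junction statistics; tolerances are
#' `nSigma` standard deviations with a floor of 1e-3 (so zero-variance ideal
#' libraries still admit exact matches). The omega criterion uses only the
#' trans pool (|omega| > 90 degrees) with circular mean and spread.
#'
#' @param library A \linkS4class{TorsionLibrary}.
#' @param nSigma Tolerance width in standard deviations (default 3).
#' @return List of (mean, tol) pairs: `dCN`, `dCCA`, `angleCACN`, `omega`.
#' @export
deriveClosureCriteria <- function(library, nSigma = 3) {
  gs <- geometryStats(library)
  if (!nrow(gs) || any(gs$n == 0)) stop("library geometry statistics are empty")
  row <- function(q) gs[gs$quantity == q, ]
  tol <- function(s) max(nSigma * s, 1e-3)
  omTrans <- library@provenance$omegaTrans
  if (is.null(omTrans) || !length(omTrans)) {
    stop("library has no trans-omega pool for the closure criterion")
  }
  omMean <- .circularMeanDeg(omTrans)
  list(dCN = list(mean = row("dCN")$mean, tol = tol(row("dCN")$sd)),
       dCCA = list(mean = row("dCCA")$mean, tol = tol(row("dCCA")$sd)),
       angleCACN = list(mean = row("angleCACN")$mean,
                        tol = tol(row("angleCACN")$sd)),
       omega = list(mean = omMean, tol = tol(.circularSdDeg(omTrans, omMean))))
}

#' Check the geometry of a candidate peptide junction
#'
#' Measures d(C_i, N_i+1), d(C_i, CA_i+1), the CA_i-C_i-N_i+1 bond angle
#' and the omega torsion CA_i-C_i-N_i+1-CA_i+1, and compares each against
#' mean +/- tol of the criteria (omega on the circle).
#'
#' @param resI List with `CA` and `C` 3-vectors of residue i.
#' @param resIp1 List with `N` and `CA` 3-vectors of residue i+1.
#' @param criteria Result of [deriveClosureCriteria()].
#' @return List: `pass` (logical), `values`, `deviations` (absolute, named),
#'   `normalized` (deviation / tol, named).
#' @export
checkJunction <- function(resI, resIp1, criteria) {
  if (is.null(resI$CA) || is.null(resI$C)) stop("residue i needs CA and C atoms")
  if (is.null(resIp1$N) || is.null(resIp1$CA)) stop("residue i+1 needs N and CA atoms")
  vals <- c(dCN = .vnorm(resIp1$N - resI$C),
            dCCA = .vnorm(resIp1$CA - resI$C),
            angleCACN = bondAngle(resI$CA, resI$C, resIp1$N),
            omega = dihedralAngle(resI$CA, resI$C, resIp1$N, resIp1$CA))
  dev <- c(dCN = abs(vals["dCN"] - criteria$dCN$mean),
           dCCA = abs(vals["dCCA"] - criteria$dCCA$mean),
           angleCACN = abs(vals["angleCACN"] - criteria$angleCACN$mean),
           omega = angularDistance(vals["omega"], criteria$omega$mean))
  names(dev) <- names(vals)
  tols <- c(criteria$dCN$tol, criteria$dCCA$tol, criteria$angleCACN$tol,
            criteria$omega$tol)
  norm <- dev / tols
  list(pass = all(dev <= tols), values = vals, deviations = dev,
       normalized = norm)
}

#' Remodel the carbonyl oxygen and amide hydrogen at a closure junction
#'
#' Places O bonded to C_i in the CA_i-C_i-N_i+1 plane on the far side from
#' the amide nitrogen (torsion N_i+1-CA_i-C_i-O = 180) at the ideal C=O
#' length and CA-C-O angle, and H bonded to N_i+1 in the same peptide plane
#' anti to O (torsion O-C_i-N_i+1-H = 180) at the ideal N-H length and
#' C-N-H angle. Proline at i+1 gets no amide hydrogen.
#'
#' @param resI List with `CA`, `C` of residue i.
#' @param resIp1 List with `N`, `CA` of residue i+1.
#' @param geometry See [defaultBuildGeometry()].
#' @param prolineIp1 TRUE when residue i+1 is proline.
#' @return List with `O` (3-vector) and `H` (3-vector or NULL).
#' @export
remodelClosure <- function(resI, resIp1, geometry = defaultBuildGeometry(),
                           prolineIp1 = FALSE) {
  O <- placeAtom(resIp1$N, resI$CA, resI$C, geometry$bCO, geometry$aCACO, 180)
  H <- if (prolineIp1) NULL else
    placeAtom(O, resI$C, resIp1$N, geometry$bNH, geometry$aCNH, 180)
  list(O = O, H = H)
}

## Draw torsion paths until every peptide omega that will become a junction
## of the built fragment (all but the final residue's) lies inside the
## criteria band. Fragments violating the band would re-emit junctions the
## closure check itself rejects, so they are never built.
.sampleOmegaScreened <- function(ext, library, chunkMax, index, criteria,
                                 maxTries = 100L) {
  for (t in seq_len(maxTries)) {
    tor <- sampleTorsionPath(ext, library, chunkMax = chunkMax, index = index)
    om <- tor$omega[-nrow(tor)]
    if (all(angularDistance(om, criteria$omega$mean) <= criteria$omega$tol)) {
      return(tor)
    }
  }
  stop("could not draw a torsion path with all peptide omegas inside the ",
       "closure criteria band; the library omega pool is inconsistent with ",
       "the criteria")
}

## Atom coordinates of one fragment residue as a named list.
.fragResidue <- function(atoms, resnum) {
  sub <- atoms[atoms$resnum == resnum, , drop = FALSE]
  out <- list()
  for (nm in unique(sub$name)) {
    r <- sub[sub$name == nm, ][1, ]
    out[[nm]] <- c(r$x, r$y, r$z)
  }
  out
}

#' Close an internal gap with fragment pairs grown from both anchors
#'
#' Builds `poolSize` forward fragments (anchored by Kabsch superposition at
#' the upstream template anchor) and, in `junction_scan` mode, `poolSize`
#' backward fragments anchored at the downstream anchor, each spanning the
#' full gap. Pairs are scanned in pool order with the junction index
#' ascending; the first junction passing [checkJunction()] yields the
#' chimera forward[first..k] + backward[k+1..last]. A forward fragment whose
#' last residue closes directly onto the downstream template anchor is also
#' accepted (this is the only route in `anchor_only` mode, and the only
#' possible junction for a gap of length 1). The accepted chimera has its
#' junction carbonyl O / amide H remodelled and must pass the clash check
#' against `contextAtoms`.
#'
#' @param segment An L-IDR segment (data.frame row or list).
#' @param template \linkS4class{StructureModel}.
#' @param library \linkS4class{TorsionLibrary}.
#' @param criteria Result of [deriveClosureCriteria()].
#' @param poolSize Fragments per pool (default 50).
#' @param mode "junction_scan" (default) or "anchor_only".
#' @param contextAtoms Atom table used for clash screening (template without
#'   the anchor residues, environment, previously placed fragments); NULL
#'   disables the clash screen.
#' @param clashParams See [defaultClashParams()].
#' @param chunkMax Torsion sampling chunk size.
#' @param geometry See [defaultBuildGeometry()].
#' @return List: `success`; on success `fragment` (placed
#'   \linkS4class{BackboneFragment}), `junction` (residue i of the closure),
#'   `check` (junction report), `attempts`; on failure `best` (smallest
#'   max-normalised-deviation candidate: junction, values, deviations).
#' @export
closeGap <- function(segment, template, library, criteria, poolSize = 50L,
                     mode = c("junction_scan", "anchor_only"),
                     contextAtoms = NULL, clashParams = defaultClashParams(),
                     chunkMax = 5L, geometry = defaultBuildGeometry()) {
  mode <- match.arg(mode)
  seg <- .segmentAsList(segment)
  if (seg$kind != "L-IDR") stop("closeGap handles L-IDR segments only")
  upLetter <- .templateLetter(template, seg$chain, seg$upstreamAnchor)
  downLetter <- .templateLetter(template, seg$chain, seg$downstreamAnchor)
  tmplAtoms <- atomTable(template)
  downAnchor <- .residueBackbone(tmplAtoms, seg$chain, seg$downstreamAnchor)
  gapseq <- seg$sequence
  lets <- strsplit(gapseq, "")[[1]]

  upAnchor <- .residueBackbone(tmplAtoms, seg$chain, seg$upstreamAnchor)
  n <- seg$last - seg$first + 1L
  extF <- paste0(upLetter, gapseq)
  extB <- paste0(gapseq, downLetter)

  ## pools are kept as bare N/CA/C coordinate matrices in the template
  ## frame plus the torsion path; full atom tables are only materialised
  ## for candidates that reach the acceptance step
  samplePool <- function(ext, anchorRow, anchor) {
    idx <- chunkMatchIndex(ext, library, chunkMax)
    target <- rbind(anchor$N, anchor$CA, anchor$C)
    lapply(seq_len(poolSize), function(p) {
      tor <- .sampleOmegaScreened(ext, library, chunkMax, idx, criteria)
      bb <- .backboneNCAC(n + 1L, tor, geometry)
      fit <- kabschSuperpose(rbind(bb$N[anchorRow, ], bb$CA[anchorRow, ],
                                   bb$C[anchorRow, ]), target)
      list(tor = tor, N = applySuperposition(bb$N, fit),
           CA = applySuperposition(bb$CA, fit),
           C = applySuperposition(bb$C, fit))
    })
  }
  fwd <- samplePool(extF, 1L, upAnchor)
  bwd <- if (mode == "junction_scan") {
    samplePool(extB, n + 1L, downAnchor)
  } else list()
  ## residue rows: forward gap resnum q -> row q - first + 2 (row 1 is the
  ## anchor copy); backward q -> row q - first + 1 (last row anchor copy)
  rowF <- function(q) q - seg$first + 2L
  rowB <- function(q) q - seg$first + 1L
  materialize <- function(pool, ext, anchorEnd, i) {
    attachFragment(buildBackbone(ext, pool[[i]]$tor, geometry), seg,
                   template, anchorEnd = anchorEnd)
  }
  best <- NULL
  attempts <- 0L

  tryAccept <- function(chimAtoms, junction, chk) {
    ## remodel O/H at the closure point, then clash-screen the chimera
    if (junction < seg$last) {
      ri <- .fragResidue(chimAtoms, junction)
      rip1 <- .fragResidue(chimAtoms, junction + 1L)
      isPro <- lets[junction + 1L - seg$first + 1L] == "P"
      new <- remodelClosure(ri, rip1, geometry, prolineIp1 = isPro)
      chimAtoms[chimAtoms$resnum == junction & chimAtoms$name == "O",
                c("x", "y", "z")] <- rbind(new$O)
      if (!is.null(new$H) && any(chimAtoms$resnum == junction + 1L & chimAtoms$name == "H")) {
        chimAtoms[chimAtoms$resnum == junction + 1L & chimAtoms$name == "H",
                  c("x", "y", "z")] <- rbind(new$H)
      }
    } else {
      ## closure onto the template anchor: remodel the built residue's O
      ri <- .fragResidue(chimAtoms, junction)
      new <- remodelClosure(ri, downAnchor, geometry, prolineIp1 = TRUE)
      chimAtoms[chimAtoms$resnum == junction & chimAtoms$name == "O",
                c("x", "y", "z")] <- rbind(new$O)
    }
    if (!is.null(contextAtoms)) {
      cc <- clashCheck(chimAtoms, contextAtoms, clashParams)
      if (cc$count > 0L) return(NULL)
    }
    rownames(chimAtoms) <- NULL
    new("BackboneFragment", atoms = chimAtoms, torsions = data.frame(),
        segment = seg)
  }

  poolArray <- function(pool, field, row) {
    t(vapply(pool, function(x) x[[field]][row, ], numeric(3)))
  }
  scanK <- if (n >= 2L) seg$first:(seg$last - 1L) else integer(0)
  if (mode == "junction_scan" && length(scanK)) {
    fC <- lapply(scanK, function(k) poolArray(fwd, "C", rowF(k)))
    fCA <- lapply(scanK, function(k) poolArray(fwd, "CA", rowF(k)))
    bN <- lapply(scanK, function(k) poolArray(bwd, "N", rowB(k + 1L)))
    bCA <- lapply(scanK, function(k) poolArray(bwd, "CA", rowB(k + 1L)))
    names(fC) <- names(fCA) <- names(bN) <- names(bCA) <- scanK
  }

  ## all-pairs sweep, junction by junction, with a cheap d(C,N) prefilter:
  ## only pairs inside the dCN band get the full four-criterion evaluation.
  P <- length(fwd)
  candList <- list()
  if (mode == "junction_scan" && length(scanK)) {
    for (ki in seq_along(scanK)) {
      kk <- as.character(scanK[ki])
      fc <- fC[[kk]]; bn <- bN[[kk]]
      d2 <- outer(rowSums(fc^2), rowSums(bn^2), "+") - 2 * (fc %*% t(bn))
      dcn <- sqrt(pmax(d2, 0))
      attempts <- attempts + length(dcn)
      hit <- which(abs(dcn - criteria$dCN$mean) <= criteria$dCN$tol,
                   arr.ind = TRUE)
      ## full metrics for the prefilter survivors, plus the globally
      ## closest-dCN pair so a failure report always has a best candidate
      nearest <- arrayInd(which.min(abs(dcn - criteria$dCN$mean)), dim(dcn))
      probe <- unique(rbind(hit, nearest))
      if (nrow(probe)) {
        m <- .junctionMetricsVec(fCA[[kk]][probe[, 1], , drop = FALSE],
                                 fC[[kk]][probe[, 1], , drop = FALSE],
                                 bN[[kk]][probe[, 2], , drop = FALSE],
                                 bCA[[kk]][probe[, 2], , drop = FALSE])
        dev <- cbind(dCN = abs(m$dCN - criteria$dCN$mean),
                     dCCA = abs(m$dCCA - criteria$dCCA$mean),
                     angleCACN = abs(m$angleCACN - criteria$angleCACN$mean),
                     omega = angularDistance(m$omega, criteria$omega$mean))
        norm <- sweep(dev, 2, c(criteria$dCN$tol, criteria$dCCA$tol,
                                criteria$angleCACN$tol, criteria$omega$tol), "/")
        worst <- apply(norm, 1, max)
        bi <- which.min(worst)
        if (is.null(best) || worst[bi] < best$score) {
          best <- list(score = worst[bi], junction = scanK[ki],
                       values = c(dCN = m$dCN[bi], dCCA = m$dCCA[bi],
                                  angleCACN = m$angleCACN[bi],
                                  omega = m$omega[bi]),
                       deviations = dev[bi, ], normalized = norm[bi, ])
        }
        ok <- which(worst <= 1)
        if (length(ok)) {
          candList[[length(candList) + 1L]] <-
            cbind(f = probe[ok, 1], b = probe[ok, 2], k = scanK[ki])
        }
      }
    }
  }
  ## forward fragments closing directly onto the downstream template anchor
  fcl <- poolArray(fwd, "C", rowF(seg$last))
  fcal <- poolArray(fwd, "CA", rowF(seg$last))
  mA <- .junctionMetricsVec(fcal, fcl,
                            matrix(downAnchor$N, P, 3, byrow = TRUE),
                            matrix(downAnchor$CA, P, 3, byrow = TRUE))
  devA <- cbind(dCN = abs(mA$dCN - criteria$dCN$mean),
                dCCA = abs(mA$dCCA - criteria$dCCA$mean),
                angleCACN = abs(mA$angleCACN - criteria$angleCACN$mean),
                omega = angularDistance(mA$omega, criteria$omega$mean))
  normA <- sweep(devA, 2, c(criteria$dCN$tol, criteria$dCCA$tol,
                            criteria$angleCACN$tol, criteria$omega$tol), "/")
  attempts <- attempts + P
  worstA <- apply(normA, 1, max)
  bi <- which.min(worstA)
  if (is.null(best) || worstA[bi] < best$score) {
    best <- list(score = worstA[bi], junction = seg$last,
                 values = c(dCN = mA$dCN[bi], dCCA = mA$dCCA[bi],
                            angleCACN = mA$angleCACN[bi], omega = mA$omega[bi]),
                 deviations = devA[bi, ], normalized = normA[bi, ])
  }
  okA <- which(worstA <= 1)
  if (length(okA)) {
    candList[[length(candList) + 1L]] <-
      cbind(f = okA, b = P + 1L, k = seg$last)  # b sentinel: anchor closure
  }

  cand <- do.call(rbind, candList)
  if (!is.null(cand) && nrow(cand)) {
    ## pool order: forward index, then backward index, then junction
    cand <- cand[order(cand[, "f"], cand[, "b"], cand[, "k"]), , drop = FALSE]
    for (ci in seq_len(nrow(cand))) {
      fi <- unname(cand[ci, "f"]); k <- unname(cand[ci, "k"])
      fa <- atomTable(materialize(fwd, extF, "upstream", fi))
      if (cand[ci, "b"] > P) {
        chk <- checkJunction(.fragResidue(fa, seg$last), downAnchor, criteria)
        frag <- tryAccept(fa, seg$last, chk)
      } else {
        ba <- atomTable(materialize(bwd, extB, "downstream", cand[ci, "b"]))
        chk <- checkJunction(.fragResidue(fa, k), .fragResidue(ba, k + 1L),
                             criteria)
        chim <- rbind(fa[fa$resnum <= k, , drop = FALSE],
                      ba[ba$resnum > k, , drop = FALSE])
        frag <- tryAccept(chim, k, chk)
      }
      if (!is.null(frag)) {
        return(list(success = TRUE, fragment = frag, junction = k,
                    check = chk, attempts = attempts))
      }
    }
  }
  list(success = FALSE, best = best, attempts = attempts)
}

## Vectorised junction metrics: each argument is an m x 3 matrix of the
## corresponding atom across candidates; returns per-row dCN, dCCA,
## CA-C-N angle and omega.
.junctionMetricsVec <- function(CAi, Ci, Nip1, CAip1) {
  rn <- function(m) sqrt(rowSums(m * m))
  rcross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  dCN <- rn(Nip1 - Ci)
  dCCA <- rn(CAip1 - Ci)
  u <- CAi - Ci
  v <- Nip1 - Ci
  cosang <- rowSums(u * v) / (rn(u) * rn(v))
  ang <- .rad2deg(acos(pmax(-1, pmin(1, cosang))))
  b1 <- Ci - CAi
  b2 <- Nip1 - Ci
  b3 <- CAip1 - Nip1
  n1 <- rcross(b1, b2)
  n2 <- rcross(b2, b3)
  om <- .rad2deg(atan2(rowSums((b2 / rn(b2)) * rcross(n1, n2)),
                       rowSums(n1 * n2)))
  om[om <= -180] <- om[om <= -180] + 360
  list(dCN = dCN, dCCA = dCCA, angleCACN = ang, omega = om)
}
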