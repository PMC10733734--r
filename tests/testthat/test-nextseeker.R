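# Gap closure: criteria derivation, junction screening, exact reconstruction
# through fragment pairs, and junction remodelling.

idealCriteria <- function() {
  lib <- buildTorsionLibrary(list(s = makeReferenceChain(length = 12, seed = 3)))
  deriveClosureCriteria(lib)
}

test_that("criteria take library means with n-sigma tolerances and a floor", {
  crit <- idealCriteria()
  g <- defaultBuildGeometry()
  expect_equal(crit$dCN$mean, g$bCN, tolerance = 1e-9)
  expect_equal(crit$angleCACN$mean, g$aCACN, tolerance = 1e-9)
  expect_equal(abs(crit$omega$mean), 180, tolerance = 1e-9)
  # zero-variance fixtures floor every tolerance
  expect_equal(crit$dCN$tol, 1e-3)
  expect_equal(crit$omega$tol, 1e-3)

  # hand-built statistics: tol = n_sigma * sd
  lib <- makeMiniLibrary(seed = 1, nChains = 2)
  gs <- geometryStats(lib)
  gs$mean[gs$quantity == "dCN"] <- 1.33
  gs$sd[gs$quantity == "dCN"] <- 0.01
  lib@geometryStats <- gs
  crit2 <- deriveClosureCriteria(lib, nSigma = 3)
  expect_equal(crit2$dCN$mean, 1.33)
  expect_equal(crit2$dCN$tol, 0.03)
})

test_that("junction checks accept native pairs and reject displaced ones", {
  ref <- makeReferenceChain(length = 8, seed = 2)
  at <- atomTable(ref)
  crit <- idealCriteria()
  r4 <- residueAtoms(at, 4); r5 <- residueAtoms(at, 5)
  chk <- checkJunction(r4, r5, crit)
  expect_true(chk$pass)
  expect_lt(max(chk$deviations), 1e-6)
  # deviations equal the shared measurement primitive
  m <- measureGeometry(r4$CA, r4$C, r5$N, r5$CA)
  expect_equal(unname(chk$values["dCN"]), m$distance, tolerance = 1e-12)
  expect_equal(unname(chk$values["angleCACN"]), m$angle, tolerance = 1e-12)
  expect_equal(unname(chk$values["omega"]), m$dihedral, tolerance = 1e-12)

  # displace residue 5 rigidly along the C->N axis by 1 Angstrom: both
  # bond-length criteria fail
  dir <- (r5$N - r4$C) / sqrt(sum((r5$N - r4$C)^2))
  r5b <- r5; r5b$N <- r5$N + dir; r5b$CA <- r5$CA + dir
  chk2 <- checkJunction(r4, r5b, crit)
  expect_false(chk2$pass)
  expect_gt(chk2$deviations[["dCN"]], 0.9)
  expect_gt(chk2$deviations[["dCCA"]], 0.3)
})

test_that("omega deviations are measured on the circle", {
  crit <- idealCriteria()
  crit$omega$mean <- 180
  crit$omega$tol <- 5
  # a junction omega of -179 is 2 degrees from +180, not 359
  ref <- makeReferenceChain(length = 4, seed = 1)
  tor <- data.frame(phi = rep(-57, 4), psi = rep(-47, 4),
                    omega = c(-179, 180, 180, 180))
  at <- atomTable(buildBackbone("AAAA", tor))
  chk <- checkJunction(residueAtoms(at, 1), residueAtoms(at, 2), crit)
  expect_true(chk$pass)
  expect_equal(unname(chk$deviations[["omega"]]), 1, tolerance = 1e-6)
})

test_that("an internal deletion is reconstructed through fragment pairs", {
  n <- 14
  fx <- helixFixture(n, seed = 2)
  tmpl <- deleteSegment(fx$structure, 5, 8)
  segs <- detectMissingSegments(tmpl, fx$sequences)
  # the library holds the original chain, so exact torsions are in the pool
  lib <- buildTorsionLibrary(list(orig = fx$structure))
  crit <- deriveClosureCriteria(lib)
  set.seed(1)
  res <- closeGap(as.list(segs[1, ]), tmpl, lib, crit, poolSize = 1,
                  chunkMax = 20)
  expect_true(res$success)
  pa <- atomTable(res$fragment)
  orig <- atomTable(fx$structure)
  ref <- orig[orig$resnum %in% 5:8 & orig$name %in% c("N", "CA", "C"), ]
  got <- pa[pa$name %in% c("N", "CA", "C"), ]
  got <- got[order(got$resnum, match(got$name, c("N", "CA", "C"))), ]
  ref <- ref[order(ref$resnum, match(ref$name, c("N", "CA", "C"))), ]
  expect_lt(max(abs(as.matrix(ref[, c("x", "y", "z")]) -
                    as.matrix(got[, c("x", "y", "z")]))), 1e-3)
  # the chimera passes the junction screen at every inherited junction
  for (k in 5:7) {
    chk <- checkJunction(residueAtoms(pa, k), residueAtoms(pa, k + 1), crit)
    expect_true(chk$pass)
  }
  # and at both template junctions
  ta <- atomTable(tmpl)
  expect_true(checkJunction(residueAtoms(ta, 4), residueAtoms(pa, 5),
                            crit)$pass)
  expect_true(checkJunction(residueAtoms(pa, 8), residueAtoms(ta, 9),
                            crit)$pass)
})

test_that("a single-residue gap degenerates to anchor junction checking", {
  fx <- helixFixture(10, seed = 5)
  tmpl <- deleteSegment(fx$structure, 5, 5)
  segs <- detectMissingSegments(tmpl, fx$sequences)
  lib <- buildTorsionLibrary(list(orig = fx$structure))
  crit <- deriveClosureCriteria(lib)
  set.seed(2)
  res <- closeGap(as.list(segs[1, ]), tmpl, lib, crit, poolSize = 1,
                  chunkMax = 20)
  expect_true(res$success)
  expect_equal(res$junction, 5)
})

test_that("anchor_only mode closes with forward fragments alone", {
  fx <- helixFixture(12, seed = 6)
  tmpl <- deleteSegment(fx$structure, 5, 7)
  segs <- detectMissingSegments(tmpl, fx$sequences)
  lib <- buildTorsionLibrary(list(orig = fx$structure))
  crit <- deriveClosureCriteria(lib)
  set.seed(3)
  res <- closeGap(as.list(segs[1, ]), tmpl, lib, crit, poolSize = 1,
                  mode = "anchor_only", chunkMax = 20)
  expect_true(res$success)
  expect_equal(res$junction, 7)
})

test_that("geometrically impossible gaps fail with a best-candidate report", {
  a <- makeReferenceChain(length = 3, seed = 1)
  bAt <- atomTable(makeReferenceChain(length = 8, seed = 1))
  bAt <- bAt[bAt$resnum >= 6, ]
  bAt$x <- bAt$x + 50  # anchors 50 Angstrom apart for a 2-residue gap
  tmpl <- StructureModel(rbind(atomTable(a), bAt), method = "xray",
                         resolution = 1.5)
  seg <- list(chain = "A", kind = "L-IDR", first = 4L, last = 5L,
              sequence = "AA", upstreamAnchor = 3L, downstreamAnchor = 6L)
  lib <- makeMiniLibrary(seed = 4, nChains = 5, geometryNoise = 1)
  crit <- deriveClosureCriteria(lib)
  set.seed(4)
  res <- closeGap(seg, tmpl, lib, crit, poolSize = 30)
  expect_false(res$success)
  expect_gt(res$best$score, 1)
  expect_named(res$best$deviations, c("dCN", "dCCA", "angleCACN", "omega"),
               ignore.order = TRUE)
})

test_that("closure success is non-decreasing in pool size", {
  # library: the original helix plus decoy coils; a pool member closes only
  # when its single-chunk draw comes from the helix run
  n <- 14
  fx <- helixFixture(n, seed = 2)
  tmpl <- deleteSegment(fx$structure, 5, 8)
  segs <- detectMissingSegments(tmpl, fx$sequences)
  src <- list(orig = fx$structure)
  for (d in 1:9) {
    src[[sprintf("decoy%d", d)]] <-
      makeReferenceChain(pattern = strrep("C", 20), seed = 100 + d)
  }
  lib <- buildTorsionLibrary(src)
  crit <- deriveClosureCriteria(lib)
  rate <- function(P) {
    mean(vapply(1:8, function(s) {
      set.seed(s)
      closeGap(as.list(segs[1, ]), tmpl, lib, crit, poolSize = P,
               chunkMax = 20)$success
    }, TRUE))
  }
  r10 <- rate(10); r100 <- rate(100)
  expect_gte(r100, r10)
  expect_gt(r100, 0)
})

test_that("junction remodelling places O and H in the peptide plane", {
  ref <- makeReferenceChain(length = 6, seed = 3)
  at <- atomTable(ref)
  r3 <- residueAtoms(at, 3); r4 <- residueAtoms(at, 4)
  g <- defaultBuildGeometry()
  new <- remodelClosure(r3, r4, g)
  expect_equal(sqrt(sum((new$O - r3$C)^2)), g$bCO, tolerance = 1e-6)
  expect_equal(bondAngle(r3$CA, r3$C, new$O), g$aCACO, tolerance = 1e-6)
  m <- measureGeometry(r3$CA, r3$C, new$O, new$H)
  expect_true(is.finite(m$dihedral))
  # improper O-C-N-H is planar trans
  expect_equal(abs(dihedralAngle(new$O, r3$C, r4$N, new$H)), 180,
               tolerance = 1e-3)
  # proline at i+1: no amide hydrogen
  expect_null(remodelClosure(r3, r4, g, prolineIp1 = TRUE)$H)
})
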