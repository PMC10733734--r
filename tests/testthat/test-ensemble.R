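# Attachment and full ensemble generation on synthetic fixtures. The exact
# reconstruction checks rebuild deleted residues from their original
# torsions, so builder + Kabsch attachment must reproduce the deleted
# coordinates to numerical precision.

originalTorsions <- function(structure) measureTorsions(atomTable(structure))

test_that("terminal fragments rebuilt from original torsions land on the originals", {
  fx <- helixFixture(14, seed = 2)
  tor <- originalTorsions(fx$structure)
  orig <- atomTable(fx$structure)

  # N-IDR: delete 1-3, rebuild 1-3 + copy of anchor residue 4
  tmpl <- deleteSegment(fx$structure, 1, 3)
  seg <- as.list(detectMissingSegments(tmpl, fx$sequences)[1, ])
  frag <- buildBackbone("AAAA", tor[1:4, c("phi", "psi", "omega")])
  placed <- attachFragment(frag, seg, tmpl, anchorEnd = "downstream")
  pa <- atomTable(placed)
  ref <- orig[orig$resnum %in% 1:3 & orig$name %in% c("N", "CA", "C"), ]
  got <- pa[pa$name %in% c("N", "CA", "C"), ]
  got <- got[order(got$resnum, match(got$name, c("N", "CA", "C"))), ]
  ref <- ref[order(ref$resnum, match(ref$name, c("N", "CA", "C"))), ]
  expect_lt(max(abs(as.matrix(ref[, c("x", "y", "z")]) -
                    as.matrix(got[, c("x", "y", "z")]))), 1e-3)

  # C-IDR: delete 12-14, rebuild anchor copy 11 + 12-14
  tmpl2 <- deleteSegment(fx$structure, 12, 14)
  seg2 <- as.list(detectMissingSegments(tmpl2, fx$sequences)[1, ])
  frag2 <- buildBackbone("AAAA", tor[11:14, c("phi", "psi", "omega")])
  placed2 <- attachFragment(frag2, seg2, tmpl2, anchorEnd = "upstream")
  pa2 <- atomTable(placed2)
  ref2 <- orig[orig$resnum %in% 12:14 & orig$name %in% c("N", "CA", "C"), ]
  got2 <- pa2[pa2$name %in% c("N", "CA", "C"), ]
  got2 <- got2[order(got2$resnum, match(got2$name, c("N", "CA", "C"))), ]
  ref2 <- ref2[order(ref2$resnum, match(ref2$name, c("N", "CA", "C"))), ]
  expect_lt(max(abs(as.matrix(ref2[, c("x", "y", "z")]) -
                    as.matrix(got2[, c("x", "y", "z")]))), 1e-3)
})

test_that("the one-residue anchor superposition is an exact three-point fit", {
  fx <- helixFixture(10, seed = 4)
  tmpl <- deleteSegment(fx$structure, 8, 10)
  anchor <- residueAtoms(atomTable(tmpl), 7)
  copy <- buildBackbone("A", data.frame(phi = -57, psi = -47, omega = 180))
  ca <- atomTable(copy)
  mob <- rbind(residueAtoms(ca, 1)$N, residueAtoms(ca, 1)$CA,
               residueAtoms(ca, 1)$C)
  fit <- kabschSuperpose(mob, rbind(anchor$N, anchor$CA, anchor$C))
  expect_lt(fit$rmsd, 1e-9)
})

test_that("attachment enforces the anchor-copy construction", {
  fx <- helixFixture(10)
  tmpl <- deleteSegment(fx$structure, 8, 10)
  seg <- as.list(detectMissingSegments(tmpl, fx$sequences)[1, ])
  tooShort <- buildBackbone("AAA", data.frame(phi = rep(-57, 3),
                                              psi = rep(-47, 3),
                                              omega = rep(180, 3)))
  expect_error(attachFragment(tooShort, seg, tmpl), "anchor copy")
})

test_that("a complete template yields n untouched copies", {
  fx <- helixFixture(8)
  segs <- detectMissingSegments(fx$structure, fx$sequences)
  models <- generateEnsemble(fx$structure, fx$sequences, segs,
                             makeMiniLibrary(seed = 1, nChains = 2),
                             nConformers = 3)
  expect_length(models, 3)
  for (m in models) expect_equal(atomTable(m)[, c("x", "y", "z")],
                                 atomTable(fx$structure)[, c("x", "y", "z")])
})

test_that("C-IDR ensembles are complete, clash-free and seed-reproducible", {
  fx <- helixFixture(14, seed = 2)
  tmpl <- deleteSegment(fx$structure, 12, 14)
  segs <- detectMissingSegments(tmpl, fx$sequences)
  lib <- makeMiniLibrary(seed = 7, nChains = 10, geometryNoise = 1)
  cfg <- defaultRunConfig(seed = 5, chunkMax = 1L)
  run1 <- generateEnsemble(tmpl, fx$sequences, segs, lib, nConformers = 5,
                           config = cfg)
  run2 <- generateEnsemble(tmpl, fx$sequences, segs, lib, nConformers = 5,
                           config = cfg)
  expect_length(run1, 5)
  params <- defaultClashParams(tolerance = cfg$tolerance)
  for (k in seq_along(run1)) {
    at <- atomTable(run1[[k]])
    expect_setequal(unique(at$resnum), 1:14)  # every residue exactly once
    expect_equal(anyDuplicated(paste(at$resnum, at$name)), 0)
    expect_identical(at, atomTable(run2[[k]]))
    # recount clashes between the rebuilt tail and the far template
    built <- at[at$resnum >= 12, ]
    ctx <- at[at$resnum <= 10, ]  # anchor residue 11 excluded (bonded)
    expect_equal(bruteClashCount(built, ctx, params), 0)
    md <- attr(run1[[k]], "metadata")
    expect_equal(md$conformer, k)
    expect_true(all(md$acceptance$acceptanceRate > 0))
  }
  # distinct conformers are actually different
  expect_false(isTRUE(all.equal(atomTable(run1[[1]])$x,
                                atomTable(run1[[2]])$x)))
})

test_that("environment atoms confine the built tail", {
  fx <- helixFixture(14, seed = 2)
  tmpl <- deleteSegment(fx$structure, 12, 14)
  segs <- detectMissingSegments(tmpl, fx$sequences)
  lib <- makeMiniLibrary(seed = 7, nChains = 10, geometryNoise = 1)
  # slab of pseudo-atoms above the template, inside the reach of the
  # 3-residue tail growing from the anchor near z = 11; tails must avoid it
  slab <- makeEnvironmentSlab(16, 22, spacing = 2, xyExtent = 15)
  models <- generateEnsemble(tmpl, fx$sequences, segs, lib, nConformers = 3,
                             config = defaultRunConfig(seed = 11, chunkMax = 1L),
                             environmentAtoms = slab)
  params <- defaultClashParams()
  for (m in models) {
    built <- atomTable(m)[atomTable(m)$resnum >= 12, ]
    expect_equal(bruteClashCount(built, slab, params), 0)
  }
})

test_that("an unbuildable segment exhausts the retry budget with a report", {
  fx <- helixFixture(14, seed = 2)
  tmpl <- deleteSegment(fx$structure, 12, 14)
  segs <- detectMissingSegments(tmpl, fx$sequences)
  lib <- makeMiniLibrary(seed = 7, nChains = 10, geometryNoise = 1)
  anchor <- residueAtoms(atomTable(tmpl), 11)
  # bury the anchor region in pseudo-atoms so no candidate can fit
  cage <- makeEnvironmentSlab(anchor$CA[3] - 8, anchor$CA[3] + 8,
                              spacing = 1.5, xyExtent = 10)
  cage$x <- cage$x + anchor$CA[1]
  cage$y <- cage$y + anchor$CA[2]
  err <- tryCatch(
    generateEnsemble(tmpl, fx$sequences, segs, lib, nConformers = 1,
                     config = defaultRunConfig(seed = 3, retryBudget = 5),
                     environmentAtoms = cage),
    idrSamplingFailure = function(e) e)
  expect_s3_class(err, "idrSamplingFailure")
  expect_match(conditionMessage(err), "A:12-14")
  expect_equal(err$attempts, 5)
})

test_that("multi-chain templates are completed chain by chain", {
  a <- makeReferenceChain(length = 10, seed = 1, chain = "A")
  bAt <- atomTable(makeReferenceChain(length = 10, seed = 2, chain = "B"))
  bAt$x <- bAt$x + 25  # keep the chains apart
  tmpl <- StructureModel(rbind(atomTable(a), bAt), method = "xray",
                         resolution = 1.5)
  seqs <- SequenceSet(c(A = strrep("A", 10), B = strrep("A", 10)))
  tmpl <- deleteSegment(deleteSegment(tmpl, 8, 10, chain = "A"),
                        1, 2, chain = "B")
  segs <- detectMissingSegments(tmpl, seqs)
  expect_setequal(segs$kind, c("C-IDR", "N-IDR"))
  lib <- makeMiniLibrary(seed = 7, nChains = 10, geometryNoise = 1)
  models <- generateEnsemble(tmpl, seqs, segs, lib, nConformers = 2,
                             config = defaultRunConfig(seed = 8, chunkMax = 1L))
  for (m in models) {
    at <- atomTable(m)
    expect_setequal(unique(at$resnum[at$chain == "A"]), 1:10)
    expect_setequal(unique(at$resnum[at$chain == "B"]), 1:10)
  }
})

test_that("unknown configuration keys are rejected", {
  expect_error(validateRunConfig(list(seeed = 1)), "unknown")
  expect_error(validateRunConfig(list(closureMode = "magic")), "closureMode")
  expect_equal(validateRunConfig(list(seed = 9))$seed, 9)
})
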