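## Fragment attachment by anchor-residue superposition and full ensemble
## generation: per conformer, every detected segment is rebuilt by torsion
## sampling, oriented onto the template with the Kabsch fit of a one-residue
## anchor copy, screened for van der Waals clashes against template +
## environment + previously placed fragments, and internal gaps are closed
## by the two-sided fragment-pair search in closeGap().

## Backbone coordinates (N, CA, C) of one residue from an atom table.
.residueBackbone <- function(atoms, chain, resnum) {
  sub <- atoms[atoms$chain == chain & atoms$resnum == resnum &
               atoms$name %in% c("N", "CA", "C"), , drop = FALSE]
  if (!all(c("N", "CA", "C") %in% sub$name)) {
    stop(sprintf("residue %s:%d lacks backbone atoms needed for anchoring",
                 chain, resnum))
  }
  get <- function(nm) { r <- sub[sub$name == nm, ][1, ]; c(r$x, r$y, r$z) }
  list(N = get("N"), CA = get("CA"), C = get("C"))
}

.segmentAsList <- function(segment) {
  if (is.data.frame(segment)) as.list(segment[1, ]) else segment
}

#' Attach a built fragment to the template by anchor superposition
#'
#' The fragment must have been built with one extra "anchor copy" residue on
#' the anchored end: the copy of the downstream template anchor appended for
#' an N-IDR, or the copy of the upstream anchor prepended for a C-IDR or a
#' forward L-IDR build. The copy's N, CA, C are superposed onto the template
#' anchor's backbone (three points, exact fit for ideal geometry), the whole
#' fragment is transformed, the anchor copy discarded, and the remaining
#' residues renumbered to the segment range in the segment's chain.
#'
#' @param fragment \linkS4class{BackboneFragment} built for the segment
#'   sequence plus the anchor copy.
#' @param segment One segment (single data.frame row or list), see
#'   [validateSegments()].
#' @param template \linkS4class{StructureModel}.
#' @param anchorEnd "upstream" or "downstream"; defaults to the anchored end
#'   implied by the segment kind (N-IDR: downstream; otherwise upstream).
#' @return The placed \linkS4class{BackboneFragment} (anchor copy removed,
#'   residues numbered `first:last`).
#' @export
attachFragment <- function(fragment, segment, template, anchorEnd = NULL) {
  seg <- .segmentAsList(segment)
  if (is.null(anchorEnd)) {
    anchorEnd <- if (seg$kind == "N-IDR") "downstream" else "upstream"
  }
  anchorRes <- if (anchorEnd == "downstream") seg$downstreamAnchor else seg$upstreamAnchor
  if (is.na(anchorRes)) stop("segment has no ", anchorEnd, " anchor")
  target <- .residueBackbone(atomTable(template), seg$chain, anchorRes)

  at <- atomTable(fragment)
  resnums <- sort(unique(at$resnum))
  nseg <- seg$last - seg$first + 1L
  if (length(resnums) != nseg + 1L) {
    stop(sprintf("fragment has %d residues; expected segment length %d plus one anchor copy",
                 length(resnums), nseg))
  }
  copyRes <- if (anchorEnd == "downstream") resnums[length(resnums)] else resnums[1L]
  mob <- at[at$resnum == copyRes, , drop = FALSE]
  getm <- function(nm) { r <- mob[mob$name == nm, ][1, ]; c(r$x, r$y, r$z) }
  mobile <- rbind(getm("N"), getm("CA"), getm("C"))
  fit <- kabschSuperpose(mobile, rbind(target$N, target$CA, target$C))

  xyz <- applySuperposition(cbind(at$x, at$y, at$z), fit)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at <- at[at$resnum != copyRes, , drop = FALSE]
  kept <- sort(unique(at$resnum))
  at$resnum <- seg$first + match(at$resnum, kept) - 1L
  at$chain <- seg$chain
  rownames(at) <- NULL
  new("BackboneFragment", atoms = at,
      torsions = fragmentTorsions(fragment), segment = seg)
}

## One-letter code of a template residue (for anchor-copy sequences).
.templateLetter <- function(template, chain, resnum) {
  at <- atomTable(template)
  rn <- at$resname[at$chain == chain & at$resnum == resnum][1]
  code <- unname(.aa321[rn])
  if (is.na(code)) "X" else code
}

## Extended sequence (segment + anchor copy) and anchored end for a
## terminal segment.
.terminalExt <- function(seg, template) {
  if (seg$kind == "N-IDR") {
    list(ext = paste0(seg$sequence,
                      .templateLetter(template, seg$chain, seg$downstreamAnchor)),
         anchorEnd = "downstream")
  } else {
    list(ext = paste0(.templateLetter(template, seg$chain, seg$upstreamAnchor),
                      seg$sequence),
         anchorEnd = "upstream")
  }
}

## Build + attach one terminal segment candidate (N-IDR or C-IDR). When
## criteria are supplied the torsion draw is omega-screened so every
## junction of the placed fragment stays inside the criteria band.
.buildTerminalCandidate <- function(seg, template, library, chunkMax, geometry,
                                    ext = NULL, index = NULL, criteria = NULL) {
  if (is.null(ext)) ext <- .terminalExt(seg, template)
  tor <- if (is.null(criteria)) {
    sampleTorsionPath(ext$ext, library, chunkMax = chunkMax, index = index)
  } else {
    .sampleOmegaScreened(ext$ext, library, chunkMax, index, criteria)
  }
  frag <- buildBackbone(ext$ext, tor, geometry)
  attachFragment(frag, seg, template, anchorEnd = ext$anchorEnd)
}

## Clash context rows to drop for a segment: the atoms of its anchor
## residue(s), which are covalently bonded to the built chain.
.anchorContextFilter <- function(contextAtoms, seg) {
  drop <- rep(FALSE, nrow(contextAtoms))
  for (a in c(seg$upstreamAnchor, seg$downstreamAnchor)) {
    if (!is.na(a)) {
      drop <- drop | (contextAtoms$chain == seg$chain & contextAtoms$resnum == a)
    }
  }
  contextAtoms[!drop, , drop = FALSE]
}

#' Default run configuration
#'
#' @param seed Top-level random seed; per-conformer child seeds are
#'   `seed + conformer index`.
#' @param tolerance Clash tolerance in Angstrom (subtracted from vdW sums).
#' @param retryBudget Fragment draws per terminal segment per conformer.
#' @param chunkMax Longest library sub-run match in torsion sampling.
#' @param poolSize Forward/backward pool size for gap closure. Closure is a
#'   rare-event search over pool pairs, so thousands per side are needed for
#'   stochastic gaps; the default matches the scale at which a realistic
#'   library closes medium-length linkers reliably.
#' @param closureRetries Fresh-pool closeGap calls per gap per conformer
#'   before declaring failure.
#' @param closureMode "junction_scan" (default) or "anchor_only".
#' @param nSigma Width multiplier for closure criteria.
#' @param plddtThreshold Confidence threshold for trimming predictions.
#' @return Named list of settings.
#' @export
defaultRunConfig <- function(seed = 1L, tolerance = 0.4, retryBudget = 100L,
                             chunkMax = 5L, poolSize = 4000L,
                             closureRetries = 4L,
                             closureMode = "junction_scan", nSigma = 3,
                             plddtThreshold = 70) {
  list(seed = as.integer(seed), tolerance = tolerance,
       retryBudget = as.integer(retryBudget), chunkMax = as.integer(chunkMax),
       poolSize = as.integer(poolSize),
       closureRetries = as.integer(closureRetries),
       closureMode = closureMode,
       nSigma = nSigma, plddtThreshold = plddtThreshold)
}

#' Validate a run configuration list
#' @param config Named list of settings.
#' @return The merged configuration (defaults filled in).
#' @export
validateRunConfig <- function(config) {
  base <- defaultRunConfig()
  unknown <- setdiff(names(config), c(names(base), "environmentAtoms"))
  if (length(unknown)) {
    stop("unknown run-configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(config$closureMode) &&
      !config$closureMode %in% c("junction_scan", "anchor_only")) {
    stop("closureMode must be 'junction_scan' or 'anchor_only'")
  }
  utils::modifyList(base, config)
}

#' Generate a conformer ensemble for the missing segments of a template
#'
#' For each conformer every segment is rebuilt: terminal segments via
#' sample-build-attach with clash accept/reject under a retry budget,
#' internal gaps via the two-anchor fragment-pair closure of [closeGap()].
#' Segments are processed chain by chain in template order, longest first
#' within a chain; accepted fragments join the clash context for later
#' segments. Environment atoms (e.g. a lipid bilayer slab) participate in
#' clash checking only. Reproducible: conformer k uses seed `seed + k`.
#'
#' @param template \linkS4class{StructureModel} (segments already missing
#'   from it).
#' @param sequences \linkS4class{SequenceSet} of full-length chains.
#' @param segments Segment data.frame from [detectMissingSegments()] or
#'   [trimLowConfidence()].
#' @param library \linkS4class{TorsionLibrary}.
#' @param nConformers Number of conformers to generate.
#' @param config Run configuration, see [defaultRunConfig()].
#' @param environmentAtoms Optional atom table of environment atoms
#'   (clash context only; not written into the models).
#' @return List of \linkS4class{StructureModel} conformers; each carries a
#'   `metadata` attribute (seed, per-segment acceptance rates).
#' @export
generateEnsemble <- function(template, sequences, segments, library,
                             nConformers = 1L, config = defaultRunConfig(),
                             environmentAtoms = NULL) {
  config <- validateRunConfig(config)
  segments <- validateSegments(segments)
  geometry <- defaultBuildGeometry()
  clashParams <- defaultClashParams(tolerance = config$tolerance)
  criteria <- deriveClosureCriteria(library, nSigma = config$nSigma)

  ## chain-by-chain in template order; longest segment first within a chain
  if (nrow(segments)) {
    ord <- order(match(segments$chain, chainIds(template)),
                 -(segments$last - segments$first), segments$first)
    segments <- segments[ord, , drop = FALSE]
  }

  tmplAtoms <- atomTable(template)
  envAtoms <- if (is.null(environmentAtoms)) NULL else as.data.frame(environmentAtoms)

  ## chunk-match indices are deterministic; compute once per terminal segment
  termInfo <- vector("list", nrow(segments))
  for (si in seq_len(nrow(segments))) {
    seg <- as.list(segments[si, ])
    if (seg$kind != "L-IDR") {
      ext <- .terminalExt(seg, template)
      termInfo[[si]] <- list(ext = ext,
                             index = chunkMatchIndex(ext$ext, library,
                                                     config$chunkMax))
    }
  }

  models <- vector("list", nConformers)
  for (k in seq_len(nConformers)) {
    set.seed(config$seed + k)
    placed <- list()
    rates <- data.frame(chain = character(), first = integer(),
                        kind = character(), attempts = integer(),
                        acceptanceRate = numeric())
    for (si in seq_len(nrow(segments))) {
      seg <- as.list(segments[si, ])
      context <- tmplAtoms
      if (length(placed)) context <- rbind(context, do.call(rbind, placed))
      ctxSeg <- .anchorContextFilter(context, seg)
      if (!is.null(envAtoms)) {
        ctxSeg <- rbind(ctxSeg, envAtoms[, names(ctxSeg), drop = FALSE])
      }
      if (seg$kind == "L-IDR") {
        tries <- 0L
        repeat {
          tries <- tries + 1L
          res <- closeGap(seg, template, library, criteria,
                          poolSize = config$poolSize, mode = config$closureMode,
                          contextAtoms = ctxSeg, clashParams = clashParams,
                          chunkMax = config$chunkMax, geometry = geometry)
          if (res$success || tries >= config$closureRetries) break
        }
        if (!res$success) {
          .samplingFailure(seg, k, attempts = tries * config$poolSize,
                           extra = res)
        }
        placed[[length(placed) + 1L]] <- atomTable(res$fragment)
        rates <- rbind(rates, data.frame(
          chain = seg$chain, first = seg$first, kind = seg$kind,
          attempts = res$attempts, acceptanceRate = 1 / max(1, tries)))
      } else {
        accepted <- FALSE
        for (att in seq_len(config$retryBudget)) {
          cand <- .buildTerminalCandidate(seg, template, library,
                                          config$chunkMax, geometry,
                                          ext = termInfo[[si]]$ext,
                                          index = termInfo[[si]]$index,
                                          criteria = criteria)
          cc <- clashCheck(atomTable(cand), ctxSeg, clashParams)
          if (cc$count == 0L) {
            placed[[length(placed) + 1L]] <- atomTable(cand)
            rates <- rbind(rates, data.frame(
              chain = seg$chain, first = seg$first, kind = seg$kind,
              attempts = att, acceptanceRate = 1 / att))
            accepted <- TRUE
            break
          }
        }
        if (!accepted) .samplingFailure(seg, k, attempts = config$retryBudget)
      }
    }
    allAtoms <- tmplAtoms
    if (length(placed)) allAtoms <- rbind(allAtoms, do.call(rbind, placed))
    allAtoms <- allAtoms[order(match(allAtoms$chain, chainIds(template)),
                               allAtoms$resnum, allAtoms$icode), , drop = FALSE]
    allAtoms$serial <- seq_len(nrow(allAtoms))
    model <- StructureModel(allAtoms, method = template@method,
                            resolution = template@resolution)
    attr(model, "metadata") <- list(seed = config$seed + k, conformer = k,
                                    acceptance = rates)
    models[[k]] <- model
  }
  models
}

.samplingFailure <- function(seg, conformer, attempts, extra = NULL) {
  msg <- sprintf(
    "sampling failure: segment %s %s:%d-%d not placed in conformer %d after %d attempt(s)",
    seg$kind, seg$chain, seg$first, seg$last, conformer, attempts)
  cond <- structure(class = c("idrSamplingFailure", "error", "condition"),
                    list(message = msg, call = sys.call(-1),
                         segment = seg, attempts = attempts, report = extra))
  stop(cond)
}
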