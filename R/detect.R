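## Detection and classification of disordered segments to build: compare the
## full-length sequence against residues observed with complete backbones
## (or, for predicted structures, against residues surviving a pLDDT trim).

.segmentColumns <- c("chain", "kind", "first", "last", "sequence",
                     "upstreamAnchor", "downstreamAnchor")

#' Validate a table of IDR segments
#'
#' Segments are plain data.frames with columns `chain`, `kind` (one of
#' "N-IDR", "L-IDR", "C-IDR"), `first`, `last` (inclusive author numbering),
#' `sequence` (one-letter string of the missing stretch), `upstreamAnchor`
#' and `downstreamAnchor` (author resnum of the template residue flanking
#' the gap; NA on the free end of a terminal segment).
#'
#' @param segments data.frame as above.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
validateSegments <- function(segments) {
  miss <- setdiff(.segmentColumns, names(segments))
  if (length(miss)) stop("segment table lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(segments)) return(segments)
  if (!all(segments$kind %in% c("N-IDR", "L-IDR", "C-IDR"))) {
    stop("segment kind must be N-IDR, L-IDR or C-IDR")
  }
  len <- segments$last - segments$first + 1L
  if (any(len != nchar(segments$sequence))) {
    stop("segment range length does not match sequence length")
  }
  bad <- (segments$kind == "N-IDR" & (!is.na(segments$upstreamAnchor) | is.na(segments$downstreamAnchor))) |
         (segments$kind == "C-IDR" & (is.na(segments$upstreamAnchor) | !is.na(segments$downstreamAnchor))) |
         (segments$kind == "L-IDR" & (is.na(segments$upstreamAnchor) | is.na(segments$downstreamAnchor)))
  if (any(bad)) stop("segment anchors inconsistent with kind")
  for (ch in unique(segments$chain)) {
    s <- segments[segments$chain == ch, , drop = FALSE]
    s <- s[order(s$first), , drop = FALSE]
    if (nrow(s) > 1L && any(s$first[-1] <= s$last[-nrow(s)])) {
      stop("segments overlap within chain ", ch)
    }
  }
  segments
}

.emptySegments <- function() {
  data.frame(chain = character(), kind = character(), first = integer(),
             last = integer(), sequence = character(),
             upstreamAnchor = integer(), downstreamAnchor = integer(),
             stringsAsFactors = FALSE)
}

## Classify maximal runs of missing positions given the observed position set.
.classifyRuns <- function(chain, missingPos, observedPos, seqLetters, firstRes) {
  if (!length(missingPos)) return(.emptySegments())
  missingPos <- sort(missingPos)
  runBreaks <- c(0L, which(diff(missingPos) > 1L), length(missingPos))
  out <- vector("list", length(runBreaks) - 1L)
  for (k in seq_len(length(runBreaks) - 1L)) {
    run <- missingPos[(runBreaks[k] + 1L):runBreaks[k + 1L]]
    a <- run[1L]; b <- run[length(run)]
    before <- any(observedPos < a)
    after <- any(observedPos > b)
    kind <- if (!before && after) "N-IDR" else if (before && !after) "C-IDR"
            else if (before && after) "L-IDR"
            else stop("chain ", chain, " has no observed residues to anchor segments")
    out[[k]] <- data.frame(
      chain = chain, kind = kind, first = a, last = b,
      sequence = paste(seqLetters[(a:b) - firstRes + 1L], collapse = ""),
      upstreamAnchor = if (before) max(observedPos[observedPos < a]) else NA_integer_,
      downstreamAnchor = if (after) min(observedPos[observedPos > b]) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Detect missing segments by sequence comparison
#'
#' Compares the full-length sequence of every chain in `sequences` against
#' the residues observed in the template. A residue observed without a
#' complete backbone (missing any of N, CA, C) counts as missing and is
#' rebuilt. Observed letters must agree with the full-length sequence at
#' every observed position (after parent mapping of modified residues);
#' a mismatch is a hard error naming the chain and residue. Matching is
#' positional via author numbering, not alignment-based.
#'
#' @param structure A \linkS4class{StructureModel} template.
#' @param sequences A \linkS4class{SequenceSet}.
#' @return data.frame of segments (see [validateSegments()]).
#' @export
detectMissingSegments <- function(structure, sequences) {
  at <- atomTable(structure)
  segs <- list()
  for (ch in names(sequences@sequences)) {
    if (!ch %in% at$chain) {
      stop("chain ", ch, " in sequence set is absent from the structure")
    }
    seqStr <- chainSequence(sequences, ch)
    f0 <- firstResnum(sequences, ch)
    letters1 <- strsplit(seqStr, "")[[1]]
    positions <- f0:(f0 + length(letters1) - 1L)

    sub <- at[at$chain == ch & at$name %in% c("N", "CA", "C"), , drop = FALSE]
    resnums <- unique(sub$resnum)
    complete <- resnums[vapply(resnums, function(r) {
      all(c("N", "CA", "C") %in% sub$name[sub$resnum == r])
    }, TRUE)]

    obs <- extractObservedSequence(structure, ch)
    obs <- obs[obs$resnum %in% complete, , drop = FALSE]
    outside <- setdiff(obs$resnum, positions)
    if (length(outside)) {
      stop(sprintf("chain %s: observed residue %d outside the full-sequence range",
                   ch, outside[1]))
    }
    idx <- obs$resnum - f0 + 1L
    mism <- which(obs$code != letters1[idx] & obs$code != "X")
    if (length(mism)) {
      stop(sprintf("chain %s: residue %d is %s in the structure but %s in the sequence",
                   ch, obs$resnum[mism[1]], obs$code[mism[1]], letters1[idx[mism[1]]]))
    }
    missingPos <- setdiff(positions, obs$resnum)
    segs[[ch]] <- .classifyRuns(ch, missingPos, obs$resnum, letters1, f0)
  }
  out <- do.call(rbind, segs)
  if (is.null(out)) out <- .emptySegments()
  rownames(out) <- NULL
  validateSegments(out)
}

#' Trim low-confidence residues from a predicted structure
#'
#' Residues with pLDDT strictly below `threshold` are deleted (pLDDT is
#' read from the CA B-factor, as in AlphaFold model files) and the deleted
#' runs are returned as classified IDR segments, exactly as
#' [detectMissingSegments()] would then report them.
#'
#' @param structure A \linkS4class{StructureModel} with per-residue pLDDT in
#'   the B-factor column.
#' @param threshold pLDDT threshold; strict inequality (default 70).
#' @return List with `structure` (trimmed) and `segments` (data.frame).
#' @export
trimLowConfidence <- function(structure, threshold = 70) {
  at <- atomTable(structure)
  segs <- list()
  keep <- rep(TRUE, nrow(at))
  for (ch in chainIds(structure)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    key <- paste(sub$resnum, sub$icode, sep = "\r")
    resk <- unique(key)
    plddt <- vapply(resk, function(k) {
      rows <- sub[key == k, , drop = FALSE]
      ca <- rows[rows$name == "CA", , drop = FALSE]
      if (!nrow(ca) || is.na(ca$b[1])) NA_real_ else ca$b[1]
    }, 1, USE.NAMES = FALSE)
    if (anyNA(plddt)) {
      stop("chain ", ch, ": residue without a pLDDT value (CA B-factor)")
    }
    resnums <- vapply(resk, function(k) sub$resnum[key == k][1], 1L, USE.NAMES = FALSE)
    low <- plddt < threshold
    if (any(low)) {
      letters1 <- unname(.aa321[vapply(resk, function(k) sub$resname[key == k][1],
                                       "", USE.NAMES = FALSE)])
      letters1[is.na(letters1)] <- "X"
      f0 <- min(resnums)
      seqLetters <- character(max(resnums) - f0 + 1L)
      seqLetters[resnums - f0 + 1L] <- letters1
      segs[[ch]] <- .classifyRuns(ch, resnums[low], resnums[!low], seqLetters, f0)
      keep[at$chain == ch & paste(at$resnum, at$icode, sep = "\r") %in% resk[low]] <- FALSE
    }
  }
  out <- do.call(rbind, segs)
  if (is.null(out)) out <- .emptySegments()
  rownames(out) <- NULL
  trimmed <- StructureModel(at[keep, , drop = FALSE], method = structure@method,
                            resolution = structure@resolution,
                            modelNumber = structure@modelNumber)
  list(structure = trimmed, segments = validateSegments(out))
}

#' Write a JSON report of detected segments
#' @param segments Segment data.frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeSegmentReport <- function(segments, path) {
  jsonlite::write_json(segments, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
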