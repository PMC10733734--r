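## Knowledge-based torsion library: harvesting (phi, psi, omega) runs from
## high-resolution X-ray chains, junction-geometry statistics, sequence-
## matched path sampling with chunk backoff, and JSON (de)serialisation.

#' Build a torsion library from source structures
#'
#' Only chains from X-ray structures at or better than `maxResolution`
#' contribute (default 1.8 Angstrom). Contiguous runs are broken at chain
#' breaks (peptide-bond C-N distance above `breakDistance`) and at residues
#' with incomplete backbones. Every junction inside a run contributes to
#' the geometry statistics (d C-N, d C-CA(i+1), angle CA-C-N, omega); the
#' sampleable fragment records are the run residues with a complete
#' (phi, psi, omega) triple, so a run of length L yields L - 2 records.
#' Phosphorylated Ser/Thr (SEP/TPO) are harvested under their parent
#' letters so that sampling for S/T reaches both record families.
#'
#' @param structures List of \linkS4class{StructureModel} objects; names are
#'   used as provenance identifiers.
#' @param maxResolution Resolution cutoff in Angstrom (default 1.8).
#' @param breakDistance C(i)-N(i+1) distance (Angstrom) above which a chain
#'   break is declared (default 1.6).
#' @return A \linkS4class{TorsionLibrary}.
#' @export
buildTorsionLibrary <- function(structures, maxResolution = 1.8,
                                breakDistance = 1.6) {
  if (is.null(names(structures))) {
    names(structures) <- sprintf("structure_%d", seq_along(structures))
  }
  qualifies <- vapply(structures, function(s) {
    s@method == "xray" && !is.na(s@resolution) && s@resolution <= maxResolution
  }, TRUE)
  if (!any(qualifies)) {
    stop(sprintf(
      "empty torsion library: no X-ray chains at resolution <= %.2f Angstrom",
      maxResolution))
  }

  fragments <- list()
  dCN <- dCCA <- angCACN <- omega <- numeric(0)
  for (sid in names(structures)[qualifies]) {
    s <- structures[[sid]]
    at <- atomTable(s)
    for (ch in chainIds(s)) {
      sub <- at[at$chain == ch & at$name %in% c("N", "CA", "C"), , drop = FALSE]
      if (!nrow(sub)) next
      key <- paste(sub$resnum, sub$icode, sep = "\r")
      resk <- unique(key)
      complete <- vapply(resk, function(k) {
        all(c("N", "CA", "C") %in% sub$name[key == k])
      }, TRUE)
      coordsOf <- function(k, nm) {
        r <- sub[key == k & sub$name == nm, , drop = FALSE]
        c(r$x[1], r$y[1], r$z[1])
      }
      ## maximal runs of backbone-complete residues, split at long C-N bonds
      runs <- list(); cur <- integer(0)
      for (i in seq_along(resk)) {
        if (!complete[i]) {
          if (length(cur)) { runs <- c(runs, list(cur)); cur <- integer(0) }
          next
        }
        if (length(cur)) {
          d <- .vnorm(coordsOf(resk[i], "N") - coordsOf(resk[cur[length(cur)]], "C"))
          if (d > breakDistance) { runs <- c(runs, list(cur)); cur <- integer(0) }
        }
        cur <- c(cur, i)
      }
      if (length(cur)) runs <- c(runs, list(cur))

      for (run in runs) {
        L <- length(run)
        rn <- vapply(resk[run], function(k) sub$resname[key == k][1], "",
                     USE.NAMES = FALSE)
        lets <- unname(.aa321[rn]); lets[is.na(lets)] <- "X"
        N <- t(vapply(resk[run], coordsOf, numeric(3), nm = "N"))
        CA <- t(vapply(resk[run], coordsOf, numeric(3), nm = "CA"))
        C <- t(vapply(resk[run], coordsOf, numeric(3), nm = "C"))
        if (L >= 2L) {
          for (i in seq_len(L - 1L)) {
            dCN <- c(dCN, .vnorm(N[i + 1, ] - C[i, ]))
            dCCA <- c(dCCA, .vnorm(CA[i + 1, ] - C[i, ]))
            angCACN <- c(angCACN, bondAngle(CA[i, ], C[i, ], N[i + 1, ]))
            omega <- c(omega, dihedralAngle(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ]))
          }
        }
        if (L >= 3L) {
          ii <- 2:(L - 1L)
          tors <- data.frame(
            resname = rn[ii],
            phi = vapply(ii, function(i) dihedralAngle(C[i - 1, ], N[i, ], CA[i, ], C[i, ]), 1),
            psi = vapply(ii, function(i) dihedralAngle(N[i, ], CA[i, ], C[i, ], N[i + 1, ]), 1),
            omega = vapply(ii, function(i) dihedralAngle(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ]), 1),
            ss = "C", stringsAsFactors = FALSE)
          fragments[[length(fragments) + 1L]] <-
            list(sequence = paste(lets[ii], collapse = ""), torsions = tors,
                 source = sprintf("%s:%s", sid, ch))
        }
      }
    }
  }

  stat <- function(q, x) data.frame(quantity = q, mean = mean(x),
                                    sd = if (length(x) > 1) stats::sd(x) else 0,
                                    n = length(x), stringsAsFactors = FALSE)
  ## omega clusters at +/-180 for trans peptides, so its summary is circular
  omMean <- .circularMeanDeg(omega)
  omStat <- data.frame(quantity = "omega", mean = omMean,
                       sd = .circularSdDeg(omega, omMean), n = length(omega),
                       stringsAsFactors = FALSE)
  gs <- rbind(stat("dCN", dCN), stat("dCCA", dCCA),
              stat("angleCACN", angCACN), omStat)
  new("TorsionLibrary", fragments = fragments, geometryStats = gs,
      provenance = list(sources = names(structures)[qualifies],
                        maxResolution = maxResolution,
                        breakDistance = breakDistance,
                        omegaTrans = omega[abs(omega) > 90],
                        schema = "torsion-library-1"))
}

#' Sample a torsion path for a sequence
#'
#' Assembles a (phi, psi, omega) path from library sub-runs: at each
#' position the sampler looks for library runs whose sequence matches the
#' next k residues, with k backing off from `chunkMax` down to 1; the first
#' k with at least one match wins and one matching (run, offset) is chosen
#' uniformly. Uses the R random number stream, so results are reproducible
#' under `set.seed()`.
#'
#' @param sequence One-letter query sequence.
#' @param library A \linkS4class{TorsionLibrary}.
#' @param chunkMax Longest sub-run match attempted (default 5).
#' @param index Optional precomputed match index from [chunkMatchIndex()]
#'   for repeated sampling of the same sequence (e.g. fragment pools).
#' @return data.frame with columns phi, psi, omega, one row per residue.
#' @export
sampleTorsionPath <- function(sequence, library, chunkMax = 5L, index = NULL) {
  n <- nchar(sequence)
  if (n < 1L) stop("sequence must be non-empty")
  frags <- libraryFragments(library)
  if (!length(frags)) stop("torsion library has no fragment records")
  if (is.null(index)) index <- chunkMatchIndex(sequence, library, chunkMax)

  rows <- vector("list", n)
  pos <- 1L
  while (pos <= n) {
    placed <- FALSE
    for (k in seq(min(chunkMax, n - pos + 1L), 1L)) {
      cand <- index[[pos]][[k]]
      if (!is.null(cand) && nrow(cand)) {
        pick <- cand[sample.int(nrow(cand), 1L), ]
        rows[[pos]] <- frags[[pick[1]]]$torsions[pick[2]:(pick[2] + k - 1L),
                                                 c("phi", "psi", "omega")]
        pos <- pos + k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("no torsion records for residue letter '%s'",
                   substr(sequence, pos, pos)))
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Precompute library sub-run matches for one query sequence
#'
#' For every query position and chunk length k up to `chunkMax`, the
#' (fragment, offset) pairs whose stored sequence matches the next k query
#' letters. Passing the result to [sampleTorsionPath()] removes the string
#' scan from each draw, which matters when building fragment pools.
#'
#' @inheritParams sampleTorsionPath
#' @return Nested list: `index[[pos]][[k]]` is a 2-column matrix
#'   (fragment index, offset) or NULL.
#' @export
chunkMatchIndex <- function(sequence, library, chunkMax = 5L) {
  n <- nchar(sequence)
  fragSeqs <- vapply(libraryFragments(library), function(f) f$sequence, "")
  lapply(seq_len(n), function(pos) {
    lapply(seq_len(min(chunkMax, n - pos + 1L)), function(k) {
      query <- substr(sequence, pos, pos + k - 1L)
      out <- list()
      for (fi in seq_along(fragSeqs)) {
        if (nchar(fragSeqs[fi]) < k) next
        m <- gregexpr(query, fragSeqs[fi], fixed = TRUE)[[1]]
        if (m[1] != -1L) out[[length(out) + 1L]] <- cbind(fi, as.integer(m))
      }
      if (length(out)) do.call(rbind, out) else NULL
    })
  })
}

#' Serialise a torsion library to JSON
#' @param library A \linkS4class{TorsionLibrary}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTorsionLibrary <- function(library, path) {
  obj <- list(schema = library@provenance$schema,
              provenance = library@provenance[setdiff(names(library@provenance), "schema")],
              geometryStats = geometryStats(library),
              fragments = lapply(libraryFragments(library), function(f) {
                list(sequence = f$sequence, source = f$source,
                     torsions = f$torsions)
              }))
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a torsion library from JSON
#' @param path Path written by [writeTorsionLibrary()].
#' @return A \linkS4class{TorsionLibrary}.
#' @export
readTorsionLibrary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, "torsion-library-1")) {
    stop("not a torsion library JSON (missing/unknown schema tag): ", path)
  }
  wrap <- function(x) { x <- as.numeric(x); x[!is.na(x) & x <= -180] <- 180; x }
  frags <- lapply(seq_len(NROW(obj$fragments)), function(i) {
    tors <- data.frame(resname = obj$fragments$torsions$resname[[i]],
                       phi = wrap(obj$fragments$torsions$phi[[i]]),
                       psi = wrap(obj$fragments$torsions$psi[[i]]),
                       omega = wrap(obj$fragments$torsions$omega[[i]]),
                       ss = obj$fragments$torsions$ss[[i]],
                       stringsAsFactors = FALSE)
    list(sequence = obj$fragments$sequence[i],
         source = obj$fragments$source[i], torsions = tors)
  })
  prov <- obj$provenance
  prov$schema <- obj$schema
  new("TorsionLibrary", fragments = frags,
      geometryStats = as.data.frame(obj$geometryStats), provenance = prov)
}
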