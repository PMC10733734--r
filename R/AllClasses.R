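#' @import methods
NULL

## Column layout shared by every atom table in the package. One row per atom;
## residues are identified by (chain, resnum, icode).
.atomColumns <- c("serial", "name", "altloc", "resname", "chain",
                  "resnum", "icode", "x", "y", "z", "occ", "b", "element")

emptyAtomTable <- function() {
  data.frame(serial = integer(), name = character(), altloc = character(),
             resname = character(), chain = character(), resnum = integer(),
             icode = character(), x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), b = numeric(), element = character(),
             stringsAsFactors = FALSE)
}

.checkAtomTable <- function(atoms) {
  miss <- setdiff(.atomColumns, names(atoms))
  if (length(miss)) {
    return(sprintf("atom table lacks columns: %s", paste(miss, collapse = ", ")))
  }
  if (nrow(atoms)) {
    if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
        !all(is.finite(atoms$z))) {
      return("atom coordinates must be finite")
    }
    if (any(!nzchar(trimws(atoms$name)))) {
      return("atom names must be non-empty")
    }
  }
  TRUE
}

#' StructureModel: a macromolecular structure as a flat atom table
#'
#' Holds one model of a structure as a data.frame with one row per atom
#' (columns `serial`, `name`, `altloc`, `resname`, `chain`, `resnum`,
#' `icode`, `x`, `y`, `z`, `occ`, `b`, `element`), plus experiment metadata.
#' For predicted structures the per-residue confidence (pLDDT) is carried in
#' the B-factor column. Residues are identified by (chain, resnum, icode);
#' author numbering is authoritative throughout.
#'
#' @slot atoms data.frame of atom records (see above).
#' @slot method character; one of "xray", "nmr", "em", "predicted", "unknown".
#' @slot resolution numeric; resolution in Angstrom, or NA when absent.
#' @slot modelNumber integer; model number for multi-model files.
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", method = "character",
                 resolution = "numeric", modelNumber = "integer"),
  prototype(atoms = emptyAtomTable(), method = "unknown",
            resolution = NA_real_, modelNumber = 1L),
  validity = function(object) {
    msgs <- character()
    chk <- .checkAtomTable(object@atoms)
    if (!isTRUE(chk)) msgs <- c(msgs, chk)
    if (length(object@method) != 1L ||
        !object@method %in% c("xray", "nmr", "em", "predicted", "unknown")) {
      msgs <- c(msgs, "method must be one of xray/nmr/em/predicted/unknown")
    }
    if (length(msgs)) msgs else TRUE
  })

#' Construct a StructureModel
#' @param atoms Atom table (see \linkS4class{StructureModel}).
#' @param method Experimental method string.
#' @param resolution Resolution in Angstrom or NA.
#' @param modelNumber Model number.
#' @return A \linkS4class{StructureModel}.
#' @export
StructureModel <- function(atoms, method = "unknown", resolution = NA_real_,
                           modelNumber = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$resnum <- as.integer(atoms$resnum)
  atoms$serial <- as.integer(atoms$serial)
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms[, .atomColumns], method = method,
      resolution = as.numeric(resolution), modelNumber = as.integer(modelNumber))
}

#' @describeIn StructureModel-class Atom table accessor.
#' @param x A StructureModel.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname StructureModel-class
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' @describeIn StructureModel-class Chain identifiers in file order.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname StructureModel-class
#' @export
setMethod("chainIds", "StructureModel", function(x) unique(x@atoms$chain))

setMethod("show", "StructureModel", function(object) {
  at <- object@atoms
  nres <- if (nrow(at)) nrow(unique(at[, c("chain", "resnum", "icode")])) else 0L
  cat(sprintf("StructureModel: %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(at), nres, length(chainIds(object)),
              paste(chainIds(object), collapse = ",")))
  cat(sprintf("  method: %s; resolution: %s; model %d\n", object@method,
              ifelse(is.na(object@resolution), "NA",
                     format(object@resolution)), object@modelNumber))
})

#' SequenceSet: full-length chain sequences
#'
#' Maps chain identifiers to full-length one-letter sequences together with
#' the author residue number of the first position.
#'
#' @slot sequences Named character vector of one-letter sequences.
#' @slot firstResnum Named integer vector, parallel to `sequences`.
#' @export
setClass("SequenceSet",
  representation(sequences = "character", firstResnum = "integer"),
  validity = function(object) {
    msgs <- character()
    if (!identical(names(object@sequences), names(object@firstResnum))) {
      msgs <- c(msgs, "sequences and firstResnum must share chain names")
    }
    if (any(!nzchar(names(object@sequences)))) {
      msgs <- c(msgs, "chain names must be non-empty")
    }
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", object@sequences)
    if (any(bad)) {
      msgs <- c(msgs, sprintf("sequence for chain %s has letters outside the 20 standard codes + X",
                              paste(names(object@sequences)[bad], collapse = ",")))
    }
    if (length(msgs)) msgs else TRUE
  })

#' Construct a SequenceSet
#' @param sequences Named character vector of one-letter sequences.
#' @param firstResnum Named integer vector (default 1 for every chain).
#' @return A \linkS4class{SequenceSet}.
#' @export
SequenceSet <- function(sequences, firstResnum = NULL) {
  sequences <- toupper(sequences)
  if (is.null(firstResnum)) {
    firstResnum <- stats::setNames(rep(1L, length(sequences)), names(sequences))
  }
  new("SequenceSet", sequences = sequences,
      firstResnum = stats::setNames(as.integer(firstResnum[names(sequences)]),
                                    names(sequences)))
}

#' @describeIn SequenceSet-class Sequence accessor.
#' @param x A SequenceSet.
#' @param chain Optional single chain id.
#' @export
setGeneric("chainSequence", function(x, chain) standardGeneric("chainSequence"))

#' @rdname SequenceSet-class
#' @export
setMethod("chainSequence", "SequenceSet", function(x, chain) {
  if (!chain %in% names(x@sequences)) stop("unknown chain: ", chain)
  x@sequences[[chain]]
})

#' @describeIn SequenceSet-class First author residue number of a chain.
#' @export
setGeneric("firstResnum", function(x, chain) standardGeneric("firstResnum"))

#' @rdname SequenceSet-class
#' @export
setMethod("firstResnum", "SequenceSet", function(x, chain) {
  if (!chain %in% names(x@firstResnum)) stop("unknown chain: ", chain)
  x@firstResnum[[chain]]
})

setMethod("show", "SequenceSet", function(object) {
  cat(sprintf("SequenceSet: %d chain(s)\n", length(object@sequences)))
  for (ch in names(object@sequences)) {
    s <- object@sequences[[ch]]
    cat(sprintf("  %s: %d aa from resnum %d: %s%s\n", ch, nchar(s),
                object@firstResnum[[ch]], substr(s, 1, 40),
                if (nchar(s) > 40) "..." else ""))
  }
})

#' TorsionLibrary: knowledge-based torsion fragments and junction geometry
#'
#' A library of contiguous torsion-angle runs harvested from high-resolution
#' X-ray chains, plus summary statistics of the peptide-junction geometry
#' (d C-N, d C-CA(i+1), angle CA-C-N, omega) used to derive gap-closure
#' criteria.
#'
#' @slot fragments list; each element a list with `sequence` (one-letter
#'   string) and `torsions` (data.frame with resname, phi, psi, omega, ss).
#' @slot geometryStats data.frame with columns quantity, mean, sd, n
#'   (quantities: dCN, dCCA, angleCACN, omega).
#' @slot provenance list: source identifiers, resolution cutoff, schema tag.
#' @export
setClass("TorsionLibrary",
  representation(fragments = "list", geometryStats = "data.frame",
                 provenance = "list"),
  validity = function(object) {
    msgs <- character()
    for (fr in object@fragments) {
      if (!is.character(fr$sequence) || nchar(fr$sequence) < 1L) {
        msgs <- c(msgs, "fragment with empty sequence"); break
      }
      if (nchar(fr$sequence) != nrow(fr$torsions)) {
        msgs <- c(msgs, "fragment sequence/torsion length mismatch"); break
      }
      ang <- unlist(fr$torsions[, c("phi", "psi", "omega")])
      if (any(ang < -180 - 1e-9 | ang > 180 + 1e-9, na.rm = TRUE)) {
        msgs <- c(msgs, "torsion angles outside (-180, 180]"); break
      }
    }
    if (nrow(object@geometryStats) && any(object@geometryStats$sd < 0)) {
      msgs <- c(msgs, "geometry stats standard deviations must be >= 0")
    }
    if (length(msgs)) msgs else TRUE
  })

setMethod("show", "TorsionLibrary", function(object) {
  nrec <- sum(vapply(object@fragments, function(f) nrow(f$torsions), 1L))
  cat(sprintf("TorsionLibrary: %d fragment run(s), %d torsion record(s)\n",
              length(object@fragments), nrec))
  if (nrow(object@geometryStats)) {
    gs <- object@geometryStats
    for (i in seq_len(nrow(gs))) {
      cat(sprintf("  %-9s mean %8.3f  sd %8.4f  (n=%d)\n", gs$quantity[i],
                  gs$mean[i], gs$sd[i], gs$n[i]))
    }
  }
})

#' @describeIn TorsionLibrary-class Fragment run accessor.
#' @param x A TorsionLibrary.
#' @export
setGeneric("libraryFragments", function(x) standardGeneric("libraryFragments"))

#' @rdname TorsionLibrary-class
#' @export
setMethod("libraryFragments", "TorsionLibrary", function(x) x@fragments)

#' @describeIn TorsionLibrary-class Junction geometry statistics accessor.
#' @export
setGeneric("geometryStats", function(x) standardGeneric("geometryStats"))

#' @rdname TorsionLibrary-class
#' @export
setMethod("geometryStats", "TorsionLibrary", function(x) x@geometryStats)

#' BackboneFragment: a built backbone chain for one disordered segment
#'
#' Coordinates of the backbone atoms (N, CA, C, O and amide H except for
#' proline) built for one segment, plus the torsion path used.
#'
#' @slot atoms Atom table (same layout as \linkS4class{StructureModel}).
#' @slot torsions data.frame with columns phi, psi, omega (degrees).
#' @slot segment list describing the segment (chain, kind, first, last,
#'   sequence, anchors).
#' @export
setClass("BackboneFragment",
  representation(atoms = "data.frame", torsions = "data.frame",
                 segment = "list"),
  validity = function(object) {
    chk <- .checkAtomTable(object@atoms)
    if (!isTRUE(chk)) chk else TRUE
  })

setMethod("show", "BackboneFragment", function(object) {
  cat(sprintf("BackboneFragment: %d residues (%s), %d atoms\n",
              nrow(object@torsions),
              if (length(object@segment)) object@segment$kind else "?",
              nrow(object@atoms)))
})

#' @rdname BackboneFragment-class
#' @param x A BackboneFragment.
#' @export
setMethod("atomTable", "BackboneFragment", function(x) x@atoms)

#' @describeIn BackboneFragment-class Torsion path used to build the fragment.
#' @export
setGeneric("fragmentTorsions", function(x) standardGeneric("fragmentTorsions"))

#' @rdname BackboneFragment-class
#' @export
setMethod("fragmentTorsions", "BackboneFragment", function(x) x@torsions)
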