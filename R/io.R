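## Structure and sequence I/O. Parsing of PDB/PDBx-mmCIF atom records is
## delegated to bio3d; this layer resolves altlocs, filters waters, reads
## header metadata and converts to the flat StructureModel atom table.
## The ensemble writer emits fixed-width PDB with TER records per chain.

.waterNames <- c("HOH", "WAT", "DOD", "SOL")

#' Read a structure file into a StructureModel
#'
#' Accepts PDB and PDBx/mmCIF (dialect chosen by extension, overridable).
#' Alternate locations are resolved to the highest-occupancy copy (ties:
#' first encountered); waters are excluded; non-polymer HETATM records are
#' excluded unless their residue name maps to a standard or modified amino
#' acid (e.g. SEP, TPO, MSE). Experimental method and resolution are taken
#' from the header when present.
#'
#' @param path File path.
#' @param modelIndex 1-based model to select from multi-model files.
#' @param format "auto" (default; by extension), "pdb" or "cif".
#' @param keepWaters Keep water residues (default FALSE).
#' @return A \linkS4class{StructureModel}.
#' @export
readStructure <- function(path, modelIndex = 1L, format = c("auto", "pdb", "cif"),
                          keepWaters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch({
    ## read.cif warns that it is a beta parser; that is not actionable here
    suppressWarnings(
      if (format == "cif") {
        bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
      } else {
        bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
      })
  }, error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))

  at <- pdb$atom
  nModels <- max(1L, nrow(pdb$xyz))
  if (modelIndex < 1L || modelIndex > nModels) {
    stop(sprintf("modelIndex %d out of range (file has %d model(s))",
                 modelIndex, nModels))
  }
  xyz <- matrix(pdb$xyz[modelIndex, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- "A"
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  elem <- at$elesy
  if (is.null(elem)) elem <- NA_character_
  elem[is.na(elem) | !nzchar(trimws(elem))] <-
    substr(trimws(at$elety[is.na(elem) | !nzchar(trimws(elem))]), 1, 1)

  keep <- rep(TRUE, nrow(at))
  if (!keepWaters) keep <- keep & !(at$resid %in% .waterNames)
  isHet <- at$type == "HETATM"
  keep <- keep & (!isHet | at$resid %in% names(.aa321))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]

  atoms <- data.frame(serial = as.integer(at$eleno), name = trimws(at$elety),
                      altloc = trimws(at$alt), resname = trimws(at$resid),
                      chain = at$chain, resnum = as.integer(at$resno),
                      icode = trimws(at$insert), x = at$x, y = at$y, z = at$z,
                      occ = at$o, b = at$b, element = toupper(trimws(elem)),
                      stringsAsFactors = FALSE)
  atoms <- .resolveAltlocs(atoms)
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resnum, atoms$icode, atoms$serial), ]
  rownames(atoms) <- NULL

  hdr <- .readHeaderMeta(path, format)
  StructureModel(atoms, method = hdr$method, resolution = hdr$resolution,
                 modelNumber = as.integer(modelIndex))
}

## Keep, per (chain, resnum, icode, name), the highest-occupancy altloc;
## ties broken by file order.
.resolveAltlocs <- function(atoms) {
  if (!nrow(atoms) || all(!nzchar(atoms$altloc))) return(atoms)
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  atoms2 <- atoms[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- atoms2[keep, , drop = FALSE]
  out[order(match(paste(out$chain, out$resnum, out$icode, sep = "\r"),
                  unique(paste(atoms$chain, atoms$resnum, atoms$icode, sep = "\r"))),
            out$serial), , drop = FALSE]
}

.readHeaderMeta <- function(path, format) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  method <- "unknown"
  resolution <- NA_real_
  if (format == "pdb") {
    ex <- grep("^EXPDTA", lines, value = TRUE)
    if (length(ex)) method <- .mapMethod(ex[1])
    rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(rl)) {
      m <- regmatches(rl[1], regexpr("[0-9]+\\.?[0-9]*(?= *ANGSTROM)", rl[1], perl = TRUE))
      if (length(m)) resolution <- as.numeric(m)
    }
  } else {
    ex <- grep("_exptl\\.method", lines, value = TRUE)
    if (length(ex)) method <- .mapMethod(ex[1])
    for (tag in c("_refine\\.ls_d_res_high", "_reflns\\.d_resolution_high")) {
      rl <- grep(tag, lines, value = TRUE)
      if (length(rl)) {
        m <- regmatches(rl[1], regexpr("[0-9]+\\.?[0-9]*", sub(tag, "", rl[1])))
        if (length(m)) { resolution <- as.numeric(m); break }
      }
    }
  }
  list(method = method, resolution = resolution)
}

.mapMethod <- function(line) {
  up <- toupper(line)
  if (grepl("X-RAY", up)) "xray"
  else if (grepl("NMR", up)) "nmr"
  else if (grepl("ELECTRON MICROSCOPY|CRYO", up)) "em"
  else if (grepl("PREDICT|THEORETICAL", up)) "predicted"
  else "unknown"
}

#' Read full-length chain sequences from FASTA
#'
#' The header token after ">" up to the first whitespace is the chain id; a
#' single-record file with a long header token applies to chain "A". An
#' optional `start=N` field in the description sets the author residue
#' number of the first position (default 1).
#'
#' @param path FASTA file path.
#' @return A \linkS4class{SequenceSet}.
#' @export
readSequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no FASTA records in ", path)
  headers <- names(aa)
  tokens <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  ids <- tokens
  if (length(aa) == 1L && nchar(tokens[1]) > 2L) ids <- "A"
  starts <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("start=-?[0-9]+", h))
    if (length(m)) as.integer(sub("start=", "", m)) else 1L
  }, 1L, USE.NAMES = FALSE)
  if (anyDuplicated(ids)) stop("duplicate chain ids in FASTA: ", path)
  SequenceSet(stats::setNames(as.character(aa), ids),
              stats::setNames(starts, ids))
}

#' Observed residue letters of one chain
#'
#' One entry per residue that has at least one backbone atom (N, CA or C).
#' Modified residues are mapped to their parent one-letter code where known
#' (SEP to S, TPO to T, MSE to M, ...), else "X".
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param chain Chain id.
#' @return data.frame with columns `resnum`, `icode`, `code`.
#' @export
extractObservedSequence <- function(structure, chain) {
  at <- atomTable(structure)
  if (!chain %in% at$chain) stop("unknown chain: ", chain)
  at <- at[at$chain == chain & at$name %in% c("N", "CA", "C"), , drop = FALSE]
  if (!nrow(at)) {
    return(data.frame(resnum = integer(), icode = character(),
                      code = character(), stringsAsFactors = FALSE))
  }
  key <- paste(at$resnum, at$icode, sep = "\r")
  first <- !duplicated(key)
  res <- at[first, c("resnum", "icode", "resname")]
  code <- unname(.aa321[res$resname])
  code[is.na(code)] <- "X"
  out <- data.frame(resnum = res$resnum, icode = res$icode, code = code,
                    stringsAsFactors = FALSE)
  out[order(out$resnum, out$icode), , drop = FALSE]
}

#' Write an ensemble of conformers as PDB files
#'
#' One fixed-width PDB file per conformer, atoms renumbered serially from 1,
#' residues written in chain order with TER records between chains. Output
#' is byte-deterministic for identical inputs.
#'
#' @param models List of \linkS4class{StructureModel} objects.
#' @param outDir Output directory (created if needed).
#' @param prefix File-name prefix; files are named `prefix_001.pdb`, ...
#' @return Character vector of the written paths.
#' @export
writeEnsemble <- function(models, outDir, prefix = "conf") {
  if (!length(models)) return(character())
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (file.access(outDir, 2L) != 0L) stop("output directory not writable: ", outDir)
  paths <- character(length(models))
  for (k in seq_along(models)) {
    paths[k] <- file.path(outDir, sprintf("%s_%03d.pdb", prefix, k))
    writeLines(.pdbLines(models[[k]]), paths[k])
  }
  paths
}

.pdbAtomName <- function(name, element) {
  ## standard PDB alignment: element columns 13-14, so 1-3 char names with
  ## 1-char elements are blank-padded on the left
  if (nchar(name) >= 4L) return(substr(name, 1, 4))
  if (nchar(element) == 1L) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

.pdbLines <- function(model) {
  at <- atomTable(model)
  lines <- character(0)
  if (model@method != "unknown") {
    lines <- c(lines, sprintf("EXPDTA    %s", switch(model@method,
      xray = "X-RAY DIFFRACTION", nmr = "SOLUTION NMR",
      em = "ELECTRON MICROSCOPY", predicted = "THEORETICAL MODEL")))
  }
  if (!is.na(model@resolution)) {
    lines <- c(lines, sprintf(
      "REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", model@resolution))
  }
  serial <- 0L
  for (ch in chainIds(model)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, .pdbAtomName(sub$name[i], sub$element[i]), substr(sub$altloc[i], 1, 1),
        sub$resname[i], ch, sub$resnum[i], substr(sub$icode[i], 1, 1),
        sub$x[i], sub$y[i], sub$z[i], sub$occ[i], sub$b[i], sub$element[i]))
    }
    serial <- serial + 1L
    n <- nrow(sub)
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d%1s", serial,
                              sub$resname[n], ch, sub$resnum[n],
                              substr(sub$icode[n], 1, 1)))
  }
  c(lines, "END")
}
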