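## Ensemble summaries: phi/psi-region fractions of the built residues,
## CA-CA distance statistics between IDR and template residues, and radius
## of gyration of the built segments. The region assignment is a fixed
## rectangle classification of the Ramachandran plane, a deliberately
## simple stand-in for a full secondary-structure assignment; users who
## need DSSP run it externally on the written PDB files.

.regionOfTorsion <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return(NA_character_)
  if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5) return("helix")
  if (phi >= -180 && phi <= -90 &&
      ((psi >= 90 && psi <= 180) || (psi >= -180 && psi <= -170))) return("sheet")
  "other"
}

#' Ramachandran-region fractions of built residues across an ensemble
#'
#' Per built residue, the fraction of conformers whose (phi, psi) falls in
#' the helix rectangle (phi in [-100, -30], psi in [-80, -5]), the sheet
#' region (phi in [-180, -90], psi in [90, 180] or [-180, -170]), or
#' elsewhere. Residues whose phi or psi is undefined in a model (chain
#' termini) are skipped and counted.
#'
#' @param models List of \linkS4class{StructureModel} conformers.
#' @param segments Segment data.frame; fractions are computed for these
#'   residues.
#' @return List: `fractions` (data.frame chain, resnum, helix, sheet,
#'   other), `skipped` (count of undefined-torsion residue observations).
#' @export
torsionRegionFractions <- function(models, segments) {
  if (!length(models)) stop("need at least one model")
  segments <- validateSegments(segments)
  tally <- list()
  skipped <- 0L
  for (m in models) {
    at <- atomTable(m)
    for (ch in unique(segments$chain)) {
      tor <- measureTorsions(at[at$chain == ch, , drop = FALSE])
      segCh <- segments[segments$chain == ch, , drop = FALSE]
      for (si in seq_len(nrow(segCh))) {
        for (r in segCh$first[si]:segCh$last[si]) {
          row <- tor[tor$resnum == r, , drop = FALSE]
          reg <- .regionOfTorsion(row$phi[1], row$psi[1])
          if (is.na(reg)) { skipped <- skipped + 1L; next }
          key <- paste(ch, r)
          if (is.null(tally[[key]])) {
            tally[[key]] <- c(helix = 0L, sheet = 0L, other = 0L)
          }
          tally[[key]][reg] <- tally[[key]][reg] + 1L
        }
      }
    }
  }
  keys <- names(tally)
  fr <- do.call(rbind, lapply(keys, function(k) {
    parts <- strsplit(k, " ")[[1]]
    cnt <- tally[[k]]
    tot <- sum(cnt)
    data.frame(chain = parts[1], resnum = as.integer(parts[2]),
               helix = cnt[["helix"]] / tot, sheet = cnt[["sheet"]] / tot,
               other = cnt[["other"]] / tot, n = tot,
               stringsAsFactors = FALSE)
  }))
  fr <- fr[order(fr$chain, fr$resnum), , drop = FALSE]
  rownames(fr) <- NULL
  list(fractions = fr, skipped = skipped)
}

#' CA-CA distance statistics between IDR and template residues
#'
#' For every (IDR residue, template residue) pair, the mean, min and max of
#' the CA-CA distance across the ensemble.
#'
#' @param models List of \linkS4class{StructureModel} conformers.
#' @param idrResidues data.frame with columns chain, resnum.
#' @param templateResidues data.frame with columns chain, resnum.
#' @return List: `stats` (data.frame idrChain, idrResnum, tmplChain,
#'   tmplResnum, mean, min, max, n), `skipped` (missing-CA observations).
#' @export
caDistanceStats <- function(models, idrResidues, templateResidues) {
  if (!length(models)) stop("need at least one model")
  skipped <- 0L
  acc <- list()
  caOf <- function(at, ch, r) {
    row <- at[at$chain == ch & at$resnum == r & at$name == "CA", , drop = FALSE]
    if (!nrow(row)) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  for (m in models) {
    at <- atomTable(m)
    for (i in seq_len(nrow(idrResidues))) {
      ca1 <- caOf(at, idrResidues$chain[i], idrResidues$resnum[i])
      for (j in seq_len(nrow(templateResidues))) {
        ca2 <- caOf(at, templateResidues$chain[j], templateResidues$resnum[j])
        if (is.null(ca1) || is.null(ca2)) { skipped <- skipped + 1L; next }
        key <- paste(i, j)
        acc[[key]] <- c(acc[[key]], .vnorm(ca1 - ca2))
      }
    }
  }
  rows <- lapply(names(acc), function(k) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    d <- acc[[k]]
    data.frame(idrChain = idrResidues$chain[ij[1]],
               idrResnum = idrResidues$resnum[ij[1]],
               tmplChain = templateResidues$chain[ij[2]],
               tmplResnum = templateResidues$resnum[ij[2]],
               mean = mean(d), min = min(d), max = max(d), n = length(d),
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  stats <- stats[order(stats$idrChain, stats$idrResnum, stats$tmplChain,
                       stats$tmplResnum), , drop = FALSE]
  rownames(stats) <- NULL
  list(stats = stats, skipped = skipped)
}

## Radius of gyration of the built-segment atoms of one model.
.segmentRg <- function(model, segments) {
  at <- atomTable(model)
  sel <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(segments))) {
    sel <- sel | (at$chain == segments$chain[i] &
                  at$resnum >= segments$first[i] &
                  at$resnum <= segments$last[i])
  }
  xyz <- cbind(at$x, at$y, at$z)[sel, , drop = FALSE]
  if (!nrow(xyz)) return(NA_real_)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Write an ensemble analysis report
#'
#' JSON report (region fractions, CA-CA distance summaries, per-conformer
#' radius of gyration of the built segments) plus, when a PNG device is
#' available, fraction-per-residue and Rg-histogram plots. All report
#' numbers are exactly the outputs of [torsionRegionFractions()] and
#' [caDistanceStats()].
#'
#' @param models List of \linkS4class{StructureModel} conformers.
#' @param segments Segment data.frame.
#' @param out Output directory.
#' @param templateResidues Optional data.frame (chain, resnum) of template
#'   residues for the distance map; default: none (distance block omitted).
#' @return Invisible list of written file paths.
#' @export
ensembleReport <- function(models, segments, out, templateResidues = NULL) {
  if (!length(models)) stop("need at least one model")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  frac <- torsionRegionFractions(models, segments)
  rg <- vapply(models, .segmentRg, 1, segments = segments)
  report <- list(nConformers = length(models),
                 segments = segments,
                 regionFractions = frac$fractions,
                 skippedTorsions = frac$skipped,
                 segmentRg = rg)
  if (!is.null(templateResidues)) {
    idrRes <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
      data.frame(chain = segments$chain[i],
                 resnum = segments$first[i]:segments$last[i])
    }))
    dist <- caDistanceStats(models, idrRes, templateResidues)
    report$caDistances <- dist$stats
    report$skippedDistances <- dist$skipped
  }
  jsonPath <- file.path(out, "ensemble_report.json")
  jsonlite::write_json(report, jsonPath, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  paths <- jsonPath
  if (capabilities("png")) {
    fr <- frac$fractions
    long <- data.frame(resnum = rep(fr$resnum, 3),
                       region = rep(c("helix", "sheet", "other"),
                                    each = nrow(fr)),
                       fraction = c(fr$helix, fr$sheet, fr$other))
    p1 <- ggplot2::ggplot(long, ggplot2::aes(x = resnum, y = fraction, fill = region)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "residue", y = "fraction of conformers",
                    title = "Ramachandran-region fractions of built residues") +
      ggplot2::theme_minimal()
    fracPng <- file.path(out, "region_fractions.png")
    grDevices::png(fracPng, width = 900, height = 500)
    print(p1)
    grDevices::dev.off()
    rgPng <- file.path(out, "segment_rg.png")
    p2 <- ggplot2::ggplot(data.frame(rg = rg), ggplot2::aes(x = rg)) +
      ggplot2::geom_histogram(bins = 20, fill = "steelblue") +
      ggplot2::labs(x = "radius of gyration of built segments (Angstrom)",
                    y = "conformers") +
      ggplot2::theme_minimal()
    grDevices::png(rgPng, width = 700, height = 500)
    print(p2)
    grDevices::dev.off()
    paths <- c(paths, fracPng, rgPng)
  }
  invisible(paths)
}
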