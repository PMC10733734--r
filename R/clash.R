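## Steric clash screening of candidate fragments against a fixed context
## (template + environment + previously placed fragments). A pair clashes
## when its distance falls below the sum of van der Waals radii minus a
## subtractive tolerance. A uniform-grid cell list keeps the search linear;
## tests cross-check its counts against the all-pairs brute force.

#' Default clash-check parameters
#'
#' Element-keyed united van der Waals radii (Angstrom) with a subtractive
#' tolerance: atoms i, j clash when d(i, j) < r_i + r_j - tolerance.
#'
#' @param tolerance Angstrom subtracted from each radius sum (default 0.4).
#' @return List with `radii` (named numeric), `tolerance`, and
#'   `fallbackRadius` used (with a warning) for unlisted elements.
#' @export
defaultClashParams <- function(tolerance = 0.4) {
  list(radii = c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                 I = 1.98, FE = 1.80, ZN = 1.39, MG = 1.73, NA. = 2.27,
                 K = 2.75, CA = 2.31),
       tolerance = tolerance,
       fallbackRadius = 1.5)
}

.atomRadii <- function(elements, params) {
  el <- toupper(trimws(elements))
  el[el == "NA"] <- "NA."
  r <- unname(params$radii[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) in clash check, using fallback radius: ",
            paste(unique(el[unknown]), collapse = ", "))
    r[unknown] <- params$fallbackRadius
  }
  r
}

#' Count steric clashes between a fragment and its context
#'
#' @param fragAtoms Atom table (or data.frame with x, y, z, element) of the
#'   candidate fragment.
#' @param contextAtoms Atom table of the fixed context.
#' @param params Clash parameters, see [defaultClashParams()].
#' @param exclude Optional 2-column matrix/data.frame of (fragment row,
#'   context row) index pairs exempt from checking (bonded or junction
#'   atoms).
#' @return List with `count` and `pairs` (data.frame: fragment row `i`,
#'   context row `j`, `distance`, `cutoff`).
#' @export
clashCheck <- function(fragAtoms, contextAtoms, params = defaultClashParams(),
                       exclude = NULL) {
  nf <- nrow(fragAtoms)
  nc <- nrow(contextAtoms)
  empty <- data.frame(i = integer(), j = integer(), distance = numeric(),
                      cutoff = numeric())
  if (nf == 0L || nc == 0L) return(list(count = 0L, pairs = empty))

  rf <- .atomRadii(fragAtoms$element, params)
  rc <- .atomRadii(contextAtoms$element, params)
  maxCut <- max(rf) + max(rc) - params$tolerance
  if (maxCut <= 0) return(list(count = 0L, pairs = empty))

  fxyz <- cbind(fragAtoms$x, fragAtoms$y, fragAtoms$z)
  cxyz <- cbind(contextAtoms$x, contextAtoms$y, contextAtoms$z)

  ## uniform grid over context atoms, cell edge = max cutoff
  h <- maxCut
  cellIdx <- function(xyz) cbind(floor(xyz[, 1] / h), floor(xyz[, 2] / h),
                                 floor(xyz[, 3] / h))
  ccell <- cellIdx(cxyz)
  ckey <- paste(ccell[, 1], ccell[, 2], ccell[, 3])
  bins <- split(seq_len(nc), ckey)

  exKey <- character(0)
  if (!is.null(exclude) && NROW(exclude) > 0) {
    exKey <- paste(exclude[, 1], exclude[, 2])
  }

  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  hits <- vector("list", nf)
  fcell <- cellIdx(fxyz)
  for (i in seq_len(nf)) {
    nb <- sweep(offs, 2, fcell[i, ], "+")
    keys <- paste(nb[, 1], nb[, 2], nb[, 3])
    js <- unlist(bins[keys], use.names = FALSE)
    if (!length(js)) next
    dx <- cxyz[js, 1] - fxyz[i, 1]
    dy <- cxyz[js, 2] - fxyz[i, 2]
    dz <- cxyz[js, 3] - fxyz[i, 3]
    dist <- sqrt(dx * dx + dy * dy + dz * dz)
    cut <- rf[i] + rc[js] - params$tolerance
    sel <- dist < cut
    if (length(exKey)) sel <- sel & !(paste(i, js) %in% exKey)
    if (any(sel)) {
      hits[[i]] <- data.frame(i = i, j = js[sel], distance = dist[sel],
                              cutoff = cut[sel])
    }
  }
  pairs <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(pairs)) pairs <- empty
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  list(count = nrow(pairs), pairs = pairs)
}
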