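# Hydrogen-bond detection, occupancy matrices, net-force magnitude
# matrices, and grouped Pearson correlation between the two.

#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: donor-acceptor distance <= \code{dMax} AND
#' hydrogen-donor-acceptor angle (at the donor heavy atom) <=
#' \code{angleMaxDeg}. Defaults are the common trajectory-analysis values
#' 0.35 nm / 30 degrees.
#'
#' @param positions natoms x 3 matrix (nm), rows in structure atom order.
#' @param donors data.frame(donor, hydrogen): row indices of donor heavy
#'   atoms and their attached hydrogens.
#' @param acceptors integer row indices of acceptor atoms.
#' @param dMax donor-acceptor distance cutoff (nm).
#' @param angleMaxDeg H-D-A angle cutoff (degrees).
#' @return data.frame(donor, acceptor) of detected bonds.
#' @export
detectHbonds <- function(positions, donors, acceptors, dMax = 0.35,
                         angleMaxDeg = 30) {
  if (!all(c("donor", "hydrogen") %in% names(donors)))
    stop("role-table error: donors must have columns donor, hydrogen")
  if (anyNA(donors$hydrogen))
    stop("role-table error: donor without hydrogen entry")
  res <- list()
  cosMin <- cos(angleMaxDeg * pi / 180)
  for (i in seq_len(nrow(donors))) {
    D <- positions[donors$donor[i], ]
    H <- positions[donors$hydrogen[i], ]
    for (acc in acceptors) {
      if (acc == donors$donor[i]) next
      A <- positions[acc, ]
      da <- A - D
      r <- .norm3(da)
      if (r > dMax || r < 1e-9) next
      dh <- H - D
      ca <- sum(dh * da) / (.norm3(dh) * r)
      if (ca >= cosMin)
        res[[length(res) + 1L]] <- c(donors$donor[i], acc)
    }
  }
  if (!length(res))
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  m <- do.call(rbind, res)
  data.frame(donor = m[, 1], acceptor = m[, 2])
}

#' Hydrogen-bond occupancy matrix over a residue range
#'
#' Entry (ri, rj) is the fraction of frames in which at least one hydrogen
#' bond (either donation direction) connects residues ri and rj. Symmetric,
#' diagonal zero.
#'
#' @param frames a \linkS4class{FrameSequence}.
#' @param structure the matching \linkS4class{MolecularStructure}.
#' @param residRange integer vector of residue ids indexing the matrix.
#' @param donors,acceptors role table as in \code{\link{detectHbonds}}
#'   (row indices into the structure atom order).
#' @param dMax,angleMaxDeg detection criteria.
#' @return numeric matrix with dimnames = residue ids, entries in [0, 1].
#' @export
occupancyMatrix <- function(frames, structure, residRange, donors, acceptors,
                            dMax = 0.35, angleMaxDeg = 30) {
  if (!length(residRange)) stop("empty residue range")
  if (nFrames(frames) < 1L) stop("need at least one frame")
  resOf <- atoms(structure)$resid
  n <- length(residRange)
  counts <- matrix(0, n, n, dimnames = list(residRange, residRange))
  for (f in seq_len(nFrames(frames))) {
    hb <- detectHbonds(frames@coords[, , f, drop = TRUE], donors, acceptors,
                       dMax, angleMaxDeg)
    if (!nrow(hb)) next
    ri <- match(resOf[hb$donor], residRange)
    rj <- match(resOf[hb$acceptor], residRange)
    ok <- !is.na(ri) & !is.na(rj) & ri != rj
    seen <- unique(cbind(pmin(ri[ok], rj[ok]), pmax(ri[ok], rj[ok])))
    if (nrow(seen)) {
      counts[seen] <- counts[seen] + 1
      counts[seen[, c(2, 1), drop = FALSE]] <-
        counts[seen[, c(2, 1), drop = FALSE]] + 1
    }
  }
  counts / nFrames(frames)
}

#' Net-force magnitude matrix over a residue range
#'
#' Entry (ri, rj) is the Euclidean norm of the class-summed net force
#' vector between the residues, converted to pN. Symmetric by the
#' antisymmetry of the underlying vectors.
#'
#' @param net a \linkS4class{NetForceTable}.
#' @param residRange integer vector of residue ids indexing the matrix.
#' @param classes interaction classes to sum (default the non-bonded ones).
#' @param chain restrict to pairs within this chain (default: all).
#' @return numeric matrix (pN) with dimnames = residue ids.
#' @export
forceMagnitudeMatrix <- function(net, residRange,
                                 classes = c("coulomb", "lj"),
                                 chain = NULL) {
  n <- length(residRange)
  M <- matrix(0, n, n, dimnames = list(residRange, residRange))
  e <- net@entries
  e <- e[e$class %in% classes, , drop = FALSE]
  if (!is.null(chain))
    e <- e[e$chain_i == chain & e$chain_j == chain, , drop = FALSE]
  if (!nrow(e)) return(M)
  key <- paste(e$resid_i, e$resid_j, sep = "\r")
  sums <- rowsum(as.matrix(e[c("Fx", "Fy", "Fz")]), key)
  mag <- sqrt(rowSums(sums^2)) * .KJ_MOL_NM_TO_PN
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  ri <- match(as.integer(parts[, 1]), residRange)
  rj <- match(as.integer(parts[, 2]), residRange)
  ok <- !is.na(ri) & !is.na(rj)
  M[cbind(ri[ok], rj[ok])] <- mag[ok]
  M[cbind(rj[ok], ri[ok])] <- mag[ok]
  M
}

#' Grouped Pearson correlation between two residue-pair matrices
#'
#' The two matrices (e.g. non-bonded net-force magnitudes and hydrogen-bond
#' occupancies over the same residue range) are divided into unit-pair
#' blocks by a residue-to-unit grouping (e.g. 21 ankyrin-repeat units give
#' a 21 x 21 grid); each grid entry is the Pearson correlation over the
#' vectorised entries of that block. Residue self-pairs (the matrix
#' diagonal) are excluded. Blocks with fewer than \code{minPairs} entries
#' or zero variance are NA. The function applies no force filtering itself;
#' any weak-interaction cut is an explicit upstream step.
#'
#' @param A,B numeric matrices of identical shape.
#' @param grouping character/factor vector of unit labels, one per
#'   row/column of A.
#' @param minPairs minimum valid entries per block (default 3).
#' @return a \linkS4class{CorrelationGrid}.
#' @export
groupedPCC <- function(A, B, grouping, minPairs = 3L) {
  if (!all(dim(A) == dim(B))) stop("shape mismatch between A and B")
  if (length(grouping) != nrow(A))
    stop("grouping must label every row of the matrices")
  units <- unique(as.character(grouping))
  k <- length(units)
  pcc <- matrix(NA_real_, k, k, dimnames = list(units, units))
  cnt <- matrix(0L, k, k, dimnames = list(units, units))
  selfPair <- row(A) == col(A)
  for (u in seq_len(k)) {
    for (v in seq_len(k)) {
      block <- outer(grouping == units[u], grouping == units[v]) & !selfPair
      a <- A[block]
      b <- B[block]
      ok <- is.finite(a) & is.finite(b)
      a <- a[ok]
      b <- b[ok]
      cnt[u, v] <- length(a)
      if (length(a) >= minPairs && stats::sd(a) > 0 && stats::sd(b) > 0)
        pcc[u, v] <- stats::cor(a, b)
    }
  }
  new("CorrelationGrid", pcc = pcc, counts = cnt)
}

#' Intra- vs inter-unit summary of a correlation grid
#'
#' Mean and standard deviation of the diagonal entries (intra-unit) and of
#' the first off-diagonal entries (adjacent-unit) of the grid; undefined
#' entries are excluded and counted.
#'
#' @param grid a \linkS4class{CorrelationGrid}.
#' @return list(intra = c(mean, sd), inter = c(mean, sd),
#'   nIntra, nInter, nUndefined).
#' @export
diagonalSummary <- function(grid) {
  P <- grid@pcc
  k <- nrow(P)
  if (k < 2L) stop("grid must be at least 2 x 2")
  dg <- diag(P)
  off <- c(P[cbind(1:(k - 1), 2:k)], P[cbind(2:k, 1:(k - 1))])
  if (all(!is.finite(dg))) stop("all diagonal entries undefined")
  dgOK <- dg[is.finite(dg)]
  offOK <- off[is.finite(off)]
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  list(intra = c(mean = mean(dgOK), sd = sd0(dgOK)),
       inter = c(mean = if (length(offOK)) mean(offOK) else NA_real_,
                 sd = sd0(offOK)),
       nIntra = length(dgOK), nInter = length(offOK),
       nUndefined = sum(!is.finite(c(dg, off))))
}
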