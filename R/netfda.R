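# Condition-difference (net) force fields: time averaging, the forced-minus-
# free difference, four-fold rotational symmetrisation, thresholding and
# domain-level aggregation.

.PAIR_KEYS <- c("chain_i", "resid_i", "chain_j", "resid_j", "class")

#' Construct a PairForceTable from a per-frame entry table
#'
#' Convenience constructor used by the synthetic generators and table
#' readers; pairs are reordered to the canonical ri < rj orientation
#' (flipping vector signs as needed).
#'
#' @param entries data.frame with columns chain_i, resid_i, chain_j,
#'   resid_j, class, frame, time, Fx, Fy, Fz.
#' @param nframes total number of frames the table covers.
#' @return a \linkS4class{PairForceTable}.
#' @export
pairForceTable <- function(entries, nframes) {
  flip <- entries$chain_i > entries$chain_j |
    (entries$chain_i == entries$chain_j & entries$resid_i > entries$resid_j)
  if (any(flip)) {
    tmp <- entries$chain_i[flip]
    entries$chain_i[flip] <- entries$chain_j[flip]
    entries$chain_j[flip] <- tmp
    tmp <- entries$resid_i[flip]
    entries$resid_i[flip] <- entries$resid_j[flip]
    entries$resid_j[flip] <- tmp
    entries$Fx[flip] <- -entries$Fx[flip]
    entries$Fy[flip] <- -entries$Fy[flip]
    entries$Fz[flip] <- -entries$Fz[flip]
  }
  new("PairForceTable", entries = entries, nframes = as.integer(nframes))
}

# Per-pair, per-class mean vectors of a PairForceTable over a frame window.
# Pairs absent from a frame count as zero (omitted-zero storage).
.pairMeans <- function(table, window = NULL) {
  e <- table@entries
  nf <- table@nframes
  if (!is.null(window)) {
    if (!length(window)) stop("empty frame window")
    e <- e[e$frame %in% window, , drop = FALSE]
    nf <- length(window)
  }
  if (nf < 1L) stop("empty frame window")
  if (!nrow(e))
    return(data.frame(chain_i = character(0), resid_i = integer(0),
                      chain_j = character(0), resid_j = integer(0),
                      class = character(0), Fx = numeric(0), Fy = numeric(0),
                      Fz = numeric(0)))
  agg <- stats::aggregate(e[c("Fx", "Fy", "Fz")], by = e[.PAIR_KEYS],
                          FUN = sum)
  agg$Fx <- agg$Fx / nf
  agg$Fy <- agg$Fy / nf
  agg$Fz <- agg$Fz / nf
  agg
}

#' Time-average a pairwise force table
#'
#' Arithmetic per-pair, per-class mean of the per-frame force vectors over a
#' frame window; frames where a pair has no stored entry contribute zero.
#'
#' @param table a \linkS4class{PairForceTable}.
#' @param window integer frame indices (default: all frames).
#' @return a \linkS4class{NetForceTable}-shaped object holding the means
#'   (nForced = window size, nFree = 0).
#' @export
timeAverage <- function(table, window = NULL) {
  m <- .pairMeans(table, window)
  nf <- if (is.null(window)) table@nframes else length(window)
  new("NetForceTable", entries = m, nForced = as.integer(nf), nFree = 0L)
}

# Align mean tables on the union of keys, filling absent pairs with zero.
.alignMeans <- function(tables) {
  keyOf <- function(d) paste(d$chain_i, d$resid_i, d$chain_j, d$resid_j,
                             d$class, sep = "\r")
  keys <- unique(unlist(lapply(tables, function(d) keyOf(d))))
  template <- do.call(rbind, lapply(tables, function(d) d[.PAIR_KEYS]))
  template <- template[!duplicated(keyOf(template)), , drop = FALSE]
  template <- template[match(keys, keyOf(template)), , drop = FALSE]
  mats <- lapply(tables, function(d) {
    m <- matrix(0, length(keys), 3)
    idx <- match(keyOf(d), keys)
    m[idx, ] <- as.matrix(d[c("Fx", "Fy", "Fz")])
    m
  })
  list(template = template, mats = mats)
}

# Residue universe of a PairForceTable (chain:resid strings).
.residueUniverse <- function(table) {
  e <- table@entries
  sort(unique(c(paste(e$chain_i, e$resid_i), paste(e$chain_j, e$resid_j))))
}

#' Net force distribution between two simulation conditions
#'
#' The mean pairwise force over the forced replicates minus the mean over
#' the force-free replicates, per residue pair and interaction class:
#' with two replicates per condition this is (A1 + A2 - B1 - B2) / 2.
#' Replicates are weighted equally regardless of their frame counts (the
#' equal-weight form of the condition difference); set
#' \code{frameWeighted = TRUE} to pool frames instead.
#'
#' @param forced list of \linkS4class{PairForceTable}, forced condition.
#' @param free list of \linkS4class{PairForceTable}, force-free condition.
#' @param frameWeighted logical; pool frames across replicates instead of
#'   averaging replicate means (default FALSE).
#' @return a \linkS4class{NetForceTable}.
#' @export
netFDA <- function(forced, free, frameWeighted = FALSE) {
  if (!length(forced) || !length(free))
    stop("both condition lists must be non-empty")
  uni <- lapply(c(forced, free), .residueUniverse)
  if (length(unique(vapply(uni, paste, "", collapse = "|"))) != 1L)
    stop("alignment error: residue universes differ between tables")
  condMean <- function(tabs) {
    if (frameWeighted) {
      total <- sum(vapply(tabs, function(t) t@nframes, integer(1)))
      sums <- lapply(tabs, function(t) {
        m <- .pairMeans(t)
        m[c("Fx", "Fy", "Fz")] <- m[c("Fx", "Fy", "Fz")] * t@nframes
        m
      })
      al <- .alignMeans(sums)
      list(template = al$template, m = Reduce(`+`, al$mats) / total)
    } else {
      al <- .alignMeans(lapply(tabs, .pairMeans))
      list(template = al$template,
           m = Reduce(`+`, al$mats) / length(tabs))
    }
  }
  mf <- condMean(forced)
  m0 <- condMean(free)
  al <- .alignMeans(list(cbind(mf$template,
                               as.data.frame(`colnames<-`(mf$m,
                                                          c("Fx", "Fy", "Fz")))),
                         cbind(m0$template,
                               as.data.frame(`colnames<-`(m0$m,
                                                          c("Fx", "Fy", "Fz"))))))
  net <- al$mats[[1]] - al$mats[[2]]
  entries <- al$template
  entries$Fx <- net[, 1]
  entries$Fy <- net[, 2]
  entries$Fz <- net[, 3]
  rownames(entries) <- NULL
  new("NetForceTable", entries = entries,
      nForced = sum(vapply(forced, function(t) t@nframes, integer(1))),
      nFree = sum(vapply(free, function(t) t@nframes, integer(1))))
}

#' Four-fold rotational symmetrisation of a net force table
#'
#' Averages the force field over the four subunits of a C4-symmetric
#' channel: each entry of chain k (and its partner chain offset) is rotated
#' about the pore axis back into the reference-chain frame (by -90 k
#' degrees) and the four images are averaged; absent images count as zero.
#' The result is the exactly C4-symmetric table (entries replicated on all
#' four chains), so the operation is idempotent; the reference-chain entries
#' are the conventional readout.
#'
#' @param net a \linkS4class{NetForceTable}.
#' @param map a \linkS4class{SymmetryMap}; chain k+1 of the cycle sits at
#'   +90 degrees from chain k; residue equivalence is by identical author
#'   resid across chains.
#' @return a symmetrised \linkS4class{NetForceTable}.
#' @export
symmetrizeC4 <- function(net, map) {
  e <- net@entries
  if (!nrow(e)) return(net)
  posOf <- function(ch) match(ch, map@chains)
  pi_ <- posOf(e$chain_i)
  pj_ <- posOf(e$chain_j)
  if (anyNA(pi_) || anyNA(pj_))
    stop("mapping error: entry references a chain outside the symmetry map")
  Rot <- lapply(0:3, function(k) .rotationMatrix(map@axis, -k * pi / 2))
  vec <- as.matrix(e[c("Fx", "Fy", "Fz")])
  # canonical representative of each entry's equivalence class under the
  # simultaneous chain cycle: orientation ((0, ri), (d, rj)) with the
  # smaller chain offset d (ties at d = 0 or 2 broken by resid order),
  # vector rotated into the reference-chain frame
  d1 <- (pj_ - pi_) %% 4L
  d2 <- (4L - d1) %% 4L
  useSwap <- d2 < d1 | (d1 == d2 & e$resid_j < e$resid_i)
  relj <- ifelse(useSwap, d2, d1)
  ri <- ifelse(useSwap, e$resid_j, e$resid_i)
  rj <- ifelse(useSwap, e$resid_i, e$resid_j)
  basePos <- ifelse(useSwap, pj_, pi_)
  sgn <- ifelse(useSwap, -1, 1)
  refVec <- matrix(0, nrow(e), 3)
  for (k in 0:3) {
    idx <- which(basePos == k + 1L)
    if (length(idx))
      refVec[idx, ] <- (sgn[idx] * vec[idx, , drop = FALSE]) %*%
        t(Rot[[k + 1L]])
  }
  key <- paste(ri, relj, rj, e$class, sep = "\r")
  sums <- rowsum(refVec, key)
  cnt <- 4L                     # average over the four expected images
  ukey <- rownames(sums)
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  avg <- sums / cnt
  # replicate the averaged reference entries onto all four chains
  outList <- vector("list", 4L)
  for (k in 0:3) {
    ci <- map@chains[k + 1L]
    cj <- map@chains[((k + as.integer(parts[, 2])) %% 4L) + 1L]
    v <- avg %*% t(.rotationMatrix(map@axis, k * pi / 2))
    outList[[k + 1L]] <- data.frame(
      chain_i = ci, resid_i = as.integer(parts[, 1]),
      chain_j = cj, resid_j = as.integer(parts[, 3]),
      class = parts[, 4], Fx = v[, 1], Fy = v[, 2], Fz = v[, 3],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, outList)
  # restore canonical pair orientation
  flip <- out$chain_i > out$chain_j |
    (out$chain_i == out$chain_j & out$resid_i > out$resid_j)
  if (any(flip)) {
    tmp <- out$chain_i[flip]
    out$chain_i[flip] <- out$chain_j[flip]
    out$chain_j[flip] <- tmp
    tmp <- out$resid_i[flip]
    out$resid_i[flip] <- out$resid_j[flip]
    out$resid_j[flip] <- tmp
    out$Fx[flip] <- -out$Fx[flip]
    out$Fy[flip] <- -out$Fy[flip]
    out$Fz[flip] <- -out$Fz[flip]
  }
  # flipped duplicates (intra-chain pairs seen from both orientations) merge
  out <- stats::aggregate(out[c("Fx", "Fy", "Fz")], by = out[.PAIR_KEYS],
                          FUN = mean)
  rownames(out) <- NULL
  new("NetForceTable", entries = out, nForced = net@nForced,
      nFree = net@nFree)
}

#' Drop weak interactions from a net force table
#'
#' Removes residue pairs whose class-summed net force magnitude, converted
#' to pN, is strictly below the threshold (the "weak interactions
#' neglected" display filter; the conventional cut is 5 pN).
#'
#' @param net a \linkS4class{NetForceTable}.
#' @param minForcePN threshold in pN, >= 0.
#' @return filtered \linkS4class{NetForceTable}.
#' @export
thresholdFilter <- function(net, minForcePN) {
  if (minForcePN < 0) stop("threshold must be >= 0")
  e <- net@entries
  if (!nrow(e)) return(net)
  key <- paste(e$chain_i, e$resid_i, e$chain_j, e$resid_j, sep = "\r")
  sums <- rowsum(as.matrix(e[c("Fx", "Fy", "Fz")]), key)
  magPN <- sqrt(rowSums(sums^2)) * .KJ_MOL_NM_TO_PN
  keep <- key %in% rownames(sums)[magPN >= minForcePN]
  out <- e[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("NetForceTable", entries = out, nForced = net@nForced,
      nFree = net@nFree)
}

#' Aggregate net forces between two domains
#'
#' For each residue of the target domain, the summed net force vector
#' exerted by all residues of the source domain (class-summed), plus the
#' domain total — e.g. the net forces on the TRP domain exerted by the LH
#' domain, whose per-residue magnitudes identify the major points of force
#' application.
#'
#' @param net a \linkS4class{NetForceTable}.
#' @param mapping data.frame(label, chain, first, last) as returned by
#'   \code{\link{readDomainMap}}; labels must not overlap on any residue.
#' @param source,target domain labels in \code{mapping}.
#' @return list(perResidue = data.frame(chain, resid, Fx, Fy, Fz, magPN),
#'   total = 3-vector kJ/mol/nm).
#' @export
aggregateDomains <- function(net, mapping, source, target) {
  lab <- function(ch, rs) {
    hits <- mapping$label[mapping$chain == ch & mapping$first <= rs &
                            mapping$last >= rs]
    if (length(hits) > 1L)
      stop("mapping error: residue ", ch, ":", rs,
           " carries overlapping domain labels")
    if (!length(hits)) NA_character_ else hits
  }
  e <- net@entries
  if (!nrow(e)) stop("empty net force table")
  li <- mapply(lab, e$chain_i, e$resid_i)
  lj <- mapply(lab, e$chain_j, e$resid_j)
  rows <- list()
  selTI <- which(li == target & lj == source)   # force on i by j: +v
  if (length(selTI))
    rows[[1]] <- data.frame(chain = e$chain_i[selTI],
                            resid = e$resid_i[selTI],
                            Fx = e$Fx[selTI], Fy = e$Fy[selTI],
                            Fz = e$Fz[selTI])
  selTJ <- which(lj == target & li == source)   # force on j by i: -v
  if (length(selTJ))
    rows[[2]] <- data.frame(chain = e$chain_j[selTJ],
                            resid = e$resid_j[selTJ],
                            Fx = -e$Fx[selTJ], Fy = -e$Fy[selTJ],
                            Fz = -e$Fz[selTJ])
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(list(perResidue = data.frame(chain = character(0),
                                        resid = integer(0), Fx = numeric(0),
                                        Fy = numeric(0), Fz = numeric(0),
                                        magPN = numeric(0)),
                total = c(0, 0, 0)))
  all <- do.call(rbind, rows)
  per <- stats::aggregate(all[c("Fx", "Fy", "Fz")],
                          by = all[c("chain", "resid")], FUN = sum)
  per$magPN <- sqrt(per$Fx^2 + per$Fy^2 + per$Fz^2) * .KJ_MOL_NM_TO_PN
  per <- per[order(-per$magPN), , drop = FALSE]
  rownames(per) <- NULL
  list(perResidue = per,
       total = c(sum(per$Fx), sum(per$Fy), sum(per$Fz)))
}
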