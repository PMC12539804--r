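# The residue-level force-distribution engine: per frame, atomic pairwise
# forces (bonded + switched Coulomb + switched Lennard-Jones) summed over
# the atoms of each residue pair, stored per interaction class.

# Bond-graph separation classes: 1 = 1-2, 2 = 1-3, 3 = 1-4; Inf otherwise.
# Returns a natoms x natoms integer-ish matrix (desk-scale systems only).
.bondSeparation <- function(n, bonds) {
  sep <- matrix(Inf, n, n)
  diag(sep) <- 0
  if (nrow(bonds)) {
    adj <- vector("list", n)
    for (i in seq_len(nrow(bonds))) {
      adj[[bonds$ai[i]]] <- c(adj[[bonds$ai[i]]], bonds$aj[i])
      adj[[bonds$aj[i]]] <- c(adj[[bonds$aj[i]]], bonds$ai[i])
    }
    for (s in seq_len(n)) {       # BFS to depth 3
      frontier <- s
      for (d in 1:3) {
        nxt <- unique(unlist(adj[frontier]))
        nxt <- nxt[sep[s, nxt] > d]
        if (!length(nxt)) break
        sep[s, nxt] <- d
        frontier <- nxt
      }
    }
  }
  sep
}

# Nonbonded atomic pair forces for one frame.
# Returns data.frame(ai, aj, class, Fx, Fy, Fz), force on ai by aj, ai < aj.
.nonbondedPairForces <- function(params, positions, sep) {
  n <- nrow(positions)
  excl12 <- "1-2" %in% params@exclusions
  excl13 <- "1-3" %in% params@exclusions
  excl14 <- "1-4" %in% params@exclusions
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sep[i, j]
      if ((s == 1 && excl12) || (s == 2 && excl13) || (s == 3 && excl14))
        next
      scale <- if (s == 3) params@scale14 else 1
      rvec <- positions[i, ] - positions[j, ]
      r <- .norm3(rvec)
      if (r >= params@cutoff) next
      fc <- coulombPairForce(params@charge[i], params@charge[j], rvec,
                             params@switchOn, params@cutoff) * scale
      lb <- .combineLB(params@sigma[i], params@sigma[j],
                       params@epsilon[i], params@epsilon[j])
      fl <- ljPairForce(lb$sigma, lb$epsilon, rvec,
                        params@switchOn, params@cutoff) * scale
      if (any(fc != 0))
        rows[[length(rows) + 1L]] <- data.frame(
          ai = i, aj = j, class = "coulomb",
          Fx = fc[1], Fy = fc[2], Fz = fc[3])
      if (any(fl != 0))
        rows[[length(rows) + 1L]] <- data.frame(
          ai = i, aj = j, class = "lj", Fx = fl[1], Fy = fl[2], Fz = fl[3])
    }
  }
  if (!length(rows))
    return(data.frame(ai = integer(0), aj = integer(0),
                      class = character(0), Fx = numeric(0),
                      Fy = numeric(0), Fz = numeric(0)))
  do.call(rbind, rows)
}

#' Residue-pairwise forces over trajectory frames
#'
#' The force-distribution analysis: for every frame, atomic pairwise forces
#' of all bonded terms plus switched Coulomb and Lennard-Jones interactions
#' are computed and summed over the atoms of each residue pair, stored
#' separately per interaction class (the per-frame, class-resolved storage
#' convention). Nonbonded pairs respect the exclusion policy of
#' \code{params}. Entries whose per-frame vector is all-zero are omitted.
#'
#' @param structure a \linkS4class{MolecularStructure}.
#' @param frames a \linkS4class{FrameSequence} with matching atom order.
#' @param params an \linkS4class{InteractionParameters} covering all atoms.
#' @return a \linkS4class{PairForceTable}: force on residue ri by rj
#'   (ri < rj by chain then resid), kJ/mol/nm.
#' @export
residuePairwiseForces <- function(structure, frames, params) {
  a <- atoms(structure)
  n <- nrow(a)
  if (length(params@charge) != n)
    stop("parameter error: parameters cover ", length(params@charge),
         " atoms, structure has ", n)
  if (dim(frames@coords)[1] != n)
    stop("shape error: frames do not match structure atom count")
  sep <- .bondSeparation(n, params@bonds)
  out <- list()
  for (f in seq_len(nFrames(frames))) {
    pos <- frames@coords[, , f, drop = TRUE]
    ab <- bondedPairForces(params, pos)
    ab$class <- if (nrow(ab)) "bonded" else character(0)
    nb <- .nonbondedPairForces(params, pos, sep)
    atomic <- rbind(ab[c("ai", "aj", "class", "Fx", "Fy", "Fz")],
                    nb[c("ai", "aj", "class", "Fx", "Fy", "Fz")])
    if (!nrow(atomic)) next
    # map atoms to residues; drop intra-residue pairs; orient ri < rj
    ci <- a$chain[atomic$ai]; ri <- a$resid[atomic$ai]
    cj <- a$chain[atomic$aj]; rj <- a$resid[atomic$aj]
    keep <- !(ci == cj & ri == rj)
    if (!any(keep)) next
    atomic <- atomic[keep, ]; ci <- ci[keep]; ri <- ri[keep]
    cj <- cj[keep]; rj <- rj[keep]
    flip <- cj < ci | (cj == ci & rj < ri)
    if (any(flip)) {
      tmp <- ci[flip]; ci[flip] <- cj[flip]; cj[flip] <- tmp
      tmp <- ri[flip]; ri[flip] <- rj[flip]; rj[flip] <- tmp
      atomic$Fx[flip] <- -atomic$Fx[flip]
      atomic$Fy[flip] <- -atomic$Fy[flip]
      atomic$Fz[flip] <- -atomic$Fz[flip]
    }
    res <- stats::aggregate(atomic[c("Fx", "Fy", "Fz")],
                            by = list(chain_i = ci, resid_i = ri,
                                      chain_j = cj, resid_j = rj,
                                      class = atomic$class), FUN = sum)
    nz <- abs(res$Fx) + abs(res$Fy) + abs(res$Fz) > 0
    res <- res[nz, , drop = FALSE]
    if (!nrow(res)) next
    res$frame <- f
    res$time <- frames@times[f]
    out[[length(out) + 1L]] <- res
  }
  entries <- if (length(out)) do.call(rbind, out) else
    data.frame(chain_i = character(0), resid_i = integer(0),
               chain_j = character(0), resid_j = integer(0),
               class = character(0), frame = integer(0), time = numeric(0),
               Fx = numeric(0), Fy = numeric(0), Fz = numeric(0))
  entries <- entries[c("chain_i", "resid_i", "chain_j", "resid_j", "class",
                       "frame", "time", "Fx", "Fy", "Fz")]
  rownames(entries) <- NULL
  new("PairForceTable", entries = entries,
      nframes = as.integer(nFrames(frames)))
}
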