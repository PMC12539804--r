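#' @import methods
NULL

.finite3 <- function(x) all(is.finite(x)) && length(x) == 3L

#' Molecular structure container
#'
#' Holds atoms of a (possibly multi-chain) molecular model. Coordinates are
#' stored in nanometres throughout the package; PDB input is converted at the
#' boundary. The optional \code{vdw} column carries per-atom van der Waals
#' radii (nm) used by the pore profiler.
#'
#' @slot atoms data.frame with columns \code{atom_id}, \code{atom_name},
#'   \code{element}, \code{resid}, \code{resname}, \code{chain},
#'   \code{x}, \code{y}, \code{z} (nm) and optionally \code{vdw} (nm).
#' @export
setClass("MolecularStructure", slots = c(atoms = "data.frame"))

setValidity("MolecularStructure", function(object) {
  a <- object@atoms
  req <- c("atom_id", "atom_name", "element", "resid", "resname",
           "chain", "x", "y", "z")
  if (!all(req %in% names(a)))
    return(paste("atoms must contain columns:", paste(req, collapse = ", ")))
  if (anyDuplicated(a$atom_id))
    return("duplicated atom_id")
  if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
    return("non-finite coordinates")
  TRUE
})

#' Ordered trajectory frames
#'
#' Per-frame coordinates for a fixed atom order matching a
#' \linkS4class{MolecularStructure}. Times are in picoseconds, coordinates
#' and box lengths in nanometres (box may be NA when unknown).
#'
#' @slot coords numeric array natoms x 3 x nframes (nm).
#' @slot times numeric, strictly increasing (ps).
#' @slot box numeric matrix nframes x 3 (nm), NA allowed.
#' @export
setClass("FrameSequence",
         slots = c(coords = "array", times = "numeric", box = "matrix"))

setValidity("FrameSequence", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be a natoms x 3 x nframes array")
  if (d[3] != length(object@times))
    return("number of frames does not match length(times)")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (!all(is.finite(object@coords)))
    return("non-finite coordinates")
  TRUE
})

#' Per-atom interaction parameters
#'
#' Charges (e), Lennard-Jones parameters (sigma nm, epsilon kJ/mol), bonded
#' terms and the nonbonded switching/cutoff scheme. Angle equilibrium values
#' and dihedral phases are stored in radians internally.
#'
#' @slot charge numeric per atom (e).
#' @slot sigma numeric per atom (nm), > 0.
#' @slot epsilon numeric per atom (kJ/mol), >= 0.
#' @slot bonds data.frame(ai, aj, k, r0): harmonic, k in kJ/mol/nm^2, r0 nm.
#' @slot angles data.frame(ai, aj, ak, k, theta0): harmonic, theta0 rad.
#' @slot dihedrals data.frame(ai, aj, ak, al, k, mult, phase): periodic.
#' @slot exclusions character, subset of c("1-2","1-3","1-4").
#' @slot scale14 numeric scale applied to included 1-4 nonbonded pairs.
#' @slot switchOn numeric nm, switch-on radius.
#' @slot cutoff numeric nm, cutoff radius (> switchOn).
#' @export
setClass("InteractionParameters",
         slots = c(charge = "numeric", sigma = "numeric", epsilon = "numeric",
                   bonds = "data.frame", angles = "data.frame",
                   dihedrals = "data.frame", exclusions = "character",
                   scale14 = "numeric", switchOn = "numeric",
                   cutoff = "numeric"))

setValidity("InteractionParameters", function(object) {
  n <- length(object@charge)
  if (length(object@sigma) != n || length(object@epsilon) != n)
    return("charge, sigma, epsilon must have equal length")
  if (any(object@sigma <= 0)) return("sigma must be > 0")
  if (any(object@epsilon < 0)) return("epsilon must be >= 0")
  if (object@switchOn >= object@cutoff)
    return("switchOn must be < cutoff")
  idx <- c(unlist(object@bonds[c("ai", "aj")]),
           unlist(object@angles[c("ai", "aj", "ak")]),
           unlist(object@dihedrals[c("ai", "aj", "ak", "al")]))
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    return("bonded term references an atom outside 1..natoms")
  if (!all(object@exclusions %in% c("1-2", "1-3", "1-4")))
    return("exclusions must be among 1-2, 1-3, 1-4")
  TRUE
})

#' Per-frame residue-pairwise forces
#'
#' The force-distribution-analysis output: for each ordered residue pair
#' (ri < rj by chain then resid) and interaction class, the per-frame force
#' vector exerted ON ri BY rj, in kJ/mol/nm. All-zero entries may be omitted.
#'
#' @slot entries data.frame(chain_i, resid_i, chain_j, resid_j, class,
#'   frame, time, Fx, Fy, Fz).
#' @slot nframes integer number of frames the table covers.
#' @export
setClass("PairForceTable",
         slots = c(entries = "data.frame", nframes = "integer"))

setValidity("PairForceTable", function(object) {
  e <- object@entries
  req <- c("chain_i", "resid_i", "chain_j", "resid_j", "class",
           "frame", "time", "Fx", "Fy", "Fz")
  if (!all(req %in% names(e)))
    return(paste("entries must contain columns:", paste(req, collapse = ", ")))
  if (nrow(e)) {
    bad <- e$chain_i > e$chain_j |
      (e$chain_i == e$chain_j & e$resid_i >= e$resid_j)
    if (any(bad)) return("pairs must be ordered ri < rj by (chain, resid)")
    if (!all(is.finite(c(e$Fx, e$Fy, e$Fz)))) return("non-finite forces")
  }
  TRUE
})

#' Time-averaged condition-difference force field
#'
#' Per residue pair and interaction class, the mean force under the forced
#' condition minus the mean under the force-free condition (kJ/mol/nm), i.e.
#' the net residual force field induced by the external perturbation.
#'
#' @slot entries data.frame(chain_i, resid_i, chain_j, resid_j, class,
#'   Fx, Fy, Fz).
#' @slot nForced integer, frames per forced replicate (total).
#' @slot nFree integer, frames per free replicate (total).
#' @export
setClass("NetForceTable",
         slots = c(entries = "data.frame", nForced = "integer",
                   nFree = "integer"))

setValidity("NetForceTable", function(object) {
  e <- object@entries
  req <- c("chain_i", "resid_i", "chain_j", "resid_j", "class",
           "Fx", "Fy", "Fz")
  if (!all(req %in% names(e)))
    return(paste("entries must contain columns:", paste(req, collapse = ", ")))
  if (nrow(e) && !all(is.finite(c(e$Fx, e$Fy, e$Fz))))
    return("non-finite forces")
  TRUE
})

#' Four-fold symmetry description of a tetrameric channel
#'
#' @slot axis unit 3-vector, the pore (membrane-normal) axis.
#' @slot center 3-vector nm, pivot of the rotational symmetry.
#' @slot chains character(4): the chain cycle; chain k+1 occupies the
#'   position of chain k rotated by +90 degrees about the axis.
#' @export
setClass("SymmetryMap",
         slots = c(axis = "numeric", center = "numeric", chains = "character"))

setValidity("SymmetryMap", function(object) {
  if (!.finite3(object@axis) || abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    return("axis must be a finite unit 3-vector")
  if (!.finite3(object@center)) return("center must be a finite 3-vector")
  if (length(object@chains) != 4L || anyDuplicated(object@chains))
    return("chains must be 4 distinct chain ids")
  TRUE
})

#' Right-handed per-subunit local frame
#'
#' The local frame used to decompose forces on the TRP domain: z points
#' extracellular along the membrane normal, x along the in-plane component
#' of the TRP-helix axis (pore centre toward membrane), y = z x x.
#'
#' @slot origin 3-vector nm.
#' @slot ex,ey,ez orthonormal right-handed unit 3-vectors.
#' @export
setClass("LocalFrame",
         slots = c(origin = "numeric", ex = "numeric", ey = "numeric",
                   ez = "numeric"))

setValidity("LocalFrame", function(object) {
  ax <- list(object@ex, object@ey, object@ez)
  if (!all(vapply(ax, .finite3, logical(1))) || !.finite3(object@origin))
    return("origin and axes must be finite 3-vectors")
  if (any(abs(vapply(ax, function(v) sqrt(sum(v^2)), numeric(1)) - 1) > 1e-6))
    return("axes must be unit length")
  if (max(abs(.cross3(object@ex, object@ey) - object@ez)) > 1e-6)
    return("frame must be right-handed (x cross y = z)")
  TRUE
})

#' Elasticity fit result
#'
#' Carries either the torsion coefficient c of M = c * phi (kJ/mol/rad) or
#' the compression-twist coupling k_ct of L = L0 - k_ct * phi (nm/rad),
#' with standard error, residuals, and the number of points fitted.
#'
#' @slot kind "torsion" or "compression-twist".
#' @slot estimate numeric: c or k_ct.
#' @slot stderr numeric standard error (>= 0).
#' @slot intercept numeric: L0 for the coupling fit, NA for the torsion fit
#'   (origin-constrained) unless an intercept was requested.
#' @slot residuals numeric.
#' @slot n integer number of points.
#' @slot extensionCoupled logical: TRUE when the bundle lengthens with twist
#'   (negative k_ct).
#' @export
setClass("ElasticityFit",
         slots = c(kind = "character", estimate = "numeric",
                   stderr = "numeric", intercept = "numeric",
                   residuals = "numeric", n = "integer",
                   extensionCoupled = "logical"))

setValidity("ElasticityFit", function(object) {
  if (!object@kind %in% c("torsion", "compression-twist"))
    return("kind must be 'torsion' or 'compression-twist'")
  if (is.finite(object@stderr) && object@stderr < 0)
    return("standard error must be >= 0")
  TRUE
})

#' Grouped Pearson-correlation grid
#'
#' Square grid indexed by structural-unit pair (e.g. ankyrin-repeat units);
#' each entry is the Pearson correlation between the residue-pair entries of
#' two matrices restricted to that unit-pair block. Undefined blocks
#' (too few pairs or zero variance) are NA.
#'
#' @slot pcc numeric matrix in [-1, 1] or NA, dimnames = unit labels.
#' @slot counts integer matrix of valid pairs per block.
#' @export
setClass("CorrelationGrid", slots = c(pcc = "matrix", counts = "matrix"))

setValidity("CorrelationGrid", function(object) {
  if (!all(dim(object@pcc) == dim(object@counts)))
    return("pcc and counts must have equal dimensions")
  v <- object@pcc[is.finite(object@pcc)]
  if (length(v) && (any(v < -1 - 1e-12) || any(v > 1 + 1e-12)))
    return("correlations must lie in [-1, 1]")
  TRUE
})

#' Pore radius profile along the channel axis
#'
#' @slot profile data.frame(z, cx, cy, radius, defined): slice position along
#'   the axis (nm), optimised in-plane centre, accessible radius (nm, >= 0),
#'   and whether the slice had atoms to constrain it.
#' @export
setClass("PoreProfile", slots = c(profile = "data.frame"))

setValidity("PoreProfile", function(object) {
  p <- object@profile
  req <- c("z", "cx", "cy", "radius", "defined")
  if (!all(req %in% names(p)))
    return(paste("profile must contain columns:", paste(req, collapse = ", ")))
  if (nrow(p) > 1L && any(diff(p$z) <= 0)) return("z must be strictly increasing")
  if (any(p$radius[p$defined] < 0, na.rm = TRUE)) return("radii must be >= 0")
  TRUE
})

#' Rotation/tilt change of a helix between two states
#'
#' Signed in-plane rotation (positive = clockwise viewed from the
#' intracellular side, i.e. positive about the extracellular-pointing +z)
#' and tilt change (positive = C-terminal end tilting up, extracellular) of
#' a helix after superposing the two states on a shared scaffold.
#'
#' @slot rotationDeg signed degrees, |rotation| <= 180.
#' @slot tiltChangeDeg signed degrees.
#' @slot rmsd scaffold superposition RMSD (nm).
#' @slot axis1,axis2 unit 3-vectors: helix axes (N to C) of the two states
#'   in the state-1 frame.
#' @export
setClass("HelixStatePair",
         slots = c(rotationDeg = "numeric", tiltChangeDeg = "numeric",
                   rmsd = "numeric", axis1 = "numeric", axis2 = "numeric"))

setValidity("HelixStatePair", function(object) {
  if (abs(object@rotationDeg) > 180 + 1e-9)
    return("|rotation| must be <= 180 degrees")
  if (object@rmsd < 0) return("RMSD must be >= 0")
  TRUE
})
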