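# Accessor and show methods.

#' @rdname MolecularStructure-class
#' @export
setMethod("atoms", "MolecularStructure", function(x) x@atoms)

#' @rdname MolecularStructure-class
#' @export
setMethod("nAtoms", "MolecularStructure", function(x) nrow(x@atoms))

#' @rdname FrameSequence-class
#' @export
setMethod("nFrames", "FrameSequence", function(x) dim(x@coords)[3])

#' @rdname FrameSequence-class
#' @export
setMethod("frameTimes", "FrameSequence", function(x) x@times)

#' @rdname FrameSequence-class
#' @export
setMethod("framePositions", "FrameSequence", function(x, i) {
  if (i < 1L || i > dim(x@coords)[3]) stop("frame index out of range")
  x@coords[, , i, drop = TRUE]
})

#' @rdname PairForceTable-class
#' @export
setMethod("forceEntries", "PairForceTable", function(x) x@entries)

#' @rdname NetForceTable-class
#' @export
setMethod("forceEntries", "NetForceTable", function(x) x@entries)

#' @rdname ElasticityFit-class
#' @export
setMethod("fitEstimate", "ElasticityFit", function(x) x@estimate)

#' @rdname ElasticityFit-class
#' @export
setMethod("fitStderr", "ElasticityFit", function(x) x@stderr)

#' @rdname CorrelationGrid-class
#' @export
setMethod("pccMatrix", "CorrelationGrid", function(x) x@pcc)

#' @rdname PoreProfile-class
#' @export
setMethod("poreSamples", "PoreProfile", function(x) x@profile)

setMethod("show", "MolecularStructure", function(object) {
  a <- object@atoms
  cat("MolecularStructure:", nrow(a), "atoms,",
      length(unique(a$chain)), "chain(s),",
      nrow(unique(a[c("chain", "resid")])), "residues\n")
})

setMethod("show", "FrameSequence", function(object) {
  cat("FrameSequence:", dim(object@coords)[3], "frames x",
      dim(object@coords)[1], "atoms; t =",
      object@times[1], "..", object@times[length(object@times)], "ps\n")
})

setMethod("show", "PairForceTable", function(object) {
  e <- object@entries
  cat("PairForceTable:", nrow(unique(e[c("chain_i", "resid_i",
                                          "chain_j", "resid_j")])),
      "residue pairs,", object@nframes, "frames, classes:",
      paste(sort(unique(e$class)), collapse = "/"), "\n")
})

setMethod("show", "NetForceTable", function(object) {
  e <- object@entries
  cat("NetForceTable:", nrow(unique(e[c("chain_i", "resid_i",
                                         "chain_j", "resid_j")])),
      "residue pairs (", object@nForced, "forced /", object@nFree,
      "free frames )\n")
})

setMethod("show", "ElasticityFit", function(object) {
  lab <- if (object@kind == "torsion") "c [kJ/mol/rad]" else "k_ct [nm/rad]"
  cat(sprintf("ElasticityFit (%s): %s = %.4g +/- %.3g, n = %d\n",
              object@kind, lab, object@estimate, object@stderr, object@n))
  if (object@kind == "compression-twist" && object@extensionCoupled)
    cat("  note: extension-coupled (bundle lengthens with twist)\n")
})

setMethod("show", "CorrelationGrid", function(object) {
  cat("CorrelationGrid:", nrow(object@pcc), "x", ncol(object@pcc),
      "unit pairs;", sum(is.finite(object@pcc)), "defined entries\n")
})

setMethod("show", "PoreProfile", function(object) {
  p <- object@profile
  ok <- p$defined
  cat("PoreProfile:", nrow(p), "slices; min radius",
      if (any(ok)) sprintf("%.3f nm at z = %.2f nm",
                           min(p$radius[ok]),
                           p$z[ok][which.min(p$radius[ok])]) else "undefined",
      "\n")
})

setMethod("show", "HelixStatePair", function(object) {
  cat(sprintf(paste0("HelixStatePair: rotation %+.2f deg ",
                     "(clockwise-from-intracellular positive), ",
                     "tilt change %+.2f deg, scaffold RMSD %.4f nm\n"),
              object@rotationDeg, object@tiltChangeDeg, object@rmsd))
})
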