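#' @rdname MolecularStructure-class
#' @param x,object a ChannelMech S4 object.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname MolecularStructure-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname FrameSequence-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameSequence-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname FrameSequence-class
#' @param i frame index.
#' @export
setGeneric("framePositions", function(x, i) standardGeneric("framePositions"))

#' @rdname PairForceTable-class
#' @export
setGeneric("forceEntries", function(x) standardGeneric("forceEntries"))

#' @rdname ElasticityFit-class
#' @export
setGeneric("fitEstimate", function(x) standardGeneric("fitEstimate"))

#' @rdname ElasticityFit-class
#' @export
setGeneric("fitStderr", function(x) standardGeneric("fitStderr"))

#' @rdname CorrelationGrid-class
#' @export
setGeneric("pccMatrix", function(x) standardGeneric("pccMatrix"))

#' @rdname PoreProfile-class
#' @export
setGeneric("poreSamples", function(x) standardGeneric("poreSamples"))
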