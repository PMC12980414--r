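#' @rdname coords
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname nAtoms
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname chains
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' @rdname extractChain
#' @export
setGeneric("extractChain", function(x, chain) standardGeneric("extractChain"))

#' @rdname nFrames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname frames
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname energies
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' @rdname contacts
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @rdname qValues
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname intensities
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname uncertainties
#' @export
setGeneric("uncertainties", function(x) standardGeneric("uncertainties"))

#' @rdname representatives
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
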