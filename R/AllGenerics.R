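#' @rdname MSRun
#' @param object,x an object.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname MSRun
#' @export
setGeneric("rtime", function(object) standardGeneric("rtime"))

#' @rdname MSRun
#' @export
setGeneric("peaksData", function(object) standardGeneric("peaksData"))

#' @rdname MSRun
#' @export
setGeneric("gradientLength", function(object) standardGeneric("gradientLength"))

#' @rdname MSRun
#' @export
setGeneric("nScans", function(object) standardGeneric("nScans"))

#' @rdname MarkerPanel
#' @export
setGeneric("markerTable", function(object) standardGeneric("markerTable"))

#' @rdname XICTrace
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
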