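#' Accessor generics
#'
#' Small accessor generics for the package's S4 result objects, following the
#' usual accessor-over-slot convention.
#'
#' @param x An object of the documented class.
#' @return The slot value (see the class documentation for units).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spacer", function(x) standardGeneric("spacer"))

#' @rdname accessors
#' @export
setGeneric("spacerLength", function(x) standardGeneric("spacerLength"))

#' @rdname accessors
#' @export
setGeneric("toeholdDirection", function(x) standardGeneric("toeholdDirection"))

#' @rdname accessors
#' @export
setGeneric("toeholdLengthF", function(x) standardGeneric("toeholdLengthF"))

#' @rdname accessors
#' @export
setGeneric("toeholdLengthR", function(x) standardGeneric("toeholdLengthR"))

#' @rdname accessors
#' @export
setGeneric("bmLength", function(x) standardGeneric("bmLength"))

#' @rdname accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))

#' @rdname accessors
#' @export
setGeneric("speciesMatrix", function(x) standardGeneric("speciesMatrix"))

#' @rdname accessors
#' @export
setGeneric("fluorValues", function(x) standardGeneric("fluorValues"))

#' @rdname accessors
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname accessors
#' @export
setGeneric("mCl", function(x) standardGeneric("mCl"))

#' @rdname accessors
#' @export
setGeneric("mUcl", function(x) standardGeneric("mUcl"))

#' @rdname accessors
#' @export
setGeneric("kCat", function(x) standardGeneric("kCat"))

#' @rdname accessors
#' @export
setGeneric("kM", function(x) standardGeneric("kM"))

#' @rdname accessors
#' @export
setGeneric("kcatOverKM", function(x) standardGeneric("kcatOverKM"))

#' @rdname accessors
#' @export
setGeneric("dfValue", function(x) standardGeneric("dfValue"))

#' @rdname accessors
#' @export
setGeneric("medianDfValue", function(x) standardGeneric("medianDfValue"))

#' Thermal energy RT of an energy model
#'
#' @param x An [EnergyModel-class].
#' @return RT in kcal/mol (0.0019872 kcal/mol/K times the model temperature).
#' @export
setGeneric("rt", function(x) standardGeneric("rt"))
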