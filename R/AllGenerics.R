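#' @rdname GenotypeMatrix-class
#' @param x a `GenotypeMatrix` (or other object with individuals).
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nLoc", function(x) standardGeneric("nLoc"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("individualNames", function(x) standardGeneric("individualNames"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname GenotypeMatrix-class
#' @param locus locus name or index.
#' @export
setGeneric("alleleCalls", function(x, locus) standardGeneric("alleleCalls"))

#' @rdname HaplotypeSet-class
#' @param x a `HaplotypeSet`.
#' @export
setGeneric("haplotypeFrequencies",
           function(x) standardGeneric("haplotypeFrequencies"))

#' @rdname HaplotypeSet-class
#' @export
setGeneric("haplotypeAssignment",
           function(x) standardGeneric("haplotypeAssignment"))

#' @rdname HaplotypeSet-class
#' @export
setGeneric("haplotypeSequences",
           function(x) standardGeneric("haplotypeSequences"))

#' @rdname FloweringSchedule-class
#' @param x a `FloweringSchedule`.
#' @export
setGeneric("scheduleValues", function(x) standardGeneric("scheduleValues"))

#' @rdname FloweringSchedule-class
#' @export
setGeneric("censusDates", function(x) standardGeneric("censusDates"))

#' @rdname FloweringSchedule-class
#' @export
setGeneric("lineageLabels", function(x) standardGeneric("lineageLabels"))

#' Posterior membership matrix of a clustering or hybrid-class result
#' @param x a `ClusterResult` or `HybridPosterior`.
#' @export
setGeneric("posteriorMatrix", function(x) standardGeneric("posteriorMatrix"))

#' @rdname ClusterResult-class
#' @param x a `ClusterResult`.
#' @export
setGeneric("coassignmentMatrix",
           function(x) standardGeneric("coassignmentMatrix"))

#' @rdname ParsimonyNetwork-class
#' @param x a `ParsimonyNetwork`.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname ParsimonyNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname ParsimonyNetwork-class
#' @export
setGeneric("networkLinks", function(x) standardGeneric("networkLinks"))

#' @rdname ParsimonyNetwork-class
#' @export
setGeneric("networkComponents",
           function(x) standardGeneric("networkComponents"))
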