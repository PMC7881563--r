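#' @rdname AssociationSet
#' @param x an object.
#' @export
setGeneric("assoc", function(x) standardGeneric("assoc"))

#' @rdname AssociationSet
#' @export
setGeneric("diseaseIDs", function(x) standardGeneric("diseaseIDs"))

#' @rdname AssociationSet
#' @export
setGeneric("microbeIDs", function(x) standardGeneric("microbeIDs"))

#' @rdname AssociationSet
#' @export
setGeneric("nDiseases", function(x) standardGeneric("nDiseases"))

#' @rdname AssociationSet
#' @export
setGeneric("nMicrobes", function(x) standardGeneric("nMicrobes"))

#' @rdname SimilarityMatrix
#' @param x a `SimilarityMatrix`.
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' @rdname SimilarityMatrix
#' @export
setGeneric("simAxis", function(x) standardGeneric("simAxis"))

#' @rdname SimilarityMatrix
#' @export
setGeneric("simKind", function(x) standardGeneric("simKind"))

#' @rdname ScoreMatrix
#' @param x a `ScoreMatrix`.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname ScoreMatrix
#' @export
setGeneric("scoreBranch", function(x) standardGeneric("scoreBranch"))

#' @rdname CVResult
#' @param x a `CVResult`.
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname CVResult
#' @export
setGeneric("aucSD", function(x) standardGeneric("aucSD"))

#' @rdname CVResult
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname CVResult
#' @export
setGeneric("perRoundRanks", function(x) standardGeneric("perRoundRanks"))

#' @rdname SyntheticAssociations
#' @param x a `SyntheticAssociations`.
#' @export
setGeneric("observed", function(x) standardGeneric("observed"))

#' @rdname SyntheticAssociations
#' @export
setGeneric("hiddenPositives", function(x) standardGeneric("hiddenPositives"))

#' @rdname SyntheticAssociations
#' @export
setGeneric("blockAssignments", function(x) standardGeneric("blockAssignments"))
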