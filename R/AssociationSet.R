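#' Construct an AssociationSet from a labelled binary matrix
#'
#' @param assoc numeric matrix of 0/1 entries; rows are diseases,
#'   columns are microbes. Must carry unique row and column names.
#'
#' @return an [AssociationSet-class] object.
#' @examples
#' A <- matrix(c(1, 1, 1, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("d1", "d2"), c("m1", "m2")))
#' AssociationSet(A)
#' @export
AssociationSet <- function(assoc) {
    storage.mode(assoc) <- "double"
    new("AssociationSet", assoc = assoc)
}

#' @rdname AssociationSet
#' @export
setMethod("assoc", "AssociationSet", function(x) x@assoc)

#' @rdname AssociationSet
#' @export
setMethod("diseaseIDs", "AssociationSet", function(x) rownames(x@assoc))

#' @rdname AssociationSet
#' @export
setMethod("microbeIDs", "AssociationSet", function(x) colnames(x@assoc))

#' @rdname AssociationSet
#' @export
setMethod("nDiseases", "AssociationSet", function(x) nrow(x@assoc))

#' @rdname AssociationSet
#' @export
setMethod("nMicrobes", "AssociationSet", function(x) ncol(x@assoc))

setMethod("show", "AssociationSet", function(object) {
    A <- object@assoc
    cat(sprintf("AssociationSet: %d diseases x %d microbes, %d known associations (density %.4f)\n",
                nrow(A), ncol(A), sum(A), mean(A)))
    cat("diseases:", .ellipsize(rownames(A)), "\n")
    cat("microbes:", .ellipsize(colnames(A)), "\n")
})

.ellipsize <- function(ids, n = 4L) {
    if (length(ids) <= n) paste(ids, collapse = ", ")
    else paste0(paste(ids[seq_len(n)], collapse = ", "), ", ... (", length(ids), ")")
}

setMethod("show", "SimilarityMatrix", function(object) {
    cat(sprintf("SimilarityMatrix: %s %s, %d x %d, off-diagonal range [%.4f, %.4f]\n",
                object@axis, object@kind, nrow(object@values), ncol(object@values),
                min(object@values), max(object@values[row(object@values) !=
                                                      col(object@values)], -Inf)))
})

#' @rdname SimilarityMatrix
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) x@values)

#' @rdname SimilarityMatrix
#' @export
setMethod("simAxis", "SimilarityMatrix", function(x) x@axis)

#' @rdname SimilarityMatrix
#' @export
setMethod("simKind", "SimilarityMatrix", function(x) x@kind)

#' @rdname ScoreMatrix
#' @export
setMethod("scores", "ScoreMatrix", function(x) x@values)

#' @rdname ScoreMatrix
#' @export
setMethod("scoreBranch", "ScoreMatrix", function(x) x@branch)

setMethod("show", "ScoreMatrix", function(object) {
    cat(sprintf("ScoreMatrix (%s): %d x %d, score range [%.4g, %.4g]\n",
                object@branch, nrow(object@values), ncol(object@values),
                min(object@values), max(object@values)))
})

#' @rdname CVResult
#' @export
setMethod("auc", "CVResult", function(x) x@auc)

#' @rdname CVResult
#' @export
setMethod("aucSD", "CVResult", function(x) x@aucSD)

#' @rdname CVResult
#' @export
setMethod("rocPoints", "CVResult", function(x) x@rocPoints)

#' @rdname CVResult
#' @export
setMethod("perRoundRanks", "CVResult", function(x) x@perRoundRanks)

setMethod("show", "CVResult", function(object) {
    if (is.na(object@aucSD))
        cat(sprintf("CVResult: AUC = %.4f\n", object@auc))
    else
        cat(sprintf("CVResult: AUC = %.4f +/- %.4f\n", object@auc, object@aucSD))
    if (nrow(object@perRoundRanks))
        cat(sprintf("  %d hold-out rounds, median rank %g of %d candidates\n",
                    nrow(object@perRoundRanks),
                    stats::median(object@perRoundRanks$rank),
                    object@perRoundRanks$candidateCount[1L]))
})

#' @rdname SyntheticAssociations
#' @export
setMethod("observed", "SyntheticAssociations", function(x) x@observed)

#' @rdname SyntheticAssociations
#' @export
setMethod("hiddenPositives", "SyntheticAssociations", function(x) x@hiddenPositives)

#' @rdname SyntheticAssociations
#' @export
setMethod("blockAssignments", "SyntheticAssociations",
    function(x) list(disease = x@diseaseBlocks, microbe = x@microbeBlocks))

setMethod("show", "SyntheticAssociations", function(object) {
    cat("SyntheticAssociations\n")
    show(object@observed)
    cat(sprintf("  hidden positives: %d; blocks: %d\n",
                nrow(object@hiddenPositives),
                length(unique(c(object@diseaseBlocks, object@microbeBlocks)))))
})
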