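#' AssociationSet: a labelled binary disease x microbe association matrix
#'
#' Container for a bipartite association network. Rows are diseases,
#' columns are microbes, and `assoc(x)[i, j] == 1` records a known
#' association between disease `i` and microbe `j`. Row and column names
#' are the (unique, case-sensitive) entity identifiers; their order is
#' stable and meaningful (first appearance in the source file for data
#' read from disk).
#'
#' @slot assoc numeric matrix of 0/1 entries with unique, non-empty
#'   dimnames.
#'
#' @seealso [AssociationSet()] for the user-facing constructor,
#'   [readPairList()] and [readDenseMatrix()] for file input.
#' @exportClass AssociationSet
setClass("AssociationSet", representation(assoc = "matrix"))

setValidity("AssociationSet", function(object) {
    A <- object@assoc
    msg <- character()
    if (!is.numeric(A))
        msg <- c(msg, "association matrix must be numeric")
    if (nrow(A) < 1L || ncol(A) < 1L)
        msg <- c(msg, "need at least one disease and one microbe")
    if (is.numeric(A) && !all(A %in% c(0, 1)))
        msg <- c(msg, "association matrix must contain only 0/1 entries")
    dn <- dimnames(A)
    if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]]))
        msg <- c(msg, "disease and microbe identifiers are required as dimnames")
    else {
        if (anyDuplicated(dn[[1L]]))
            msg <- c(msg, "duplicated disease identifiers")
        if (anyDuplicated(dn[[2L]]))
            msg <- c(msg, "duplicated microbe identifiers")
        if (any(!nzchar(c(dn[[1L]], dn[[2L]]))))
            msg <- c(msg, "empty identifier")
    }
    if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: symmetric entity-by-entity similarity
#'
#' A symmetric similarity matrix over the diseases or the microbes of an
#' [AssociationSet], tagged with the axis it describes and the measure
#' used. The diagonal is exactly 1; GIP (Gaussian interaction profile)
#' values lie in (0, 1], HIP (Hamming interaction profile) values in
#' \[0, 1\].
#'
#' @slot values symmetric numeric matrix with unit diagonal and entity
#'   identifiers as dimnames.
#' @slot axis `"microbe"` or `"disease"`.
#' @slot kind `"GIP"` or `"HIP"`.
#'
#' @seealso [gipSimilarity()], [hipSimilarity()]
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
    representation(values = "matrix", axis = "character", kind = "character"))

setValidity("SimilarityMatrix", function(object) {
    S <- object@values
    msg <- character()
    if (!identical(dim(S)[1L], dim(S)[2L]))
        msg <- c(msg, "similarity matrix must be square")
    else {
        if (!isTRUE(all.equal(S, t(S), tolerance = 0, check.attributes = FALSE)))
            msg <- c(msg, "similarity matrix must be exactly symmetric")
        if (any(diag(S) != 1))
            msg <- c(msg, "diagonal entries must equal 1")
    }
    if (!object@axis %in% c("microbe", "disease"))
        msg <- c(msg, "axis must be 'microbe' or 'disease'")
    if (!object@kind %in% c("GIP", "HIP"))
        msg <- c(msg, "kind must be 'GIP' or 'HIP'")
    if (identical(object@kind, "GIP") && (any(S <= 0) || any(S > 1)))
        msg <- c(msg, "GIP similarities must lie in (0, 1]")
    if (identical(object@kind, "HIP") && (any(S < 0) || any(S > 1)))
        msg <- c(msg, "HIP similarities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' KRLSParams: model parameters for Kronecker RLS prediction
#'
#' @slot sigmaG positive regularisation strength for the Gaussian
#'   (GIP) branch. Default 30.
#' @slot sigmaH positive regularisation strength for the Hamming (HIP)
#'   branch. Default 30.
#' @slot w fusion weight in \[0, 1\] given to the Gaussian branch when
#'   combining the two score matrices. Default 0.8.
#' @slot sigmaPrimeM,sigmaPrimeD positive GIP bandwidth trade-off
#'   parameters for the microbe and disease axes. Default 1.
#' @slot denomTol positive tolerance below which an eigenvalue-product
#'   denominator is treated as singular. Default 1e-10.
#'
#' @seealso [krlsParams()]
#' @exportClass KRLSParams
setClass("KRLSParams",
    representation(sigmaG = "numeric", sigmaH = "numeric", w = "numeric",
                   sigmaPrimeM = "numeric", sigmaPrimeD = "numeric",
                   denomTol = "numeric"))

setValidity("KRLSParams", function(object) {
    msg <- character()
    one_pos <- function(x, nm) {
        if (length(x) != 1L || !is.finite(x) || x <= 0)
            sprintf("%s must be a single positive number", nm)
        else character()
    }
    msg <- c(msg, one_pos(object@sigmaG, "sigmaG"),
             one_pos(object@sigmaH, "sigmaH"),
             one_pos(object@sigmaPrimeM, "sigmaPrimeM"),
             one_pos(object@sigmaPrimeD, "sigmaPrimeD"),
             one_pos(object@denomTol, "denomTol"))
    if (length(object@w) != 1L || !is.finite(object@w) ||
        object@w < 0 || object@w > 1)
        msg <- c(msg, "w must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' ScoreMatrix: real-valued disease x microbe prediction scores
#'
#' @slot values numeric nd x nm matrix of finite prediction scores,
#'   dimnames matching the training [AssociationSet].
#' @slot branch `"gaussian"`, `"hamming"` or `"fused"`.
#'
#' @seealso [predictAssociations()], [fuseScores()]
#' @exportClass ScoreMatrix
setClass("ScoreMatrix", representation(values = "matrix", branch = "character"))

setValidity("ScoreMatrix", function(object) {
    msg <- character()
    if (!is.numeric(object@values) || any(!is.finite(object@values)))
        msg <- c(msg, "scores must be finite numbers")
    if (!object@branch %in% c("gaussian", "hamming", "fused"))
        msg <- c(msg, "branch must be 'gaussian', 'hamming' or 'fused'")
    if (length(msg)) msg else TRUE
})

#' CVResult: outcome of a cross-validation protocol
#'
#' @slot auc area under the ROC curve, in \[0, 1\].
#' @slot aucSD standard deviation of the per-repeat AUC (repeated k-fold
#'   only; `NA` otherwise).
#' @slot rocPoints data.frame with columns `fpr`, `tpr`; starts at
#'   (0, 0), ends at (1, 1), monotone nondecreasing.
#' @slot perRoundRanks data.frame of per-round hold-out ranks (global
#'   LOOCV only; zero rows otherwise) with columns `diseaseID`,
#'   `microbeID`, `rank`, `candidateCount`, `roundAUC`.
#'
#' @seealso [globalLOOCV()], [kfoldCV()], [rocAUC()]
#' @exportClass CVResult
setClass("CVResult",
    representation(auc = "numeric", aucSD = "numeric",
                   rocPoints = "data.frame", perRoundRanks = "data.frame"))

setValidity("CVResult", function(object) {
    msg <- character()
    if (length(object@auc) != 1L || is.na(object@auc) ||
        object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must be a single number in [0, 1]")
    rp <- object@rocPoints
    if (!all(c("fpr", "tpr") %in% names(rp)))
        msg <- c(msg, "rocPoints needs fpr and tpr columns")
    else if (nrow(rp)) {
        if (rp$fpr[1L] != 0 || rp$tpr[1L] != 0 ||
            rp$fpr[nrow(rp)] != 1 || rp$tpr[nrow(rp)] != 1)
            msg <- c(msg, "ROC curve must run from (0,0) to (1,1)")
        if (is.unsorted(rp$fpr) || is.unsorted(rp$tpr))
            msg <- c(msg, "ROC curve must be monotone nondecreasing")
    }
    if (length(msg)) msg else TRUE
})

#' SyntheticAssociations: a simulated dataset with planted ground truth
#'
#' Output of [simulateAssociations()]: the observed association set
#' (with a fraction of true positives withheld), the withheld pairs, and
#' the latent block assignment of every entity.
#'
#' @slot observed the observed [AssociationSet] (withheld positives set
#'   to 0).
#' @slot hiddenPositives data.frame with columns `diseaseID`,
#'   `microbeID`: true associations hidden from the observed matrix.
#' @slot diseaseBlocks,microbeBlocks integer block labels, named by
#'   entity identifier.
#'
#' @seealso [simulateAssociations()], [recoveryAUC()]
#' @exportClass SyntheticAssociations
setClass("SyntheticAssociations",
    representation(observed = "AssociationSet",
                   hiddenPositives = "data.frame",
                   diseaseBlocks = "integer", microbeBlocks = "integer"))

setValidity("SyntheticAssociations", function(object) {
    msg <- character()
    hp <- object@hiddenPositives
    if (!all(c("diseaseID", "microbeID") %in% names(hp)))
        msg <- c(msg, "hiddenPositives needs diseaseID and microbeID columns")
    else if (nrow(hp)) {
        A <- object@observed@assoc
        ok <- hp$diseaseID %in% rownames(A) & hp$microbeID %in% colnames(A)
        if (!all(ok))
            msg <- c(msg, "hidden positives refer to unknown entities")
        else if (any(A[cbind(hp$diseaseID, hp$microbeID)] != 0))
            msg <- c(msg, "hidden positives must be 0 in the observed matrix")
    }
    if (length(msg)) msg else TRUE
})
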