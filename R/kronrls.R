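#' Model parameters for Kronecker RLS
#'
#' Bundles the tunable parameters of the predictor. The defaults are
#' the values at which the method's cross-validated performance
#' plateaus and which are used throughout the package: regularisation
#' `sigmaG = sigmaH = 30`, fusion weight `w = 0.8` (Gaussian branch
#' favoured), GIP bandwidth trade-offs `sigmaPrimeM = sigmaPrimeD = 1`.
#'
#' @param sigmaG,sigmaH positive regularisation strengths for the
#'   Gaussian- and Hamming-kernel branches.
#' @param w fusion weight in \[0, 1\] for the Gaussian branch.
#' @param sigmaPrimeM,sigmaPrimeD positive GIP bandwidth trade-offs.
#' @param denomTol positive tolerance guarding the eigenvalue-product
#'   denominators of the closed-form solver.
#' @return a [KRLSParams-class] object.
#' @examples
#' krlsParams()
#' krlsParams(sigmaG = 10, w = 0.5)
#' @export
krlsParams <- function(sigmaG = 30, sigmaH = 30, w = 0.8,
                       sigmaPrimeM = 1, sigmaPrimeD = 1, denomTol = 1e-10) {
    new("KRLSParams", sigmaG = sigmaG, sigmaH = sigmaH, w = w,
        sigmaPrimeM = sigmaPrimeM, sigmaPrimeD = sigmaPrimeD,
        denomTol = denomTol)
}

setMethod("show", "KRLSParams", function(object) {
    cat(sprintf("KRLSParams: sigmaG = %g, sigmaH = %g, w = %g, sigmaPrime(m, d) = (%g, %g), denomTol = %g\n",
                object@sigmaG, object@sigmaH, object@w,
                object@sigmaPrimeM, object@sigmaPrimeD, object@denomTol))
})

.simMat <- function(S) if (is(S, "SimilarityMatrix")) S@values else S

# symmetric eigendecomposition; symmetrize first to wash out fp noise
.symEigen <- function(S) {
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    list(vectors = e$vectors, values = e$values)
}

#' Explicit Kronecker pairwise similarity (oracle path)
#'
#' Materialises the pairwise-kernel matrix `K = S_m %x% S_d` over all
#' `N = nd * nm` (disease, microbe) pairs under column-major
#' vectorisation of nd x nm matrices, so that
#' `K %*% as.vector(Y) == as.vector(S_d %*% Y %*% t(S_m))`. Intended
#' for small instances and oracle testing only; production prediction
#' uses [krlsSolveEigen()], which never forms `K`.
#'
#' @param Sm microbe [SimilarityMatrix-class] (or nm x nm matrix).
#' @param Sd disease [SimilarityMatrix-class] (or nd x nd matrix).
#' @param maxPairs refuse to materialise more than this many pairs
#'   (default 4000).
#' @return the N x N pairwise similarity matrix.
#' @export
kroneckerSimilarity <- function(Sm, Sd, maxPairs = 4000) {
    Sm <- .simMat(Sm); Sd <- .simMat(Sd)
    N <- nrow(Sm) * nrow(Sd)
    if (N > maxPairs)
        stop(sprintf("refusing to materialise a %d x %d pairwise kernel; use krlsSolveEigen() instead", N, N))
    kronecker(Sm, Sd)
}

#' Direct regularised least squares solve (oracle path)
#'
#' Solves `vec(F) = K (K + sigma I)^{-1} vec(Y)` by dense linear
#' algebra on the explicit pairwise kernel. This is the brute-force
#' reference for [krlsSolveEigen()] and is only practical for small
#' problems.
#'
#' @param K symmetric N x N pairwise kernel (N = nd * nm,
#'   column-major pair order).
#' @param Y binary nd x nm training matrix.
#' @param sigma positive regularisation strength.
#' @return a [ScoreMatrix-class] (branch `"fused"` is not implied; the
#'   branch tag is `"gaussian"` by convention and irrelevant here).
#' @export
krlsSolveDirect <- function(K, Y, sigma) {
    stopifnot(is.matrix(K), nrow(K) == ncol(K), is.matrix(Y),
              length(Y) == nrow(K), is.numeric(sigma), sigma > 0)
    M <- K + diag(sigma, nrow(K))
    if (rcond(M) < 1e-14)
        stop("K + sigma*I is numerically singular; increase sigma")
    v <- K %*% solve(M, as.vector(Y))
    F <- matrix(v, nrow(Y), ncol(Y), dimnames = dimnames(Y))
    new("ScoreMatrix", values = F, branch = "gaussian")
}

#' Kronecker RLS closed-form solve via per-axis eigendecomposition
#'
#' Computes the same scores as [krlsSolveDirect()] on
#' `K = S_m %x% S_d` without forming any N x N matrix: with
#' `S_m = V_m L_m V_m'` and `S_d = V_d L_d V_d'`, transform
#' `Z = V_d' Y V_m`, shrink each entry by the filter factor
#' `l_d * l_m / (l_d * l_m + sigma)`, and map back,
#' `F = V_d X V_m'`. Cost is two small eigendecompositions plus
#' O(nd * nm) work.
#'
#' HIP similarity matrices need not be positive semidefinite, so a
#' denominator `l_d * l_m + sigma` can in principle approach zero; any
#' denominator with absolute value at most `denomTol` aborts with the
#' offending eigenvalue pair.
#'
#' @param Sm,Sd microbe and disease similarities
#'   ([SimilarityMatrix-class] or plain symmetric matrices).
#' @param Y binary nd x nm training matrix.
#' @param sigma positive regularisation strength.
#' @param denomTol positive singularity guard (default 1e-10).
#' @param branch branch tag for the result.
#' @return a [ScoreMatrix-class].
#' @export
krlsSolveEigen <- function(Sm, Sd, Y, sigma, denomTol = 1e-10,
                           branch = c("gaussian", "hamming")) {
    branch <- match.arg(branch)
    Sm <- .simMat(Sm); Sd <- .simMat(Sd)
    stopifnot(is.matrix(Y), nrow(Y) == nrow(Sd), ncol(Y) == nrow(Sm),
              is.numeric(sigma), length(sigma) == 1L, sigma > 0)
    em <- .symEigen(Sm)
    ed <- .symEigen(Sd)
    P <- outer(ed$values, em$values)          # nd x nm eigenvalue products
    denom <- P + sigma
    if (min(abs(denom)) <= denomTol) {
        bad <- which(abs(denom) == min(abs(denom)), arr.ind = TRUE)[1L, ]
        stop(sprintf(paste0("singular filter factor: eigenvalue pair (disease %g,",
                            " microbe %g) gives |product + sigma| = %.3g <= %g;",
                            " increase sigma"),
                     ed$values[bad[1L]], em$values[bad[2L]],
                     abs(denom[bad[1L], bad[2L]]), denomTol))
    }
    Z <- crossprod(ed$vectors, Y) %*% em$vectors
    X <- (P / denom) * Z
    F <- ed$vectors %*% X %*% t(em$vectors)
    dimnames(F) <- dimnames(Y)
    new("ScoreMatrix", values = F, branch = branch)
}

#' Fuse the Gaussian- and Hamming-branch score matrices
#'
#' `F = w * F_G + (1 - w) * F_H`.
#'
#' @param FG,FH [ScoreMatrix-class] objects of identical shape.
#' @param w fusion weight in \[0, 1\] for the Gaussian branch.
#' @return a [ScoreMatrix-class] with `branch = "fused"`.
#' @export
fuseScores <- function(FG, FH, w = 0.8) {
    G <- if (is(FG, "ScoreMatrix")) scores(FG) else FG
    H <- if (is(FH, "ScoreMatrix")) scores(FH) else FH
    if (!identical(dim(G), dim(H)))
        stop("score matrices have different shapes")
    if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1)
        stop("w must lie in [0, 1]")
    new("ScoreMatrix", values = w * G + (1 - w) * H, branch = "fused")
}

#' Predict association scores for every disease-microbe pair
#'
#' The full prediction pipeline: compute the four interaction-profile
#' similarities (GIP and HIP, for microbes and diseases) from the
#' training matrix, solve the Kronecker RLS problem per branch via
#' [krlsSolveEigen()], and fuse the two score matrices with weight `w`.
#' Deterministic given its inputs; eigenvector sign and ordering
#' ambiguities cancel in the scores.
#'
#' @param dataset an [AssociationSet-class] (the training matrix).
#' @param params a [KRLSParams-class]; defaults via [krlsParams()].
#' @return a fused [ScoreMatrix-class] of shape nd x nm.
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("d1", "d2"), c("m1", "m2")))
#' predictAssociations(AssociationSet(A))
#' @export
predictAssociations <- function(dataset, params = krlsParams()) {
    stopifnot(is(dataset, "AssociationSet"), is(params, "KRLSParams"))
    A <- assoc(dataset)
    .predictCore(A, params)
}

# inner loop used by the CV protocols: works on the raw matrix so
# hold-out rounds avoid repeated validity checks
.predictCore <- function(A, params) {
    SGm <- gipSimilarity(A, "microbe", params@sigmaPrimeM)
    SGd <- gipSimilarity(A, "disease", params@sigmaPrimeD)
    SHm <- hipSimilarity(A, "microbe")
    SHd <- hipSimilarity(A, "disease")
    FG <- krlsSolveEigen(SGm, SGd, A, params@sigmaG, params@denomTol, "gaussian")
    FH <- krlsSolveEigen(SHm, SHd, A, params@sigmaH, params@denomTol, "hamming")
    fuseScores(FG, FH, params@w)
}
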