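## Interaction-profile similarities.
##
## An entity's interaction profile is its 0/1 slice of the association
## matrix: column j for microbe j (length nd), row i for disease i
## (length nm). Both measures below depend only on pairwise profile
## Hamming counts, which for binary vectors equal squared Euclidean
## distances; the counts are obtained exactly via integer cross
## products before any transcendental is applied.

.checkBinary <- function(A) {
    if (!is.matrix(A) || !is.numeric(A) || !all(A %in% c(0, 1)))
        stop("association matrix must be a numeric 0/1 matrix")
}

# pairwise Hamming counts between profiles along an axis, plus labels
.profileHamming <- function(A, axis) {
    G <- if (axis == "microbe") crossprod(A) else tcrossprod(A)
    n1 <- diag(G)
    D2 <- outer(n1, n1, "+") - 2 * G
    D2 <- (D2 + t(D2)) / 2
    ids <- if (axis == "microbe") colnames(A) else rownames(A)
    if (!is.null(ids)) dimnames(D2) <- list(ids, ids)
    D2
}

#' GIP kernel bandwidth from interaction profiles
#'
#' The Gaussian interaction profile (GIP) kernel bandwidth is the
#' trade-off parameter `sigmaPrime` divided by the mean squared norm of
#' the axis' interaction profiles (columns of `A` for microbes, rows
#' for diseases). For an all-zero training matrix the mean norm is 0;
#' the bandwidth then falls back to `sigmaPrime` itself, which makes
#' the kernel a well-defined all-ones matrix (all profiles coincide).
#'
#' @param A binary disease x microbe matrix (or [AssociationSet-class]).
#' @param axis `"microbe"` or `"disease"`.
#' @param sigmaPrime positive trade-off parameter (default 1).
#' @return list with elements `sigmaPrime` and `sigma` (the effective
#'   bandwidth).
#' @examples
#' gipBandwidth(diag(2), "microbe")$sigma         # unit-norm profiles -> 1
#' @export
gipBandwidth <- function(A, axis = c("microbe", "disease"), sigmaPrime = 1) {
    if (is(A, "AssociationSet")) A <- assoc(A)
    axis <- match.arg(axis)
    .checkBinary(A)
    stopifnot(is.numeric(sigmaPrime), length(sigmaPrime) == 1L, sigmaPrime > 0)
    n <- if (axis == "microbe") ncol(A) else nrow(A)
    meanNorm2 <- sum(A) / n   # binary: squared profile norm sums to total 1s
    sigma <- if (meanNorm2 == 0) sigmaPrime else sigmaPrime / meanNorm2
    list(sigmaPrime = sigmaPrime, sigma = sigma)
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' `S[i, j] = exp(-sigma * ||profile_i - profile_j||^2)` with the
#' bandwidth `sigma` from [gipBandwidth()]. Entries lie in (0, 1], the
#' diagonal is exactly 1, and symmetry is exact by construction.
#'
#' @inheritParams gipBandwidth
#' @return a [SimilarityMatrix-class] with `kind = "GIP"`.
#' @export
gipSimilarity <- function(A, axis = c("microbe", "disease"), sigmaPrime = 1) {
    if (is(A, "AssociationSet")) A <- assoc(A)
    axis <- match.arg(axis)
    bw <- gipBandwidth(A, axis, sigmaPrime)
    D2 <- .profileHamming(A, axis)
    S <- exp(-bw$sigma * D2)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    new("SimilarityMatrix", values = S, axis = axis, kind = "GIP")
}

#' Hamming interaction profile (HIP) similarity
#'
#' `S[i, j] = 1 - (# positions where the two profiles differ) / L`,
#' where `L` is the profile length (nd for microbes, nm for diseases).
#' Identical profiles score 1, complementary profiles 0.
#'
#' @inheritParams gipBandwidth
#' @return a [SimilarityMatrix-class] with `kind = "HIP"`.
#' @export
hipSimilarity <- function(A, axis = c("microbe", "disease")) {
    if (is(A, "AssociationSet")) A <- assoc(A)
    axis <- match.arg(axis)
    .checkBinary(A)
    L <- if (axis == "microbe") nrow(A) else ncol(A)
    S <- 1 - .profileHamming(A, axis) / L
    S <- (S + t(S)) / 2
    diag(S) <- 1
    new("SimilarityMatrix", values = S, axis = axis, kind = "HIP")
}
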