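# Shared fixtures and independent brute-force oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# random labelled binary matrix
rbinMat <- function(nd, nm, p = 0.4, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    matrix(rbinom(nd * nm, 1, p), nd, nm,
           dimnames = list(sprintf("d%d", seq_len(nd)),
                           sprintf("m%d", seq_len(nm))))
}

# HIP similarity by an explicit per-position loop (oracle)
bruteHIP <- function(A, axis) {
    profiles <- if (axis == "microbe") lapply(seq_len(ncol(A)), function(j) A[, j])
                else lapply(seq_len(nrow(A)), function(i) A[i, ])
    n <- length(profiles)
    L <- length(profiles[[1L]])
    S <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        mism <- 0L
        for (k in seq_len(L))
            if (profiles[[i]][k] != profiles[[j]][k]) mism <- mism + 1L
        S[i, j] <- 1 - mism / L
    }
    S
}

# AUC by counting concordant positive-negative pairs, ties worth 0.5 (oracle)
bruteAUC <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

# global LOOCV by brute force: per round, materialise both Kronecker
# kernels and solve directly (oracle for globalLOOCV)
bruteLOOCV <- function(dataset, params = krlsParams(), tieTol = 1e-9) {
    A0 <- assoc(dataset)
    pos <- which(A0 == 1)
    cand <- which(A0 == 0)
    out <- data.frame(rank = integer(length(pos)),
                      roundAUC = numeric(length(pos)))
    for (i in seq_along(pos)) {
        Atr <- A0
        Atr[pos[i]] <- 0
        KG <- kroneckerSimilarity(gipSimilarity(Atr, "microbe", params@sigmaPrimeM),
                                  gipSimilarity(Atr, "disease", params@sigmaPrimeD))
        KH <- kroneckerSimilarity(hipSimilarity(Atr, "microbe"),
                                  hipSimilarity(Atr, "disease"))
        FG <- scores(krlsSolveDirect(KG, Atr, params@sigmaG))
        FH <- scores(krlsSolveDirect(KH, Atr, params@sigmaH))
        F <- params@w * FG + (1 - params@w) * FH
        s <- F[pos[i]]; cs <- F[cand]
        nAbove <- sum(cs > s + tieTol); nTie <- sum(abs(cs - s) <= tieTol)
        out$rank[i] <- 1L + nAbove
        out$roundAUC[i] <- (length(cs) - nAbove - nTie + 0.5 * nTie) / length(cs)
    }
    out
}

# small dense-block synthetic config with strong, fast-to-recover signal
strongSynth <- function(seed = 7) {
    simulateAssociations(nd = 15, nm = 60, nBlocks = 3, pIn = 0.6,
                         pOut = 0.02, hideFraction = 0.2, seed = seed)
}

# dataset whose first-appearance order survives a pair-list round trip
toyAssoc <- function() {
    A <- matrix(c(1, 1, 0,
                  1, 0, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("d1", "d2"), c("m1", "m2", "m3")))
    AssociationSet(A)
}
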