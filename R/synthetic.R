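#' Simulate a bipartite association network with planted blocks
#'
#' Generates a binary disease x microbe association matrix from a
#' planted-block (stochastic block) model: each disease and each
#' microbe is assigned uniformly to one of `nBlocks` latent
#' communities, and an association is drawn with probability `pIn`
#' when the two entities share a block and `pOut` otherwise. A uniform
#' fraction `hideFraction` of the generated positives is then withheld
#' (flipped to 0 in the observed matrix and recorded as ground truth),
#' giving recovery benchmarks an answer key. Co-association blocks are
#' exactly the structure interaction-profile similarities can exploit,
#' so the generator probes the method's own modelling assumption.
#'
#' The defaults emulate the scale of the curated human microbe-disease
#' benchmark the method targets: 39 diseases, 292 microbes, and an
#' expected positive count in the mid-hundreds
#' (`nd * nm * (pIn/nBlocks + pOut * (nBlocks - 1)/nBlocks)`, about 480
#' before hiding).
#'
#' @param nd,nm numbers of diseases and microbes (defaults 39, 292).
#' @param nBlocks number of latent blocks (default 8; at most
#'   `min(nd, nm)`).
#' @param pIn within-block association probability (default 0.30).
#' @param pOut background association probability (default 0.005);
#'   must not exceed `pIn`.
#' @param hideFraction fraction of positives withheld as ground truth
#'   (default 0.2; in \[0, 1)).
#' @param seed integer seed; identical arguments give identical
#'   datasets, and the caller's RNG state is untouched.
#' @return a [SyntheticAssociations-class].
#' @examples
#' synth <- simulateAssociations(nd = 10, nm = 30, nBlocks = 3, seed = 1)
#' synth
#' @export
simulateAssociations <- function(nd = 39, nm = 292, nBlocks = 8,
                                 pIn = 0.30, pOut = 0.005,
                                 hideFraction = 0.2, seed = 1) {
    stopifnot(nd >= 1, nm >= 1, nBlocks >= 1, nBlocks <= min(nd, nm),
              pIn >= 0, pIn <= 1, pOut >= 0, pOut <= pIn,
              hideFraction >= 0, hideFraction < 1)
    dids <- sprintf("D%03d", seq_len(nd))
    mids <- sprintf("M%03d", seq_len(nm))
    .withSeed(seed, {
        db <- sample.int(nBlocks, nd, replace = TRUE)
        mb <- sample.int(nBlocks, nm, replace = TRUE)
        p <- ifelse(outer(db, mb, "=="), pIn, pOut)
        A <- matrix(as.numeric(matrix(stats::runif(nd * nm), nd, nm) < p),
                    nd, nm, dimnames = list(dids, mids))
        pos <- which(A == 1)
        nHide <- floor(hideFraction * length(pos))
        hidden <- if (nHide > 0L) sort(sample(pos, nHide)) else integer()
        A[hidden] <- 0
        hp <- data.frame(diseaseID = dids[(hidden - 1L) %% nd + 1L],
                         microbeID = mids[(hidden - 1L) %/% nd + 1L],
                         stringsAsFactors = FALSE)
        names(db) <- dids; names(mb) <- mids
        new("SyntheticAssociations", observed = AssociationSet(A),
            hiddenPositives = hp, diseaseBlocks = db, microbeBlocks = mb)
    })
}

#' Recovery AUC on a synthetic dataset
#'
#' Fits the predictor to the observed matrix and scores its ability to
#' recover the withheld true associations: AUC with positives = hidden
#' pairs and negatives = pairs that are 0 in both the observed matrix
#' and the ground truth.
#'
#' @param synth a [SyntheticAssociations-class] with at least one
#'   hidden positive.
#' @param params a [KRLSParams-class].
#' @return the recovery AUC (single number in \[0, 1\]).
#' @export
recoveryAUC <- function(synth, params = krlsParams()) {
    stopifnot(is(synth, "SyntheticAssociations"))
    hp <- hiddenPositives(synth)
    if (!nrow(hp))
        stop("no hidden positives: recovery AUC undefined")
    A <- assoc(observed(synth))
    F <- scores(predictAssociations(observed(synth), params))
    hidden <- matrix(FALSE, nrow(A), ncol(A), dimnames = dimnames(A))
    hidden[cbind(hp$diseaseID, hp$microbeID)] <- TRUE
    negMask <- A == 0 & !hidden
    if (!any(negMask))
        stop("no true negatives: recovery AUC undefined")
    .aucRank(F[hidden], F[negMask])
}
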