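.emptyRanks <- function() {
    data.frame(diseaseID = character(), microbeID = character(),
               rank = integer(), candidateCount = integer(),
               roundAUC = numeric(), stringsAsFactors = FALSE)
}

# Mann-Whitney AUC with midrank tie handling
.aucRank <- function(posScores, negScores) {
    np <- length(posScores); nn <- length(negScores)
    r <- rank(c(posScores, negScores))
    (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# threshold-swept ROC curve from scores/labels; starts (0,0), ends (1,1)
.rocCurve <- function(scores, labels) {
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; y <- labels[o]
    np <- sum(labels == 1); nn <- sum(labels == 0)
    tp <- cumsum(y == 1); fp <- cumsum(y == 0)
    keep <- c(s[-1L] != s[-length(s)], TRUE)   # last index of each threshold
    data.frame(fpr = c(0, fp[keep] / nn), tpr = c(0, tp[keep] / np))
}

#' ROC curve and AUC from scores and binary labels
#'
#' The AUC is the Mann-Whitney rank statistic with midranks for tied
#' scores, which equals the trapezoidal area under the threshold-swept
#' ROC curve. Requires at least one positive and one negative label.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 label vector of the same length.
#' @return a [CVResult-class] (with `aucSD = NA`).
#' @examples
#' auc(rocAUC(c(0.9, 0.8, 0.1), c(1, 1, 0)))  # perfect separation -> 1
#' @export
rocAUC <- function(scores, labels) {
    stopifnot(is.numeric(scores), length(scores) == length(labels),
              all(labels %in% c(0, 1)))
    if (length(unique(labels)) < 2L)
        stop("AUC undefined: need both positive and negative labels")
    a <- .aucRank(scores[labels == 1], scores[labels == 0])
    new("CVResult", auc = a, aucSD = NA_real_,
        rocPoints = .rocCurve(scores, labels), perRoundRanks = .emptyRanks())
}

#' Global leave-one-out cross-validation
#'
#' Each known association is withheld in turn: its matrix entry is set
#' to 0, all four interaction-profile similarities are recomputed from
#' the reduced matrix, the model is refit, and the withheld pair's
#' score is compared against the scores of every candidate pair (pairs
#' that are 0 in the *original* matrix). The protocol is fully
#' deterministic.
#'
#' Two aggregations are available. `"mean-rank"` (default) averages the
#' per-round normalised rank statistic — the fraction of candidates
#' scored strictly below the test pair plus half the tied fraction —
#' which is a per-round AUC against the fixed candidate set; its ROC
#' curve is the empirical curve of normalised test-pair ranks.
#' `"pooled"` pools every round's (test score, candidate scores) into
#' one score set and computes a single ROC/AUC.
#'
#' @param dataset an [AssociationSet-class] with at least one known
#'   association and at least one candidate pair.
#' @param params a [KRLSParams-class].
#' @param aggregation `"mean-rank"` or `"pooled"`.
#' @param tieTol absolute score tolerance below which a candidate is
#'   counted as tied with the test pair (default 1e-9): pairs that are
#'   analytically tied (for example through duplicated interaction
#'   profiles) can differ by ~1e-16 depending on the solver path, and
#'   a strict comparison would make their ranks path-dependent.
#' @return a [CVResult-class]; `perRoundRanks(x)` holds the competition
#'   rank of every withheld pair among the candidates.
#' @export
globalLOOCV <- function(dataset, params = krlsParams(),
                        aggregation = c("mean-rank", "pooled"),
                        tieTol = 1e-9) {
    stopifnot(is(dataset, "AssociationSet"), is(params, "KRLSParams"))
    aggregation <- match.arg(aggregation)
    A0 <- assoc(dataset)
    pos <- which(A0 == 1)
    cand <- which(A0 == 0)
    if (length(pos) < 1L) stop("degenerate dataset: no known associations")
    if (length(cand) < 1L) stop("degenerate dataset: no candidate pairs")
    nc <- length(cand)
    nd <- nrow(A0)
    rr <- data.frame(diseaseID = rownames(A0)[(pos - 1L) %% nd + 1L],
                     microbeID = colnames(A0)[(pos - 1L) %/% nd + 1L],
                     rank = NA_integer_, candidateCount = nc,
                     roundAUC = NA_real_, stringsAsFactors = FALSE)
    pooledPos <- numeric(length(pos))
    pooledNeg <- if (aggregation == "pooled") vector("list", length(pos)) else NULL
    for (i in seq_along(pos)) {
        Atr <- A0
        Atr[pos[i]] <- 0
        F <- scores(.predictCore(Atr, params))
        s <- F[pos[i]]
        cs <- F[cand]
        # candidates analytically tied with the test pair (e.g. duplicated
        # interaction profiles) differ by ~1e-16 across solver paths; detect
        # ties with a small absolute tolerance so ranks are path-independent
        nAbove <- sum(cs > s + tieTol); nTie <- sum(abs(cs - s) <= tieTol)
        rr$rank[i] <- 1L + nAbove
        rr$roundAUC[i] <- (nc - nAbove - nTie + 0.5 * nTie) / nc
        pooledPos[i] <- s
        if (!is.null(pooledNeg)) pooledNeg[[i]] <- cs
    }
    if (aggregation == "mean-rank") {
        a <- mean(rr$roundAUC)
        # ROC of normalised test-pair ranks: at FPR t, TPR is the
        # fraction of rounds whose test quantile (1 - roundAUC) <= t
        r <- sort(1 - rr$roundAUC)
        u <- unique(r)
        pts <- data.frame(fpr = c(0, u), tpr = c(0, vapply(u, function(t)
            mean(r <= t), numeric(1L))))
        if (pts$fpr[nrow(pts)] < 1)
            pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
        new("CVResult", auc = a, aucSD = NA_real_, rocPoints = pts,
            perRoundRanks = rr)
    } else {
        neg <- unlist(pooledNeg, use.names = FALSE)
        sc <- c(pooledPos, neg)
        lab <- c(rep(1, length(pooledPos)), rep(0, length(neg)))
        res <- rocAUC(sc, lab)
        new("CVResult", auc = res@auc, aucSD = NA_real_,
            rocPoints = res@rocPoints, perRoundRanks = rr)
    }
}

# deterministic fold labels for npos positives under a given seed
.foldAssignments <- function(npos, k, seed) {
    .withSeed(seed, {
        foldid <- integer(npos)
        foldid[sample.int(npos)] <- rep(seq_len(k), length.out = npos)
        foldid
    })
}

#' Repeated k-fold cross-validation over known associations
#'
#' Per repeat, the known associations are shuffled (sub-seed
#' `seed + repeat index`) and split into `k` near-equal folds. Per
#' fold, the fold's entries are zeroed, similarities are recomputed,
#' the model is refit, and one ROC/AUC is computed with the held-out
#' entries as positives and every pair that is 0 in the *original*
#' matrix as negatives (held-out positives are never counted as
#' negatives). The repeat AUC is the mean over its folds; the result
#' reports mean and standard deviation over repeats. Bit-reproducible
#' for a fixed seed; the caller's RNG state is left untouched.
#'
#' @param dataset an [AssociationSet-class].
#' @param params a [KRLSParams-class].
#' @param k number of folds (default 5).
#' @param repeats number of shuffled repeats (default 100).
#' @param seed integer seed controlling all shuffles.
#' @return a [CVResult-class]; `rocPoints(x)` is the curve pooled over
#'   the first repeat's folds, `auc(x)`/`aucSD(x)` summarise all
#'   repeats.
#' @export
kfoldCV <- function(dataset, params = krlsParams(), k = 5, repeats = 100,
                    seed = 1) {
    stopifnot(is(dataset, "AssociationSet"), is(params, "KRLSParams"),
              k >= 2, repeats >= 1)
    A0 <- assoc(dataset)
    pos <- which(A0 == 1)
    neg <- which(A0 == 0)
    if (length(pos) < k)
        stop(sprintf("only %d known associations; cannot form %d folds",
                     length(pos), k))
    repAUC <- numeric(repeats)
    firstScores <- NULL; firstLabels <- NULL
    for (r in seq_len(repeats)) {
        foldid <- .foldAssignments(length(pos), k, seed + r)
        foldAUC <- numeric(k)
        for (f in seq_len(k)) {
            test <- pos[foldid == f]
            Atr <- A0
            Atr[test] <- 0
            F <- scores(.predictCore(Atr, params))
            foldAUC[f] <- .aucRank(F[test], F[neg])
            if (r == 1L) {
                firstScores <- c(firstScores, F[test], F[neg])
                firstLabels <- c(firstLabels, rep(1, length(test)),
                                 rep(0, length(neg)))
            }
        }
        repAUC[r] <- mean(foldAUC)
    }
    new("CVResult", auc = mean(repAUC),
        aucSD = if (repeats > 1L) stats::sd(repAUC) else NA_real_,
        rocPoints = .rocCurve(firstScores, firstLabels),
        perRoundRanks = .emptyRanks())
}

#' Rank candidate microbes for one disease (case-study protocol)
#'
#' Removes *all* known associations of the given disease (its entire
#' matrix row is zeroed), retrains on the rest, and ranks every microbe
#' for that disease by descending score. This emulates predicting for a
#' disease with no known microbes, guaranteeing independence between
#' the training set and the evaluated disease. Ties share a competition
#' rank and are ordered by microbe identifier.
#'
#' @param dataset an [AssociationSet-class].
#' @param diseaseID identifier of the disease to evaluate.
#' @param params a [KRLSParams-class].
#' @param topN number of top microbes to return (default 20).
#' @return data.frame with columns `rank`, `microbeID`, `score`.
#' @export
caseStudyRank <- function(dataset, diseaseID, params = krlsParams(),
                          topN = 20) {
    stopifnot(is(dataset, "AssociationSet"))
    A0 <- assoc(dataset)
    if (!diseaseID %in% rownames(A0))
        stop(sprintf("unknown disease '%s'", diseaseID))
    Atr <- A0
    Atr[diseaseID, ] <- 0
    F <- scores(.predictCore(Atr, params))
    s <- F[diseaseID, ]
    df <- data.frame(microbeID = colnames(A0), score = unname(s),
                     stringsAsFactors = FALSE)
    df$rank <- vapply(df$score, function(x) 1L + sum(df$score > x), integer(1L))
    df <- df[order(-df$score, df$microbeID), , drop = FALSE]
    rownames(df) <- NULL
    utils::head(df[, c("rank", "microbeID", "score")], topN)
}

#' Sweep regularisation strength and fusion weight
#'
#' Evaluates cross-validated AUC over a grid of the shared
#' regularisation strength (`sigmaG = sigmaH = sigma`, fusion weight
#' held at `wFixed`) and then over a grid of the fusion weight `w`
#' with `sigma` fixed at the best grid value. One AUC per grid cell,
#' all cells evaluated under the same seed so cells are directly
#' comparable.
#'
#' @param dataset an [AssociationSet-class].
#' @param sigmaGrid positive regularisation values to try.
#' @param wGrid fusion weights in \[0, 1\] to try (may be `NULL` to
#'   sweep sigma only).
#' @param protocol `"kfold"` or `"loocv"`.
#' @param seed integer seed (k-fold shuffles).
#' @param k,repeats k-fold settings (defaults 5 and 5).
#' @param wFixed fusion weight used during the sigma sweep.
#' @param file optional path; if given, the result table is written as
#'   TSV.
#' @return data.frame with columns `parameter` (`"sigma"` or `"w"`),
#'   `value`, `auc`, `aucSD`, `protocol`.
#' @export
parameterSweep <- function(dataset, sigmaGrid, wGrid = NULL,
                           protocol = c("kfold", "loocv"), seed = 1,
                           k = 5, repeats = 5, wFixed = 0.8, file = NULL) {
    protocol <- match.arg(protocol)
    stopifnot(length(sigmaGrid) >= 1L, all(sigmaGrid > 0))
    evalCell <- function(params) {
        res <- if (protocol == "kfold")
            kfoldCV(dataset, params, k = k, repeats = repeats, seed = seed)
        else globalLOOCV(dataset, params)
        c(res@auc, res@aucSD)
    }
    sig <- t(vapply(sigmaGrid, function(s)
        evalCell(krlsParams(sigmaG = s, sigmaH = s, w = wFixed)),
        numeric(2L)))
    out <- data.frame(parameter = "sigma", value = sigmaGrid,
                      auc = sig[, 1L], aucSD = sig[, 2L],
                      protocol = protocol, stringsAsFactors = FALSE)
    if (length(wGrid)) {
        stopifnot(all(wGrid >= 0 & wGrid <= 1))
        bestSigma <- sigmaGrid[which.max(sig[, 1L])]
        wres <- t(vapply(wGrid, function(w)
            evalCell(krlsParams(sigmaG = bestSigma, sigmaH = bestSigma, w = w)),
            numeric(2L)))
        out <- rbind(out, data.frame(parameter = "w", value = wGrid,
                                     auc = wres[, 1L], aucSD = wres[, 2L],
                                     protocol = protocol,
                                     stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    if (!is.null(file))
        utils::write.table(out, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    out
}
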