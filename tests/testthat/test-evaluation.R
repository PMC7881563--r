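test_that("AUC matches hand-worked cases and brute-force pair counting", {
    expect_equal(auc(rocAUC(c(0.9, 0.8, 0.1), c(1, 1, 0))), 1)
    expect_equal(auc(rocAUC(rep(0.3, 6), c(1, 0, 1, 0, 0, 1))), 0.5)
    expect_equal(auc(rocAUC(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 0, 1))), 0.5)
    expect_error(rocAUC(c(0.1, 0.2), c(1, 1)), "AUC undefined")

    set.seed(3)
    for (rep in 1:40) {
        n <- sample(4:50, 1)
        sc <- sample(round(runif(n), 2), n, replace = TRUE)  # force ties
        lab <- rbinom(n, 1, 0.5)
        if (length(unique(lab)) < 2) next
        expect_equal(auc(rocAUC(sc, lab)), bruteAUC(sc, lab), tolerance = 1e-12)
    }
})

test_that("AUC agrees with pROC and is invariant to monotone score transforms", {
    skip_if_not_installed("pROC")
    set.seed(4)
    sc <- runif(60); lab <- rbinom(60, 1, 0.4)
    expect_equal(auc(rocAUC(sc, lab)),
                 as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
    expect_equal(auc(rocAUC(exp(3 * sc) + 2, lab)), auc(rocAUC(sc, lab)))
})

test_that("ROC curves run from (0,0) to (1,1) and are monotone", {
    set.seed(5)
    r <- rocAUC(round(runif(40), 1), rbinom(40, 1, 0.5))
    p <- rocPoints(r)
    expect_equal(unlist(p[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(p[nrow(p), ]), c(fpr = 1, tpr = 1))
    expect_false(is.unsorted(p$fpr) || is.unsorted(p$tpr))
})

test_that("global LOOCV matches a brute-force direct-solve replay", {
    I2 <- AssociationSet(matrix(c(1, 0, 0, 1), 2,
            dimnames = list(c("d1", "d2"), c("m1", "m2"))))
    res <- globalLOOCV(I2)
    ref <- bruteLOOCV(I2)
    expect_equal(perRoundRanks(res)$rank, ref$rank)
    expect_equal(perRoundRanks(res)$roundAUC, ref$roundAUC, tolerance = 1e-10)
    expect_equal(auc(res), mean(ref$roundAUC), tolerance = 1e-10)

    ds <- AssociationSet(rbinMat(3, 4, seed = 17))
    res2 <- globalLOOCV(ds)
    ref2 <- bruteLOOCV(ds)
    expect_equal(perRoundRanks(res2)$rank, ref2$rank)
    expect_equal(auc(res2), mean(ref2$roundAUC), tolerance = 1e-10)
})

test_that("global LOOCV on a single association is uninformative by symmetry", {
    ds <- AssociationSet(matrix(c(1, 0, 0, 0), 2,
            dimnames = list(c("d1", "d2"), c("m1", "m2"))))
    res <- globalLOOCV(ds)
    expect_equal(auc(res), 0.5)         # all-zero guard ties every score
    expect_equal(nrow(perRoundRanks(res)), 1L)
})

test_that("global LOOCV is deterministic and pooled aggregation stays close", {
    obs <- observed(strongSynth())
    r1 <- globalLOOCV(obs)
    r2 <- globalLOOCV(obs)
    expect_identical(auc(r1), auc(r2))
    rp <- globalLOOCV(obs, aggregation = "pooled")
    expect_equal(auc(rp), auc(r1), tolerance = 0.05)
    expect_identical(perRoundRanks(rp)$rank, perRoundRanks(r1)$rank)
})

test_that("structured data outranks its degree-destroying permutation under LOOCV", {
    obs <- observed(strongSynth())
    structured <- auc(globalLOOCV(obs))
    expect_gt(structured, 0.75)         # strong planted blocks are recoverable
    A <- assoc(obs)
    perm <- vapply(1:3, function(s) {
        set.seed(s)
        Ap <- matrix(sample(A), nrow(A), dimnames = dimnames(A))
        auc(globalLOOCV(AssociationSet(Ap)))
    }, numeric(1))
    expect_true(all(structured > perm + 0.2))
})

test_that("k-fold CV is seed-reproducible and partitions positives exactly", {
    obs <- observed(strongSynth())
    r1 <- kfoldCV(obs, repeats = 2, seed = 5)
    r2 <- kfoldCV(obs, repeats = 2, seed = 5)
    expect_identical(auc(r1), auc(r2))
    expect_identical(aucSD(r1), aucSD(r2))
    expect_identical(rocPoints(r1), rocPoints(r2))
    expect_gt(auc(r1), 0.75)

    foldid <- kronRLS:::.foldAssignments(37, 5, 11)
    expect_length(foldid, 37)
    expect_setequal(unique(foldid), 1:5)
    expect_true(all(table(foldid) %in% c(7, 8)))   # near-equal folds
    # every positive lands in exactly one test fold
    expect_equal(sum(table(foldid)), 37)

    expect_error(kfoldCV(AssociationSet(matrix(c(1, 0, 0, 1), 2,
        dimnames = list(c("d1", "d2"), c("m1", "m2")))), k = 5),
        "cannot form 5 folds")
})

test_that("k-fold CV on permuted labels is close to chance", {
    obs <- observed(strongSynth())
    A <- assoc(obs)
    set.seed(2)
    Ap <- matrix(sample(A), nrow(A), dimnames = dimnames(A))
    r <- kfoldCV(AssociationSet(Ap), repeats = 5, seed = 1)
    expect_equal(auc(r), 0.5, tolerance = 0.05)
})

test_that("case-study ranking zeroes the disease and orders microbes deterministically", {
    st <- strongSynth()
    obs <- observed(st)
    full <- caseStudyRank(obs, "D001", topN = nMicrobes(obs))
    expect_setequal(full$microbeID, microbeIDs(obs))   # a permutation of all

    # true same-block microbes should rank better on average
    ba <- blockAssignments(st)
    trueM <- names(which(ba$microbe == ba$disease[["D001"]]))
    expect_lt(mean(full$rank[full$microbeID %in% trueM]),
              mean(full$rank[!full$microbeID %in% trueM]))

    # a disease that is already all-zero: ranking equals plain prediction
    A <- assoc(obs); A["D002", ] <- 0
    ds0 <- AssociationSet(A)
    cs <- caseStudyRank(ds0, "D002", topN = 5)
    F <- scores(predictAssociations(ds0))
    o <- order(-F["D002", ], colnames(A))
    expect_identical(cs$microbeID, colnames(A)[o][1:5])

    expect_error(caseStudyRank(obs, "no-such-disease"), "unknown disease")
})

test_that("parameter sweep cells reproduce direct protocol runs", {
    obs <- observed(strongSynth())
    sw <- parameterSweep(obs, sigmaGrid = 30, wGrid = c(0, 1),
                         protocol = "kfold", seed = 3, repeats = 2)
    direct <- kfoldCV(obs, krlsParams(), k = 5, repeats = 2, seed = 3)
    expect_equal(sw$auc[sw$parameter == "sigma"], auc(direct))

    # w endpoints equal the single-branch models
    g <- kfoldCV(obs, krlsParams(w = 1), repeats = 2, seed = 3)
    h <- kfoldCV(obs, krlsParams(w = 0), repeats = 2, seed = 3)
    expect_equal(sw$auc[sw$parameter == "w" & sw$value == 1], auc(g))
    expect_equal(sw$auc[sw$parameter == "w" & sw$value == 0], auc(h))

    tf <- withr::local_tempfile()
    parameterSweep(obs, sigmaGrid = 30, protocol = "loocv", file = tf)
    tab <- read.delim(tf)
    expect_equal(tab$auc, auc(globalLOOCV(obs)))
})
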