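test_that("Kronecker pairwise kernel obeys the column-major vec identity", {
    expect_identical(kroneckerSimilarity(diag(2), diag(3)), diag(6))
    expect_equal(dim(kroneckerSimilarity(matrix(runif(4), 2), matrix(runif(9), 3))),
                 c(6L, 6L))
    set.seed(21)
    for (rep in 1:10) {
        nd <- sample(2:5, 1); nm <- sample(2:5, 1)
        Sm <- crossprod(matrix(rnorm(nm * nm), nm))
        Sd <- crossprod(matrix(rnorm(nd * nd), nd))
        Y <- matrix(rnorm(nd * nm), nd, nm)
        K <- kroneckerSimilarity(Sm, Sd)
        expect_lt(max(abs(K %*% as.vector(Y) - as.vector(Sd %*% Y %*% t(Sm)))),
                  1e-12)
    }
    # large instances must be refused, pointing at the eigen path
    expect_error(kroneckerSimilarity(diag(70), diag(60)), "krlsSolveEigen")
})

test_that("direct solve reproduces identity-kernel closed forms and shrinkage limits", {
    Y <- rbinMat(2, 3, seed = 1)
    K <- diag(6)
    expect_equal(scores(krlsSolveDirect(K, Y, 1)), Y / 2, tolerance = 0)

    # sigma -> 0 on a well-conditioned kernel: scores converge to labels
    Kw <- 0.9 * diag(6) + 0.1
    expect_lt(max(abs(scores(krlsSolveDirect(Kw, Y, 1e-8)) - Y)), 1e-4)

    # sigma -> infinity: scores shrink to zero
    expect_lt(max(abs(scores(krlsSolveDirect(Kw, Y, 1e9)))), 1e-6)
})

test_that("eigendecomposition path matches the direct solve on both kernel kinds", {
    Y0 <- rbinMat(3, 4, seed = 2)
    Sm <- gipSimilarity(Y0, "microbe"); Sd <- gipSimilarity(Y0, "disease")
    K <- kroneckerSimilarity(Sm, Sd)
    expect_lt(max(abs(scores(krlsSolveEigen(Sm, Sd, Y0, 1)) -
                      scores(krlsSolveDirect(K, Y0, 1)))), 1e-8)

    set.seed(33)
    for (rep in 1:6) {
        nd <- sample(2:6, 1); nm <- sample(2:8, 1)
        Y <- rbinMat(nd, nm, p = runif(1, 0.2, 0.8))
        for (sigma in c(0.1, 1, 30)) {
            for (kind in c("GIP", "HIP")) {
                f <- if (kind == "GIP") gipSimilarity else hipSimilarity
                Sm <- f(Y, "microbe"); Sd <- f(Y, "disease")
                Fe <- scores(krlsSolveEigen(Sm, Sd, Y, sigma))
                Fd <- scores(krlsSolveDirect(kroneckerSimilarity(Sm, Sd), Y, sigma))
                expect_lt(max(abs(Fe - Fd)), 1e-8)
            }
        }
    }

    # rank-1 all-ones similarities: a single eigenvalue product survives
    J <- matrix(1, 2, 2)
    Y2 <- matrix(c(1, 0, 0, 1), 2, 2)
    expect_lt(max(abs(scores(krlsSolveEigen(J, J, Y2, 30)) -
                      scores(krlsSolveDirect(kronecker(J, J), Y2, 30)))), 1e-10)
})

test_that("scores are invariant to eigenvector sign flips and eigenpair order", {
    Y <- rbinMat(4, 5, seed = 9)
    Sm <- simValues(gipSimilarity(Y, "microbe"))
    Sd <- simValues(gipSimilarity(Y, "disease"))
    F <- scores(krlsSolveEigen(Sm, Sd, Y, 30))
    em <- eigen(Sm, symmetric = TRUE); ed <- eigen(Sd, symmetric = TRUE)
    # flip some signs and permute eigenpairs, then apply the filter form
    sm <- sample(c(-1, 1), ncol(Sm), replace = TRUE)
    pm <- sample(ncol(Sm)); pd <- sample(nrow(Sd))
    Vm <- sweep(em$vectors, 2, sm, "*")[, pm]; lm <- em$values[pm]
    Vd <- ed$vectors[, pd]; ld <- ed$values[pd]
    P <- outer(ld, lm)
    F2 <- Vd %*% ((P / (P + 30)) * (crossprod(Vd, Y) %*% Vm)) %*% t(Vm)
    expect_lt(max(abs(F - F2)), 1e-10)
})

test_that("near-singular filter-factor denominators are refused with a clear message", {
    Sm <- diag(c(2, 0.5))
    Sd <- matrix(c(0, 1, 1, 0), 2)     # indefinite, eigenvalues +/- 1
    Y <- matrix(c(1, 0, 0, 1), 2, 2)
    expect_error(krlsSolveEigen(Sm, Sd, Y, sigma = 2), "singular filter factor")
    expect_silent(krlsSolveEigen(Sm, Sd, Y, sigma = 30))
})

test_that("fusion is a convex combination with exact endpoint identities", {
    FG <- new("ScoreMatrix", values = matrix(runif(6), 2, 3), branch = "gaussian")
    FH <- new("ScoreMatrix", values = matrix(runif(6), 2, 3), branch = "hamming")
    expect_identical(scores(fuseScores(FG, FH, 1)), scores(FG))
    expect_identical(scores(fuseScores(FG, FH, 0)), scores(FH))
    ones <- matrix(1, 2, 2); zeros <- matrix(0, 2, 2)
    expect_true(all(scores(fuseScores(ones, zeros, 0.8)) == 0.8))
    expect_identical(scoreBranch(fuseScores(FG, FH, 0.5)), "fused")
    expect_error(fuseScores(FG, new("ScoreMatrix", values = matrix(0, 3, 2),
                                    branch = "hamming"), 0.5), "shape")
    expect_error(fuseScores(FG, FH, 1.2), "\\[0, 1\\]")
})

test_that("prediction is equivariant and degenerates gracefully on empty data", {
    # all-zero training matrix: guard gives uninformative, equal scores
    Z <- AssociationSet(matrix(0, 2, 3,
            dimnames = list(c("d1", "d2"), c("m1", "m2", "m3"))))
    FZ <- scores(predictAssociations(Z))
    expect_lt(diff(range(FZ)), 1e-12)

    # joint permutation of diseases and microbes permutes the scores
    ds <- AssociationSet(rbinMat(5, 6, seed = 13))
    F1 <- scores(predictAssociations(ds))
    pd <- sample(5); pm <- sample(6)
    dsP <- AssociationSet(assoc(ds)[pd, pm])
    F2 <- scores(predictAssociations(dsP))
    expect_equal(unname(F2), unname(F1[pd, pm]), tolerance = 1e-10)

    # the 2x2 identity's own symmetry (swap both axes) leaves scores invariant
    I2 <- AssociationSet(matrix(c(1, 0, 0, 1), 2,
            dimnames = list(c("d1", "d2"), c("m1", "m2"))))
    FI <- scores(predictAssociations(I2))
    expect_equal(unname(FI), unname(FI[2:1, 2:1]), tolerance = 1e-12)
})

test_that("parameter container validates its ranges", {
    p <- krlsParams()
    expect_equal(p@sigmaG, 30); expect_equal(p@w, 0.8)
    expect_error(krlsParams(sigmaG = -1), "positive")
    expect_error(krlsParams(w = 1.5), "\\[0, 1\\]")
})
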