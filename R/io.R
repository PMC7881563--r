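#' Read a disease-microbe pair list
#'
#' Reads a delimited text file (or connection) with one known
#' association per row: the first field is the disease identifier, the
#' second the microbe identifier; extra fields are ignored. Identifiers
#' are trimmed of surrounding whitespace and compared case-sensitively.
#' Exact duplicate (disease, microbe) rows are collapsed to a single
#' association; the number of duplicates removed is reported via
#' [message()]. Row order of first appearance fixes the disease order,
#' column order of first appearance the microbe order.
#'
#' @param file path or connection to the pair list.
#' @param delimiter single-character field delimiter (default tab).
#' @param header logical; if `TRUE` the first line is skipped. Header
#'   presence is declared, never guessed.
#'
#' @return an [AssociationSet-class].
#' @examples
#' tf <- tempfile()
#' writeLines(c("d1\tm1", "d1\tm2", "d2\tm1"), tf)
#' readPairList(tf)
#' @export
readPairList <- function(file, delimiter = "\t", header = FALSE) {
    lines <- readLines(file)
    if (header) lines <- lines[-1L]
    keep <- nzchar(trimws(lines))
    line_no <- which(keep) + as.integer(header)
    lines <- lines[keep]
    if (!length(lines))
        stop("no associations in input")
    parts <- strsplit(lines, delimiter, fixed = TRUE)
    d <- character(length(parts)); m <- character(length(parts))
    for (i in seq_along(parts)) {
        f <- trimws(parts[[i]])
        if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L]))
            stop(sprintf("malformed row at line %d: need disease and microbe identifiers",
                         line_no[i]))
        d[i] <- f[1L]; m[i] <- f[2L]
    }
    dup <- duplicated(paste(d, m, sep = "\r"))
    if (any(dup))
        message(sprintf("readPairList: %d rows read, %d duplicate association(s) removed, %d unique retained",
                        length(d), sum(dup), sum(!dup)))
    else
        message(sprintf("readPairList: %d rows read, %d unique associations",
                        length(d), length(d)))
    d <- d[!dup]; m <- m[!dup]
    dids <- unique(d); mids <- unique(m)
    A <- matrix(0, length(dids), length(mids), dimnames = list(dids, mids))
    A[cbind(d, m)] <- 1
    AssociationSet(A)
}

#' Write an AssociationSet as a pair list
#'
#' Emits one `disease<delimiter>microbe` row per known association, in
#' row-major order of the association matrix so that
#' `readPairList(writePairList(x))` reproduces `x` exactly (same entity
#' order, same matrix).
#'
#' @param x an [AssociationSet-class].
#' @param file path or connection.
#' @param delimiter field delimiter (default tab).
#' @return invisibly, the number of rows written.
#' @export
writePairList <- function(x, file, delimiter = "\t") {
    A <- assoc(x)
    idx <- which(t(A) == 1)  # row-major over A: diseases in row order
    mj <- (idx - 1L) %% ncol(A) + 1L
    di <- (idx - 1L) %/% ncol(A) + 1L
    writeLines(paste(rownames(A)[di], colnames(A)[mj], sep = delimiter), file)
    invisible(length(idx))
}

#' Read a dense labelled 0/1 association matrix
#'
#' The first row holds microbe identifiers, the first column disease
#' identifiers, and every body cell must be exactly `0` or `1`. Ragged
#' rows and non-binary cells are rejected with the offending location.
#'
#' @param file path or connection.
#' @param delimiter field delimiter (default comma).
#' @return an [AssociationSet-class].
#' @export
readDenseMatrix <- function(file, delimiter = ",") {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L)
        stop("no associations: need a header row and at least one disease row")
    parts <- strsplit(lines, delimiter, fixed = TRUE)
    mids <- trimws(parts[[1L]])[-1L]
    if (!length(mids))
        stop("header row holds no microbe identifiers")
    nm <- length(mids)
    dids <- character(length(lines) - 1L)
    A <- matrix(0, length(dids), nm)
    for (i in seq_len(length(lines) - 1L)) {
        f <- trimws(parts[[i + 1L]])
        if (length(f) != nm + 1L)
            stop(sprintf("ragged row at line %d: %d fields, expected %d",
                         i + 1L, length(f), nm + 1L))
        dids[i] <- f[1L]
        v <- suppressWarnings(as.numeric(f[-1L]))
        bad <- which(is.na(v) | !(v %in% c(0, 1)))
        if (length(bad))
            stop(sprintf("non-binary cell '%s' at row '%s', column '%s'",
                         f[bad[1L] + 1L], f[1L], mids[bad[1L]]))
        A[i, ] <- v
    }
    dimnames(A) <- list(dids, mids)
    AssociationSet(A)
}

#' Write a dense labelled association matrix
#'
#' @param x an [AssociationSet-class].
#' @param file path or connection.
#' @param delimiter field delimiter (default comma).
#' @return invisibly, the number of data rows written.
#' @export
writeDenseMatrix <- function(x, file, delimiter = ",") {
    A <- assoc(x)
    out <- c(paste(c("", colnames(A)), collapse = delimiter),
             vapply(seq_len(nrow(A)), function(i)
                 paste(c(rownames(A)[i], format(A[i, ], trim = TRUE,
                                                scientific = FALSE)),
                       collapse = delimiter), character(1L)))
    writeLines(out, file)
    invisible(nrow(A))
}

#' Write prediction scores as a ranked TSV table
#'
#' Flattens a score matrix into `(rank, disease, microbe, score)` rows
#' sorted by descending score. Ties receive the same (competition) rank
#' and are ordered secondarily by microbe identifier, then disease
#' identifier, for deterministic output. With `maskKnown = TRUE`,
#' pairs already marked 1 in the training matrix are omitted — the
#' usual novel-prediction view.
#'
#' @param scores a [ScoreMatrix-class].
#' @param dataset the training [AssociationSet-class] (shapes must
#'   match).
#' @param file path or connection.
#' @param maskKnown drop known associations from the output?
#' @return invisibly, the number of rows written.
#' @export
writeRankedScores <- function(scores, dataset, file, maskKnown = FALSE) {
    tab <- rankedScores(scores, dataset, maskKnown = maskKnown)
    out <- c("rank\tdisease\tmicrobe\tscore",
             sprintf("%d\t%s\t%s\t%.10g", tab$rank, tab$diseaseID,
                     tab$microbeID, tab$score))
    writeLines(out, file)
    invisible(nrow(tab))
}

#' @rdname writeRankedScores
#' @return `rankedScores` returns the ranked table as a data.frame with
#'   columns `rank`, `diseaseID`, `microbeID`, `score`.
#' @export
rankedScores <- function(scores, dataset, maskKnown = FALSE) {
    stopifnot(is(scores, "ScoreMatrix"), is(dataset, "AssociationSet"))
    F <- scores(scores)
    A <- assoc(dataset)
    if (!identical(dim(F), dim(A)))
        stop(sprintf("shape mismatch: scores are %dx%d, dataset is %dx%d",
                     nrow(F), ncol(F), nrow(A), ncol(A)))
    df <- data.frame(diseaseID = rep(rownames(A), times = ncol(A)),
                     microbeID = rep(colnames(A), each = nrow(A)),
                     score = as.vector(F), known = as.vector(A) == 1,
                     stringsAsFactors = FALSE)
    if (maskKnown) df <- df[!df$known, , drop = FALSE]
    if (!nrow(df))
        return(data.frame(rank = integer(), diseaseID = character(),
                          microbeID = character(), score = numeric()))
    # competition rank: 1 + number of strictly larger scores
    df$rank <- vapply(df$score, function(s) 1L + sum(df$score > s), integer(1L))
    df <- df[order(-df$score, df$microbeID, df$diseaseID), , drop = FALSE]
    rownames(df) <- NULL
    df[, c("rank", "diseaseID", "microbeID", "score")]
}

#' Write a similarity matrix as labelled CSV (for inspection)
#'
#' @param sim a [SimilarityMatrix-class].
#' @param file path or connection.
#' @export
writeSimilarity <- function(sim, file) {
    S <- simValues(sim)
    out <- c(paste(c("", colnames(S)), collapse = ","),
             vapply(seq_len(nrow(S)), function(i)
                 paste(c(rownames(S)[i], format(S[i, ], trim = TRUE, digits = 15)),
                       collapse = ","), character(1L)))
    writeLines(out, file)
    invisible(nrow(S))
}
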