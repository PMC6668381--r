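# Cross-validation orchestration and ROC / precision-recall metrics.

# coerce labels to logical (TRUE = positive)
asPositive <- function(labels) {
    if (is.factor(labels)) return(as.character(labels) == "positive")
    if (is.logical(labels)) return(labels)
    if (is.numeric(labels)) return(labels > 0)
    labels == "positive"
}

# fast tie-aware auROC via the rank (Mann-Whitney) identity; used
# internally where only the scalar is needed.
aucRank <- function(scores, labels) {
    pos <- asPositive(labels)
    np <- sum(pos); nn <- sum(!pos)
    if (np == 0L || nn == 0L) stop("both classes required for auROC")
    r <- rank(scores, ties.method = "average")
    (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC and precision-recall evaluation
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped at a single threshold) and computes the ROC curve, its
#' trapezoid area (equal to the normalized Mann-Whitney U statistic with
#' half credit for tied pairs), the precision-recall curve with trapezoid
#' auPRC, and the break-even point where precision equals recall (by
#' linear interpolation between the two straddling PR points).
#'
#' @param scores numeric classifier scores, higher = more positive.
#' @param labels class labels (logical, 0/1, or factor with level
#'   \code{"positive"}).
#' @return an \linkS4class{EvaluationReport}.
#' @examples
#' computeMetrics(c(.9, .4, .6, .1), c(1, 1, 0, 0))
#' @export
computeMetrics <- function(scores, labels) {
    pos <- asPositive(labels)
    if (any(!is.finite(scores))) stop("scores must be finite")
    np <- sum(pos); nn <- sum(!pos)
    if (np == 0L || nn == 0L)
        stop("both classes must be present to evaluate")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; p <- pos[o]
    grp <- cumsum(!duplicated(s))           # tie groups, descending score
    tp <- cumsum(p); fp <- cumsum(!p)
    last <- which(!duplicated(grp, fromLast = TRUE))  # end of each group
    tp <- tp[last]; fp <- fp[last]
    tpr <- tp / np; fpr <- fp / nn
    roc <- cbind(fpr = c(0, fpr), tpr = c(0, tpr))
    if (roc[nrow(roc), 1L] != 1 || roc[nrow(roc), 2L] != 1)
        roc <- rbind(roc, c(1, 1))
    auroc <- sum(diff(roc[, 1L]) *
                 (utils::head(roc[, 2L], -1L) + utils::tail(roc[, 2L], -1L)) / 2)
    prec <- tp / (tp + fp)
    rec <- tp / np
    pr <- cbind(recall = rec, precision = prec)
    auprc <- if (nrow(pr) > 1L)
        sum(diff(pr[, 1L]) *
            (utils::head(pr[, 2L], -1L) + utils::tail(pr[, 2L], -1L)) / 2) +
        pr[1L, 1L] * pr[1L, 2L]             # rectangle up to first point
    else pr[1L, 1L] * pr[1L, 2L]
    bep <- prBreakEven(pr)
    new("EvaluationReport", rocPoints = roc, auROC = unname(auroc),
        prPoints = pr, auPRC = unname(auprc), bep = unname(bep),
        nPos = as.integer(np), nNeg = as.integer(nn))
}

# precision == recall crossing by linear interpolation along the curve
prBreakEven <- function(pr) {
    d <- pr[, "precision"] - pr[, "recall"]
    hit <- which(abs(d) < 1e-12)
    if (length(hit)) return(pr[hit[1L], "recall"])
    cross <- which(d[-length(d)] * d[-1L] < 0)
    if (!length(cross)) {
        # no crossing on the swept curve: report the point closest to the
        # diagonal (degenerate, e.g. tiny score sets)
        i <- which.min(abs(d))
        return(mean(pr[i, ]))
    }
    i <- cross[1L]
    t <- d[i] / (d[i] - d[i + 1L])
    unname(pr[i, "recall"] + t * (pr[i + 1L, "recall"] - pr[i, "recall"]))
}

#' Stratified k-fold partition
#'
#' Assigns each class's members to k folds of size differing by at most
#' one, after a seeded shuffle. Folds are disjoint and exhaustive.
#'
#' @param labels per-sample class labels.
#' @param k number of folds (each class must have >= k members).
#' @param seed integer seed.
#' @return list of k elements, each \code{list(train=, validation=)} index
#'   vectors into \code{labels}.
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
    lab <- if (is.factor(labels)) droplevels(labels) else factor(labels)
    cnt <- table(lab)
    if (any(cnt < k))
        stop("every class needs at least k = ", k, " members; smallest has ",
             min(cnt))
    fold <- integer(length(lab))
    withSeed(seed, {
        for (cl in levels(lab)) {
            idx <- sample(which(lab == cl))
            fold[idx] <- rep_len(seq_len(k), length(idx))
        }
    })
    lapply(seq_len(k), function(f)
        list(train = which(fold != f), validation = which(fold == f)))
}

#' Cross-validated out-of-fold scoring
#'
#' Runs stratified k-fold cross-validation for one or more encodings.
#' Within each fold, position-specific profiles are fitted on the training
#' part only and frozen before the held-out part is encoded (no leakage);
#' a probability forest is trained per encoding and fold, and held-out
#' scores are pooled across folds into one report per encoding.
#'
#' @param x a labeled \linkS4class{PacesSamples} whose window is at least
#'   as wide as every requested encoder's tuned window.
#' @param encoders subset of \code{c("onehot","psnsp","psdsp","knf","ksnpf")}.
#' @param k number of folds.
#' @param seed integer seed controlling fold assignment and forest
#'   training.
#' @param nTrees trees per forest.
#' @param windows named integer vector of flank widths per encoding
#'   (default \code{\link{pacesWindows}()}).
#' @return list with \code{scores} (n x encoders matrix of out-of-fold
#'   scores), \code{reports} (named list of
#'   \linkS4class{EvaluationReport}), \code{folds}, and \code{labels}.
#' @export
crossValidate <- function(x, encoders = c("psdsp", "knf"), k = 5L,
                          seed = 1L, nTrees = 800L,
                          windows = pacesWindows()) {
    stopifnot(is(x, "PacesSamples"))
    encoders <- match.arg(encoders,
        c("onehot", "psnsp", "psdsp", "knf", "ksnpf"), several.ok = TRUE)
    if (any(windows[encoders] > x@window))
        stop("dataset window (", x@window,
             ") narrower than required encoder window")
    folds <- stratifiedKFold(x@label, k = k, seed = seed)
    n <- length(x)
    scores <- matrix(NA_real_, nrow = n, ncol = length(encoders),
                     dimnames = list(NULL, encoders))
    trimmed <- lapply(encoders, function(e) trimSamples(x, windows[[e]]))
    names(trimmed) <- encoders
    # composition encodings need no fitting: encode once
    static <- list()
    for (e in intersect(encoders, c("onehot", "knf", "ksnpf")))
        static[[e]] <- encodeFeatures(trimmed[[e]], e)
    for (f in seq_len(k)) {
        tr <- folds[[f]]$train
        va <- folds[[f]]$validation
        for (e in encoders) {
            if (e %in% names(static)) {
                xtr <- static[[e]][tr, , drop = FALSE]
                xva <- static[[e]][va, , drop = FALSE]
            } else {
                ord <- if (e == "psnsp") 1L else 2L
                prof <- fitPositionProfile(trimmed[[e]][tr], order = ord)
                xtr <- encodeFeatures(trimmed[[e]][tr], e, prof)
                xva <- encodeFeatures(trimmed[[e]][va], e, prof)
            }
            tryCatch({
                clf <- trainForest(xtr, x@label[tr], nTrees = nTrees,
                                   seed = seed + f, encoding = e)
                scores[va, e] <- predictScores(clf, xva)
            }, error = function(err)
                stop("fold ", f, " (", e, "): ", conditionMessage(err),
                     call. = FALSE))
        }
    }
    reports <- lapply(encoders, function(e)
        computeMetrics(scores[, e], x@label))
    names(reports) <- encoders
    list(scores = scores, reports = reports, folds = folds,
         labels = x@label)
}
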