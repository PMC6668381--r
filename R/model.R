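# Forest training, score combination, ensemble weight tuning, specificity
# threshold calibration, and the end-to-end training pipeline.

#' Train a probability random forest on encoded samples
#'
#' Wraps a \pkg{ranger} probability forest (single-threaded for exact
#' reproducibility under a seed) and records the feature layout so that
#' prediction matrices are checked against it.
#'
#' @param x numeric feature matrix (rows = samples) with column names.
#' @param y labels coercible by the package's positive/negative convention.
#' @param nTrees number of trees (default 800, the tuned value).
#' @param seed integer seed; identical data + seed give identical scores.
#' @param encoding encoding tag stored with the classifier.
#' @param importance record impurity-based feature importance (default
#'   FALSE; adds a little training cost).
#' @return a \linkS4class{ForestClassifier}.
#' @importFrom ranger ranger
#' @export
trainForest <- function(x, y, nTrees = 800L, seed = 1L, encoding = "",
                        importance = FALSE) {
    pos <- asPositive(y)
    if (nrow(x) != length(pos))
        stop("feature matrix rows must match the number of labels")
    if (all(pos) || all(!pos))
        stop("training labels contain a single class")
    if (is.null(colnames(x)))
        colnames(x) <- paste0("f", seq_len(ncol(x)))
    yf <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    fit <- ranger::ranger(
        x = x, y = yf, probability = TRUE,
        num.trees = as.integer(nTrees), seed = as.integer(seed),
        importance = if (isTRUE(importance)) "impurity" else "none",
        num.threads = 1L)
    new("ForestClassifier", encoding = as.character(encoding), fit = fit,
        nTrees = as.integer(nTrees), seed = as.integer(seed),
        featureNames = colnames(x))
}

#' Impurity-based feature importance of a fitted forest
#'
#' @param clf a \linkS4class{ForestClassifier} trained with
#'   \code{importance = TRUE}.
#' @return named numeric vector, decreasing.
#' @export
featureImportance <- function(clf) {
    stopifnot(is(clf, "ForestClassifier"))
    imp <- clf@fit$variable.importance
    if (is.null(imp) || !length(imp))
        stop("classifier was trained without importance recording")
    sort(imp, decreasing = TRUE)
}

#' Positive-class scores from a fitted forest
#'
#' @param clf a \linkS4class{ForestClassifier}.
#' @param x feature matrix with the training feature layout.
#' @return numeric scores in [0, 1].
#' @export
predictScores <- function(clf, x) {
    stopifnot(is(clf, "ForestClassifier"))
    if (ncol(x) != length(clf@featureNames))
        stop("feature matrix has ", ncol(x), " columns; classifier expects ",
             length(clf@featureNames))
    colnames(x) <- clf@featureNames
    stats::predict(clf@fit, data = x,
                   num.threads = 1L)$predictions[, "pos"]
}

#' Weighted-sum combination of two score vectors
#'
#' The meta-classifier score is the elementwise weighted sum of the PSDSP
#' and KNF forest scores; with non-negative weights summing to one it
#' stays in [0, 1].
#'
#' @param sPsdsp,sKnf numeric score vectors of equal length.
#' @param weights numeric length-2 (psdsp, knf), non-negative, sum 1.
#' @return numeric combined scores.
#' @export
combineScores <- function(sPsdsp, sKnf, weights = c(0.5, 0.5)) {
    if (length(sPsdsp) != length(sKnf))
        stop("score vectors must have equal length")
    if (length(weights) != 2L || any(weights < 0) ||
        abs(sum(weights) - 1) > 1e-8)
        stop("weights must be two non-negative values summing to 1")
    weights[1L] * sPsdsp + weights[2L] * sKnf
}

#' Grid search for ensemble weights on out-of-fold scores
#'
#' Evaluates the weighted sum over a weight grid and returns the pair
#' maximizing cross-validated auROC; exact ties are broken toward the
#' balanced (0.5, 0.5) combination.
#'
#' @param sPsdsp,sKnf aligned out-of-fold score vectors.
#' @param labels matching class labels.
#' @param step grid step for the PSDSP weight (default 0.1).
#' @return named numeric weights \code{c(psdsp=, knf=)}.
#' @export
tuneWeights <- function(sPsdsp, sKnf, labels, step = 0.1) {
    pos <- asPositive(labels)
    if (all(pos) || all(!pos)) stop("labels contain a single class")
    grid <- seq(0, 1, by = step)
    auc <- vapply(grid, function(w)
        aucRank(combineScores(sPsdsp, sKnf, c(w, 1 - w)), pos),
        numeric(1L))
    best <- max(auc)
    cand <- grid[auc >= best - 1e-12]
    w <- cand[order(abs(cand - 0.5), cand)][1L]
    c(psdsp = w, knf = 1 - w)
}

#' Calibrate specificity thresholds from negative scores
#'
#' For each nominal specificity q, the threshold is the smallest observed
#' score t such that at least a fraction q of the negative scores are
#' strictly below t (conservative empirical quantile). When no observed
#' score qualifies (e.g. all scores equal), a value just above the maximum
#' is returned with a warning. Thresholds are non-increasing as the
#' nominal specificity decreases.
#'
#' @param negScores numeric scores of negative samples (ideally
#'   out-of-fold); fewer than 100 triggers a warning.
#' @param specificities nominal specificities (default the server options
#'   0.99, 0.95, 0.90, 0.85).
#' @return named numeric thresholds (names = specificities).
#' @examples
#' calibrateThresholds(seq(0.01, 1, by = 0.01))["0.95"]  # 0.96
#' @export
calibrateThresholds <- function(negScores,
                                specificities = c(0.99, 0.95, 0.90, 0.85)) {
    n <- length(negScores)
    if (n == 0L) stop("no negative scores supplied")
    if (n < 100L)
        warning("calibrating on fewer than 100 negative scores; ",
                "thresholds will be coarse")
    u <- sort(unique(negScores))
    below <- vapply(u, function(v) sum(negScores < v), numeric(1L))
    out <- vapply(specificities, function(q) {
        ok <- u[below >= q * n]
        if (length(ok)) ok[1L]
        else {
            warning(sprintf(
                "no observed score attains %.0f%% specificity; using a value above the maximum",
                100 * q))
            max(negScores) + 1e-9
        }
    }, numeric(1L))
    names(out) <- as.character(specificities)
    out
}

#' Train the full ac4C motif meta-classifier
#'
#' End-to-end training: (1) stratified k-fold cross-validation on the
#' training set produces out-of-fold PSDSP and KNF forest scores (profiles
#' refitted per fold on the fold-training part only); (2) ensemble weights
#' are either the balanced default (0.5, 0.5) or grid-tuned on those
#' out-of-fold scores; (3) specificity thresholds are calibrated on the
#' out-of-fold meta scores of the negative training samples, leaving any
#' test set untouched; (4) the dinucleotide profile and both forests are
#' refitted on the complete training set.
#'
#' @param train a labeled \linkS4class{PacesSamples} with window >= 150.
#' @param nTrees trees per forest (default 800).
#' @param seed master integer seed (folds and forests derive from it).
#' @param tuneWeights logical; grid-tune the ensemble weights (default
#'   FALSE, keeping the balanced weights).
#' @param folds number of calibration CV folds (default 5).
#' @param windows named flank widths for the two encoders (defaults
#'   psdsp 138, knf 150).
#' @return a \linkS4class{PacesModel}.
#' @export
pacesTrain <- function(train, nTrees = 800L, seed = 1L,
                       tuneWeights = FALSE, folds = 5L,
                       windows = c(psdsp = 138L, knf = 150L)) {
    stopifnot(is(train, "PacesSamples"))
    cv <- crossValidate(train, encoders = c("psdsp", "knf"), k = folds,
                        seed = seed, nTrees = nTrees, windows = windows)
    w <- if (isTRUE(tuneWeights))
        tuneWeights(cv$scores[, "psdsp"], cv$scores[, "knf"], train@label)
    else c(psdsp = 0.5, knf = 0.5)
    metaOof <- combineScores(cv$scores[, "psdsp"], cv$scores[, "knf"], w)
    thresholds <- calibrateThresholds(metaOof[train@label == "negative"])
    reports <- c(cv$reports,
                 list(meta = computeMetrics(metaOof, train@label)))

    sPsdsp <- trimSamples(train, windows[["psdsp"]])
    profile <- fitPositionProfile(sPsdsp, order = 2L)
    fPsdsp <- trainForest(encodePSDSP(sPsdsp, profile), train@label,
                          nTrees = nTrees, seed = seed, encoding = "psdsp")
    sKnf <- trimSamples(train, windows[["knf"]])
    fKnf <- trainForest(encodeKNF(sKnf), train@label,
                        nTrees = nTrees, seed = seed, encoding = "knf")
    new("PacesModel",
        forestPSDSP = fPsdsp, forestKNF = fKnf, profile = profile,
        weights = w, thresholds = thresholds,
        windows = vapply(windows, as.integer, integer(1L)),
        seed = as.integer(seed), cvReports = reports)
}

#' Score samples with a trained meta-classifier
#'
#' @param model a \linkS4class{PacesModel}.
#' @param samples a \linkS4class{PacesSamples} with window >= the model's
#'   widest encoder window.
#' @return numeric meta scores in [0, 1].
#' @export
pacesScore <- function(model, samples) {
    stopifnot(is(model, "PacesModel"), is(samples, "PacesSamples"))
    sP <- predictScores(model@forestPSDSP,
        encodePSDSP(trimSamples(samples, model@windows[["psdsp"]]),
                    model@profile))
    sK <- predictScores(model@forestKNF,
        encodeKNF(trimSamples(samples, model@windows[["knf"]])))
    combineScores(sP, sK, model@weights)
}
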