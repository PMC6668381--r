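# Feature encodings: one-hot, position-specific (di)nucleotide sequence
# profiles (PSNSP/PSDSP), k-nucleotide frequencies (KNF) and k-spaced
# nucleotide pair frequencies (KSNPF). All encoders are total and
# deterministic on normalized samples; N (padding or ambiguity) never
# contributes to a count and maps to 0 in positional encodings.

#' Tuned flank widths per encoding
#'
#' Cross-validation-optimized total flank widths W for each encoding; the
#' encoded sample is the 15-nt motif plus W/2 nt per side.
#'
#' @return named integer vector over the five encodings.
#' @export
pacesWindows <- function() {
    c(onehot = 126L, psnsp = 144L, psdsp = 138L, knf = 150L, ksnpf = 144L)
}

# residues of a PacesSamples or a plain character vector
asResidues <- function(x) {
    if (is(x, "PacesSamples")) x@residues
    else as.character(normalizeSequences(x))
}

#' One-hot encoding
#'
#' Each position becomes a 4-bit block: C = (1,0,0,0), G = (0,1,0,0),
#' T = (0,0,1,0), A = (0,0,0,1); N = (0,0,0,0). Blocks are concatenated
#' 5' to 3'.
#'
#' @param x a \linkS4class{PacesSamples} or character vector of equal-length
#'   sequences.
#' @return numeric matrix, one row per sample, \code{4 * L} columns.
#' @examples
#' encodeOneHot("CNGA")
#' @export
encodeOneHot <- function(x) {
    res <- asResidues(x)
    M <- residueMatrix(res)
    L <- ncol(M)
    bitOrder <- c("C", "G", "T", "A")
    out <- matrix(0, nrow = nrow(M), ncol = 4L * L)
    for (b in seq_len(4L)) {
        hit <- M == bitOrder[b]
        out[, 4L * (seq_len(L) - 1L) + b] <- hit * 1
    }
    colnames(out) <- paste0("p", rep(seq_len(L), each = 4L), "_", bitOrder)
    out
}

#' Fit a position-specific sequence profile
#'
#' Estimates f(i, n) = N+(i, n)/Np - N-(i, n)/Nn over the labeled samples:
#' the difference between the fraction of positive and negative samples
#' carrying token n at position i. Order 1 counts single nucleotides
#' (PSNSP); order 2 counts the overlapping dinucleotide starting at each
#' position (PSDSP). Tokens containing N are not counted, so padded
#' positions contribute nothing to either class.
#'
#' @param train a labeled \linkS4class{PacesSamples}, or a character vector
#'   of equal-length sequences together with \code{labels}.
#' @param order 1 (nucleotide) or 2 (dinucleotide).
#' @param labels class labels when \code{train} is a character vector
#'   (ignored otherwise).
#' @return a \linkS4class{PositionProfile}.
#' @examples
#' fitPositionProfile(c("ACG", "ACG", "ATG", "TCG", "ACG"),
#'                    order = 1, labels = c(1, 1, 1, 0, 0))
#' @export
fitPositionProfile <- function(train, order = 2L, labels = NULL) {
    stopifnot(order %in% c(1L, 2L))
    order <- as.integer(order)
    if (is(train, "PacesSamples")) {
        residues <- train@residues
        lab <- train@label
        isPos <- lab == "positive"
        isNeg <- lab == "negative"
    } else {
        residues <- as.character(train)
        if (is.null(labels) || length(labels) != length(residues))
            stop("'labels' must accompany a plain sequence vector")
        isPos <- asPositive(labels)
        isNeg <- !isPos
    }
    np <- sum(isPos); nn <- sum(isNeg)
    if (np < 1L || nn < 1L)
        stop("profile fitting requires both a positive and a negative class")
    M <- residueMatrix(residues)
    L <- ncol(M)
    tokens <- if (order == 1L) BASES else DINUCS
    nPosRows <- L - (order - 1L)
    tab <- matrix(0, nrow = nPosRows, ncol = length(tokens),
                  dimnames = list(NULL, tokens))
    for (i in seq_len(nPosRows)) {
        tok <- if (order == 1L) M[, i] else paste0(M[, i], M[, i + 1L])
        fp <- factor(tok[isPos], levels = tokens)
        fn <- factor(tok[isNeg], levels = tokens)
        tab[i, ] <- tabulate(fp, length(tokens)) / np -
                    tabulate(fn, length(tokens)) / nn
    }
    new("PositionProfile", order = order, table = tab,
        nPos = as.integer(np), nNeg = as.integer(nn),
        sampleLength = as.integer(L))
}

# shared positional-profile encoder
encodeProfile <- function(x, profile) {
    stopifnot(is(profile, "PositionProfile"))
    res <- asResidues(x)
    M <- residueMatrix(res)
    ord <- profile@order
    if (ncol(M) != profile@sampleLength)
        stop(sprintf("samples have length %d but the profile was fitted on length %d",
                     ncol(M), profile@sampleLength))
    nPosRows <- ncol(M) - (ord - 1L)
    tokens <- colnames(profile@table)
    out <- matrix(0, nrow = nrow(M), ncol = nPosRows)
    for (i in seq_len(nPosRows)) {
        tok <- if (ord == 1L) M[, i] else paste0(M[, i], M[, i + 1L])
        idx <- match(tok, tokens)          # NA for tokens containing N
        v <- profile@table[i, ]
        out[, i] <- ifelse(is.na(idx), 0, v[idx])
    }
    colnames(out) <- paste0("p", seq_len(nPosRows))
    out
}

#' Position-specific nucleotide profile encoding (PSNSP)
#'
#' Replaces each nucleotide by its fitted f(i, n) value; N maps to 0.
#'
#' @inheritParams encodeOneHot
#' @param profile an order-1 \linkS4class{PositionProfile} fitted on
#'   samples of the same length.
#' @return numeric matrix, \code{L} columns.
#' @export
encodePSNSP <- function(x, profile) {
    if (profile@order != 1L) stop("PSNSP requires an order-1 profile")
    encodeProfile(x, profile)
}

#' Position-specific dinucleotide profile encoding (PSDSP)
#'
#' Replaces the dinucleotide at positions (i, i+1) by its fitted f(i, n)
#' value; pairs containing N map to 0.
#'
#' @inheritParams encodeOneHot
#' @param profile an order-2 \linkS4class{PositionProfile} fitted on
#'   samples of the same length.
#' @return numeric matrix, \code{L - 1} columns.
#' @export
encodePSDSP <- function(x, profile) {
    if (profile@order != 2L) stop("PSDSP requires an order-2 profile")
    encodeProfile(x, profile)
}

#' K-nucleotide frequency encoding (KNF)
#'
#' Occurrence frequencies of all overlapping k-mers for k in \code{ks},
#' each k-block normalized by its own number of N-free windows so that a
#' block sums to 1 whenever any valid window exists. k-mers are ordered
#' lexicographically (A < C < G < T); blocks are concatenated in k order.
#' The default k = 2, 3, 4 yields 16 + 64 + 256 = 336 features.
#'
#' @inheritParams encodeOneHot
#' @param ks integer vector of k-mer sizes.
#' @return numeric matrix with \code{sum(4^ks)} columns.
#' @examples
#' v <- encodeKNF("ACGTACGTACGTACGT")
#' sum(v[1, 1:16])   # dinucleotide block sums to 1
#' @importFrom Biostrings oligonucleotideFrequency
#' @export
encodeKNF <- function(x, ks = c(2L, 3L, 4L)) {
    res <- asResidues(x)
    xs <- Biostrings::DNAStringSet(res)
    L <- nchar(res[1L])
    blocks <- lapply(sort(as.integer(ks)), function(k) {
        if (L < k) {
            m <- matrix(0, nrow = length(res), ncol = 4L^k)
            colnames(m) <- paste0("k", k, "_",
                                  Biostrings::mkAllStrings(BASES, k))
            return(m)
        }
        cnt <- Biostrings::oligonucleotideFrequency(xs, width = k)
        tot <- rowSums(cnt)                 # N-free windows only
        frq <- cnt / ifelse(tot > 0, tot, 1)
        frq[tot == 0, ] <- 0
        colnames(frq) <- paste0("k", k, "_", colnames(cnt))
        frq
    })
    do.call(cbind, blocks)
}

#' K-spaced nucleotide pair frequency encoding (KSNPF)
#'
#' For each spacing k in \code{ks}, the frequencies of the 16 ordered
#' nucleotide pairs (a, b) with exactly k arbitrary residues between them,
#' normalized per k by the number of windows whose a and b are both
#' determined (non-N). The default k = 0..4 yields 16 x 5 = 80 features.
#'
#' @inheritParams encodeOneHot
#' @param ks integer vector of spacings (number of skipped residues).
#' @return numeric matrix with \code{16 * length(ks)} columns.
#' @examples
#' v <- encodeKSNPF("ACGTACGTACGTACGT")
#' dim(v)
#' @export
encodeKSNPF <- function(x, ks = 0:4) {
    res <- asResidues(x)
    M <- residueMatrix(res)
    L <- ncol(M)
    code <- matrix(match(M, BASES), nrow = nrow(M))  # NA for N
    blocks <- lapply(as.integer(ks), function(k) {
        out <- matrix(0, nrow = nrow(M), ncol = 16L,
                      dimnames = list(NULL, paste0(
                          "s", k, "_",
                          rep(BASES, each = 4L), rep(BASES, 4L))))
        nWin <- L - k - 1L
        if (nWin < 1L) return(out)
        a <- code[, seq_len(nWin), drop = FALSE]
        b <- code[, seq_len(nWin) + k + 1L, drop = FALSE]
        idx <- 4L * (a - 1L) + b
        valid <- rowSums(!is.na(idx))
        for (v in seq_len(16L))
            out[, v] <- rowSums(idx == v, na.rm = TRUE)
        out <- out / ifelse(valid > 0, valid, 1)
        out[valid == 0, ] <- 0
        out
    })
    do.call(cbind, blocks)
}

#' Encode samples under a named encoding
#'
#' Dispatcher used by the training and prediction pipelines. Positional
#' encodings (\code{psnsp}, \code{psdsp}) require a fitted profile of the
#' matching order.
#'
#' @inheritParams encodeOneHot
#' @param encoding one of \code{"onehot"}, \code{"psnsp"}, \code{"psdsp"},
#'   \code{"knf"}, \code{"ksnpf"}.
#' @param profile a \linkS4class{PositionProfile} for the positional
#'   encodings, otherwise ignored.
#' @return numeric feature matrix, one row per sample.
#' @export
encodeFeatures <- function(x, encoding, profile = NULL) {
    encoding <- match.arg(encoding,
        c("onehot", "psnsp", "psdsp", "knf", "ksnpf"))
    switch(encoding,
        onehot = encodeOneHot(x),
        psnsp = encodePSNSP(x, profile),
        psdsp = encodePSDSP(x, profile),
        knf = encodeKNF(x),
        ksnpf = encodeKSNPF(x))
}
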