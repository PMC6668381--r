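# Internal helpers shared across modules.

# Run code under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    force(code)
}

#' Normalize nucleotide sequences
#'
#' Uppercases, maps RNA uracil (U) to T, and replaces any residue outside
#' the A,C,G,T,N alphabet with N (with a warning). Accepts a character
#' vector, a \link[Biostrings]{DNAStringSet}, \code{RNAStringSet} or
#' \code{BStringSet}; always returns a \code{DNAStringSet}.
#'
#' @param x sequences (character vector or XStringSet); names are kept and
#'   invented (\code{seq1}, \code{seq2}, ...) when absent.
#' @return a \link[Biostrings]{DNAStringSet} over A,C,G,T,N.
#' @examples
#' normalizeSequences(c(tx = "acguACGU"))
#' @importFrom Biostrings DNAStringSet
#' @export
normalizeSequences <- function(x) {
    s <- toupper(as.character(x))
    s <- chartr("U", "T", s)
    if (any(grepl("[^ACGTN]", s))) {
        warning("residues outside A,C,G,T,U,N replaced with N")
        s <- vapply(s, function(z) gsub("[^ACGTN]", "N", z), character(1L),
                    USE.NAMES = FALSE)
    }
    nm <- names(x)
    if (is.null(nm) || any(nm == ""))
        nm <- if (is.null(nm)) paste0("seq", seq_along(s))
              else ifelse(nm == "", paste0("seq", seq_along(s)), nm)
    out <- Biostrings::DNAStringSet(s)
    names(out) <- nm
    out
}

# Split sequences into a per-sample character matrix (n x L); all inputs
# must share the same length L.
residueMatrix <- function(residues) {
    L <- unique(nchar(residues))
    stopifnot(length(L) == 1L)
    matrix(unlist(strsplit(residues, "", fixed = TRUE), use.names = FALSE),
           ncol = L, byrow = TRUE)
}

# Tokens in fixed lexicographic order (A < C < G < T).
BASES <- c("A", "C", "G", "T")
DINUCS <- as.vector(t(outer(BASES, BASES, paste0)))
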