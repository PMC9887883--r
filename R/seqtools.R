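#' @importFrom Biostrings DNAString RNAString DNAStringSet RNAStringSet
#'   reverseComplement
NULL

.OLIGO_ALPHABET <- c("A", "C", "G", "U", "T")

.checkAlphabet <- function(seq) {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% .OLIGO_ALPHABET)
    if (length(bad))
        stop(sprintf("invalid character '%s' at position %d (alphabet ACGUT)",
                     chars[bad[1L]], bad[1L]), call. = FALSE)
    chars
}

#' Reverse complement of a DNA or RNA sequence
#'
#' Preserves the input alphabet: a sequence containing U is complemented as
#' RNA (A -> U), otherwise as DNA (A -> T); `rna` overrides the detection
#' for sequences containing neither U nor T. Sequences mixing U and T are
#' rejected. Backed by [Biostrings::reverseComplement()].
#'
#' @param seq Character scalar over A/C/G/U/T (case-insensitive; case is
#'   not preserved — output is upper case).
#' @param rna Logical; force RNA (`TRUE`) or DNA (`FALSE`) complementation.
#'   Default `NA` detects from the sequence (DNA when ambiguous).
#' @return Character scalar, the reverse complement.
#' @examples
#' revComp("GGUACUGCGCU")   # "AGCGCAGUACC"
#' revComp(revComp("ACGU")) # involution
#' @export
revComp <- function(seq, rna = NA) {
    stopifnot(is.character(seq), length(seq) == 1L)
    if (!nzchar(seq)) return("")
    chars <- .checkAlphabet(seq)
    if ("U" %in% chars && "T" %in% chars)
        stop("sequence mixes U and T; use one alphabet", call. = FALSE)
    isRNA <- if (is.na(rna)) "U" %in% chars else isTRUE(rna)
    if (isRNA && "T" %in% chars)
        stop("cannot complement a T-containing sequence as RNA",
             call. = FALSE)
    if (!isRNA && "U" %in% chars)
        stop("cannot complement a U-containing sequence as DNA",
             call. = FALSE)
    s <- paste(chars, collapse = "")
    if (isRNA)
        as.character(reverseComplement(RNAString(s)))
    else
        as.character(reverseComplement(DNAString(s)))
}

.complementary <- function(x, y) {
    # U and T are equivalent; optional G.U wobble
    x <- ifelse(x == "T", "U", x)
    y <- ifelse(y == "T", "U", y)
    wc <- (x == "A" & y == "U") | (x == "U" & y == "A") |
          (x == "G" & y == "C") | (x == "C" & y == "G")
    wc
}

.wobble <- function(x, y) {
    x <- ifelse(x == "T", "U", x)
    y <- ifelse(y == "T", "U", y)
    (x == "G" & y == "U") | (x == "U" & y == "G")
}

#' Anneal two oligonucleotides and report the duplex geometry
#'
#' Exhaustively scores every ungapped antiparallel register of two strands
#' by Watson-Crick complementarity (U and T equivalent; G.U wobble pairs
#' only when `wobble = TRUE`) and reports the register with the most paired
#' bases, breaking ties toward the smallest register offset. The report
#' gives the number of paired bases, the 5'/3' single-stranded overhang of
#' each strand (measured from the outermost paired base) and the paired
#' fraction of all nucleotides.
#'
#' With the two RNA strands used in an in vitro helicase unwinding substrate
#' — an 11-mer annealed to a 22-mer whose 5' half is its perfect complement
#' — this reports an 11-bp duplex leaving an 11-nt 3' single-stranded
#' extension on the long strand.
#'
#' @param a,b Character scalars, the two strands 5' to 3' (A/C/G/U/T).
#' @param wobble Logical; also count G.U pairs. Default `FALSE`.
#' @return A list of class `"duplexReport"` with elements `offset`,
#'   `duplexLength` (number of paired bases), `a5Overhang`, `a3Overhang`,
#'   `b5Overhang`, `b3Overhang` and `pairedFraction`. Overhangs are `NA`
#'   when no base pairs at all.
#' @examples
#' rep <- annealOligos("AGCGCAGUACC", "GGUACUGCGCUUUUAUGACAUC")
#' rep$duplexLength  # 11
#' rep$b3Overhang    # 11-nt 3' extension on the long strand
#' @export
annealOligos <- function(a, b, wobble = FALSE) {
    stopifnot(is.character(a), is.character(b),
              nzchar(a), nzchar(b))
    av <- .checkAlphabet(a)
    bv <- .checkAlphabet(b)
    n <- length(av)
    m <- length(bv)
    brev <- rev(bv)                       # brev[k] pairs a positions; brev[k] = b[m+1-k]
    best <- list(score = -1L, d = NA_integer_, ai = integer(), bj = integer())
    for (d in seq(-(n - 1L), m - 1L)) {   # a[i] aligns brev[i + d]
        i <- seq_len(n)
        k <- i + d
        keep <- k >= 1L & k <= m
        i <- i[keep]; k <- k[keep]
        ok <- .complementary(av[i], brev[k])
        if (wobble) ok <- ok | .wobble(av[i], brev[k])
        score <- sum(ok)
        if (score > best$score) {
            best <- list(score = score, d = d, ai = i[ok],
                         bj = m + 1L - k[ok])
        }
    }
    paired <- best$score
    if (paired > 0L) {
        a5 <- min(best$ai) - 1L
        a3 <- n - max(best$ai)
        b5 <- min(best$bj) - 1L
        b3 <- m - max(best$bj)
    } else {
        a5 <- a3 <- b5 <- b3 <- NA_integer_
    }
    structure(list(offset = best$d, duplexLength = paired,
                   a5Overhang = a5, a3Overhang = a3,
                   b5Overhang = b5, b3Overhang = b3,
                   pairedFraction = 2 * paired / (n + m)),
              class = "duplexReport")
}

#' @export
print.duplexReport <- function(x, ...) {
    cat(sprintf("Duplex: %d paired bases (offset %d, paired fraction %.2f)\n",
                x$duplexLength, x$offset, x$pairedFraction))
    cat(sprintf("  strand a overhangs 5'/3': %s / %s nt\n",
                x$a5Overhang, x$a3Overhang))
    cat(sprintf("  strand b overhangs 5'/3': %s / %s nt\n",
                x$b5Overhang, x$b3Overhang))
    invisible(x)
}

#' Trim a 3' adaptor and apply the CLIP length floor
#'
#' Removes everything from the first exact occurrence of the adaptor
#' onward; when the full adaptor is absent, the longest adaptor prefix of
#' at least `minPrefix` nt found at the read's 3' terminus is trimmed
#' instead. Reads lacking any adaptor match are returned unmodified. A read
#' is kept only if the trimmed length is at least `minLen` (default 15 nt,
#' the CLIP processing floor). No error tolerance: matching is exact.
#'
#' @param reads Character vector of read sequences.
#' @param adaptor Character scalar, the 3' adaptor sequence (non-empty).
#' @param minLen Minimum post-trim length to keep a read. Default 15.
#' @param minPrefix Minimum terminal adaptor-prefix length to trim.
#'   Default 6.
#' @return `data.frame` with columns `read` (input), `trimmed` and
#'   `kept` (logical).
#' @examples
#' trimFilter("ACGTACGTACGTACGTACAGATCGGAAG", "AGATCGGAAGAGC")
#' @export
trimFilter <- function(reads, adaptor, minLen = 15L, minPrefix = 6L) {
    stopifnot(is.character(reads), is.character(adaptor),
              length(adaptor) == 1L, nzchar(adaptor))
    nA <- nchar(adaptor)
    trimmed <- vapply(reads, function(r) {
        hit <- regexpr(adaptor, r, fixed = TRUE)
        if (hit > 0L) return(substr(r, 1L, hit - 1L))
        nR <- nchar(r)
        for (k in seq(min(nA - 1L, nR), minPrefix)) {
            if (k < minPrefix) break
            if (substr(r, nR - k + 1L, nR) == substr(adaptor, 1L, k))
                return(substr(r, 1L, nR - k))
        }
        r
    }, character(1L), USE.NAMES = FALSE)
    data.frame(read = reads, trimmed = trimmed,
               kept = nchar(trimmed) >= minLen, stringsAsFactors = FALSE)
}
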