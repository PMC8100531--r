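#' @importFrom stats dnbinom median p.adjust phyper rnbinom runif rpois var
#'   hclust dist lm coef setNames qchisq fitted
#' @importFrom utils head write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over DNA character strings (A/C/G/T/N).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
str_hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# Random DNA strings of given lengths.
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

# Normalise sequences for comparison: upper case, RNA U -> DNA T.
normalize_seq <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

assert_acgt <- function(x, what = "sequence") {
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters: %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# Mean Phred score of a Phred+33 encoded quality string.
mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
}

# Fraction of ambiguous (N) bases per sequence.
n_fraction <- function(seq) {
  n <- nchar(seq)
  nn <- n - nchar(gsub("N", "", seq, fixed = TRUE))
  ifelse(n == 0L, 1, nn / n)
}

new_read_set <- function(read_id, seq, qual) {
  stopifnot(length(read_id) == length(seq), length(seq) == length(qual))
  if (length(seq) && any(nchar(seq) != nchar(qual))) {
    stop("sequence and quality strings must have equal lengths", call. = FALSE)
  }
  tibble::tibble(read_id = read_id, seq = seq, qual = qual)
}
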