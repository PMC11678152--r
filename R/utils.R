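#' @useDynLib srnaigr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# base coding shared with the compiled kernels: A=0, C=1, G=2, T/U=3, other -1
seq_to_codes <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  m <- match(x, c("A", "C", "G", "T", "U"))
  m[m == 5L] <- 4L
  m[is.na(m)] <- 0L
  as.integer(m - 1L)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

collapse_chars <- function(x) paste(x, collapse = "")

#' Reverse complement of a DNA/RNA character vector
#'
#' Gaps (`-`) are preserved, `U` maps to `A`. Works on plain character
#' vectors; [Biostrings::reverseComplement()] is used for `DNAStringSet`
#' inputs elsewhere.
#'
#' @param seq character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    x <- rev(seq_chars(chartr("ACGTUacgtu", "TGCAATGCAA", s)))
    collapse_chars(x)
  }, character(1), USE.NAMES = FALSE)
}

# run code under a temporary RNG state when seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  collapse_chars(sample(names(p), n, replace = TRUE, prob = p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
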