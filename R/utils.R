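# Shared low-level helpers: sequence handling, alignment wrappers, RNG scoping,
# condition constructors. Everything here is internal.

#' @importFrom stats rnorm runif rlnorm sd cor.test lm coef pnorm setNames
#' @importFrom utils head tail write.table read.table
NULL

mk_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mitekit_error")))
}

#' Run code with a locally-seeded RNG
#'
#' Saves and restores `.Random.seed` so seeded operations are pure functions
#' of their inputs and never disturb the caller's RNG stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    mk_error("seed must be a single integer", "mitekit_parameter_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N
#' @return character scalar
#' @export
#' @examples
#' revcomp("GGCCTTGTTCGGTT")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# integer encoding A=0 C=1 G=2 T=3, N/other = NA
seq_to_int <- function(x) {
  v <- utf8ToInt(toupper(x))
  out <- rep(NA_integer_, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

int_to_seq <- function(b) {
  chars <- c("A", "C", "G", "T")[b + 1L]
  chars[is.na(b)] <- "N"
  paste(chars, collapse = "")
}

random_dna <- function(n, at = 0.5) {
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Global (Needleman-Wunsch) alignment with the package-wide scoring scheme
# (match +1, mismatch -1, gap -2, linear). Returns the two gapped rows.
nw_align <- function(a, b) {
  .nw_align_cpp(toupper(a), toupper(b))
}

# Identity over the full global alignment, end gaps included:
# matching columns / alignment length.
alignment_identity <- function(row_a, row_b) {
  ca <- strsplit(row_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(row_b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  sum(ca == cb & ca != "-") / length(ca)
}

# Vectorised: identity of one subject against many patterns in one call.
pairwise_identity_set <- function(patterns, subject) {
  .nw_identity_cpp(toupper(patterns), toupper(subject))
}

validate_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTNacgtn]*$" else "^[ACGTacgt]*$"
  if (!grepl(pat, x)) {
    mk_error(sprintf("%s contains symbols outside the %s alphabet",
                     what, if (allow_n) "A/C/G/T/N" else "A/C/G/T"),
             "mitekit_alphabet_error")
  }
  invisible(TRUE)
}
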