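# shared internal helpers

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats qnorm pnorm pchisq qt pt rnorm sd mad median var cor
#'   complete.cases setNames dnorm runif lm glm binomial coef vcov approx
#' @importFrom utils head tail modifyList
NULL

VALID_CHROMS <- c(as.character(1:22), "X", "Y", "MT")

#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix, uppercases, and maps "M" to "MT" so that
#' labels from different sources ("chr7", "7", "chrM") compare equal.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels ("1".."22", "X", "Y", "MT";
#'   unrecognized labels are passed through unchanged).
#' @export
normalize_chrom <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^CHR", "", x)
  x[x == "M"] <- "MT"
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x
}

is_palindromic <- function(ea, nea) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ok <- ea %in% names(comp) & nea %in% names(comp)
  out <- rep(FALSE, length(ea))
  out[ok] <- unname(comp[ea[ok]]) == nea[ok]
  out
}

complement_alleles <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# one user seed -> deterministic derived substream seeds (kept < 2^31)
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%null%` <- function(a, b) if (is.null(a)) b else a
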