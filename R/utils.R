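#' @useDynLib splicecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom runif rnorm median cor fisher.test wilcox.test
#'   ks.test plogis quantile setNames sd
#' @importFrom utils read.delim write.table head
NULL

BASES <- c("A", "C", "G", "T")

CATEGORIES <- c("upstream", "acc_overlap", "exonic",
                "spanning", "don_overlap", "downstream")

CELL_TYPES <- c("neuron", "glia")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] for plain character
#' vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

## derive a stream-specific 32-bit seed from a master seed, so that the
## generators for genome / peaks / reads / variants / folds stay independent
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- c(genome = 11L, grammar = 23L, peaks = 37L, reads = 51L,
            variants = 67L, downsample = 83L, folds = 97L, model = 113L)
  if (!stream %in% names(offs)) stop("unknown seed stream: ", stream)
  (as.integer(seed) %% 1000003L) * 1009L + offs[[stream]]
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop("'", name, "' must be a single integer >= ", min)
  }
}

#' Encode / decode exon-interval chains
#'
#' Read chains store the ordered exon intervals of one molecule as a
#' semicolon-delimited string of `start-end` pairs in 0-based half-open
#' coordinates, sorted by genomic position.
#'
#' @param ivs for [encode_chain()], a two-column matrix (start, end).
#' @param x for [decode_chain()], a character vector of encoded chains.
#' @return `encode_chain()` a string; `decode_chain()` a list of matrices.
#' @export
encode_chain <- function(ivs) {
  paste(sprintf("%d-%d", ivs[, 1L], ivs[, 2L]), collapse = ";")
}

#' @rdname encode_chain
#' @export
decode_chain <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(parts) {
    m <- matrix(as.integer(unlist(strsplit(parts, "-", fixed = TRUE))),
                ncol = 2L, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  })
}
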