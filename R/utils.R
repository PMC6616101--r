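#' @keywords internal
"_PACKAGE"

#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom methods is
#' @importFrom stats median pbinom pnorm quantile rnbinom rpois runif rnorm
#'   rbinom cor.test hclust cutree as.dist setNames
#' @importFrom utils write.table read.table
NULL

# RNA alphabet used throughout; sequences are handled on the sense strand
# after transcription (T -> U).
APA_BASES <- c("A", "C", "G", "U")

rna <- function(x) chartr("Tt", "Uu", toupper(x))

dna <- function(x) chartr("Uu", "Tt", toupper(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# population (not sample) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# relative coordinate axis around a cleavage site: -up..-1, +1..+down
# (there is no position 0; -1 is the last templated nucleotide).
rel_positions <- function(window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  setdiff(seq(window[1], window[2]), 0L)
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
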