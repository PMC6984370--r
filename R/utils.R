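## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

## Repeat-class vocabulary used throughout (RepeatMasker major classes plus the
## implicit Unmasked complement).
REPEAT_CLASSES <- c("LINE", "SINE", "LTR", "DNA", "Simple_repeat", "Satellite",
                    "RNA", "Low_complexity", "Other", "Unmasked")

#' Repeat-class vocabulary
#'
#' The fixed ten-class vocabulary used by all repeat-composition functions:
#' the major RepeatMasker classes plus \code{"Unmasked"} for unannotated bases.
#'
#' @return Character vector of class names.
#' @export
#' @examples
#' repeatClasses()
repeatClasses <- function() REPEAT_CLASSES

## Derive a 31-bit substream seed from a master seed and a stream name, so each
## emission stage of the simulator draws from an independent, reproducible
## stream. Simple polynomial string hash folded with the master seed.
substreamSeed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (v in utf8ToInt(stream)) h <- (h * 131 + v) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 2654435) %% 2147483647)
}

## Evaluate `expr` under the RNG substream (seed, stream), restoring the
## caller's RNG state afterwards.
withSubstream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(seed, stream))
  expr
}

randomDna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## All k-mers of a character sequence as a character vector (positions 1..n-k+1).
seqKmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

## Split a contig name on the LAST underscore into (individual_id, local_id).
splitContigName <- function(names) {
  pos <- regexpr("_[^_]*$", names)
  bad <- pos < 0L
  if (any(bad))
    stop("contig name(s) without an underscore: ",
         paste(utils::head(names[bad], 3L), collapse = ", "))
  list(individual = substr(names, 1L, pos - 1L),
       local = substr(names, pos + 1L, nchar(names)))
}

## 0-based half-open interval overlap length.
overlapLen <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))
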