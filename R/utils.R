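#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across
#' @importFrom stats setNames sd rexp runif
NULL

# shared lookup cache (genetic-code tables, NG pair matrices)
.mc_cache <- new.env(parent = emptyenv())

#' Reverse complement of a nucleotide string
#'
#' Strict reverse complement over `A,C,G,T,N` (case-insensitive input,
#' uppercase output). Used everywhere a minus-strand feature is put back in
#' coding orientation.
#'
#' @param seq Single nucleotide string.
#' @return Single string, the reverse complement.
#' @examples
#' revcomp("TTTCAT") # "ATGAAA"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# Round half away from zero (Table-style formatting; R's round() is
# round-half-even, which disagrees with how the reference tables are printed).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # epsilon guards against 0.145 * 100 representing as 14.499999...
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Validate a nucleotide sequence
#'
#' Accepts only `A,C,G,T,N`; any other IUPAC ambiguity code is rejected with an
#' error naming the offending characters (shorebird mitogenome deposits contain
#' none, and silently reinterpreting ambiguity codes would corrupt skew counts).
#'
#' @param seq Nucleotide string.
#' @param what Label used in the error message.
#' @return The uppercased sequence, invisibly usable.
#' @keywords internal
validate_sequence <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- setdiff(unique(seq_chars(seq)), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s contains unsupported characters: %s (only A,C,G,T,N are allowed)",
      what, paste(bad, collapse = ", ")
    ))
  }
  seq
}
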