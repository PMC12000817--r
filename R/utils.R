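# internal helpers shared across modules

# round half away from zero, matching the printed precision convention
# (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# format error with a stable condition class so callers can trap parse
# failures distinctly from programming errors
format_error <- function(message, path = NULL, line = NULL) {
  loc <- c(
    if (!is.null(path)) paste0("file: ", path),
    if (!is.null(line)) paste0("line: ", line)
  )
  abort(c(message, loc), class = "mitovult_format_error")
}

# reverse complement of a DNA string (may contain N)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# pull a single sequence string out of whatever the caller handed us:
# a bare string, or a tibble from read_fasta() (first record)
as_sequence <- function(x, arg = "genome") {
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  if (is.data.frame(x)) {
    if (!"sequence" %in% names(x) || nrow(x) < 1L) {
      abort(sprintf("`%s` must contain a `sequence` column with >= 1 row", arg))
    }
    return(toupper(x$sequence[[1L]]))
  }
  abort(sprintf("`%s` must be a single string or a data frame of sequences", arg))
}

AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

DNA_BASES <- c("A", "C", "G", "T")

ALL_CODONS <- sort(as.vector(outer(
  outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0
)))
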