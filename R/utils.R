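# internal helpers shared across modules

# derive a stage-specific seed from a root seed; stays below 2^31
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101L + 7919 * offset) %% 2147483587)
}

# standard twenty amino acids
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# extended alphabet accepted on input (Asx/Glx/Xaa/Sec/Pyl ambiguity codes)
.AA_EXTENDED <- c(.AA20, "B", "J", "O", "U", "X", "Z")

reverseSequences <- function(seqs) {
  vapply(strsplit(seqs, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  as.integer(x)
}

assertFraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop("'", name, "' must lie in [", lo, ", ", hi, "]", call. = FALSE)
  as.numeric(x)
}
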