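## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

.is_dna <- function(x) {
  !is.na(x) & grepl("^[ACGT]*$", x)
}

.assert_dna <- function(x, what = "sequence") {
  bad <- which(!.is_dna(x))
  if (length(bad) > 0L) {
    stop(sprintf("non-ACGT character in %s at entry %d: '%s'",
                 what, bad[1L], x[bad[1L]]), call. = FALSE)
  }
  invisible(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Fraction of G/C in each string; NA for empty strings.
gcFraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[AT]", "", x))
  ifelse(n == 0L, NA_real_, gc / n)
}

## Convert an upstream position (negative, -1 = last base of reg_seq) to a
## 1-based string index in a sequence of length L, and back.
.pos_to_idx <- function(pos, L) L + pos + 1L
.idx_to_pos <- function(idx, L) idx - L - 1L

## Deterministic child seeds derived from one user seed (kept < 2^31).
.seed_stream <- function(seed, k) {
  ((as.numeric(seed) %% 1000003) * 1009 + 97 * as.numeric(k)) %% 2147483647
}

.pearson <- function(x, y) {
  stats::cor(x, y, method = "pearson")
}
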