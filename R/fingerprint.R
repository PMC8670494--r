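#' Parse a molecular fingerprint bitstring
#'
#' Converts a '0'/'1' character string (e.g. a 1,024-bit molecular
#' fingerprint) to a numeric 0/1 vector, order preserved.
#'
#' @param bitstring Non-empty string over the alphabet `{0,1}`.
#' @return Numeric vector of 0s and 1s with the same length as the string.
#' @examples
#' parse_fingerprint("1011")  # c(1, 0, 1, 1)
#' @export
parse_fingerprint <- function(bitstring) {
  tml_assert(is.character(bitstring) && length(bitstring) == 1 &&
               nzchar(bitstring),
             "tml_format_error", "fingerprint bitstring must be a non-empty string")
  chars <- strsplit(bitstring, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("0", "1"))
  if (length(bad) > 0) {
    tml_stop("tml_format_error",
             "illegal fingerprint character '%s' at position %d",
             chars[bad[1]], bad[1])
  }
  as.numeric(chars == "1")
}

## Expand a character column of equal-length bitstrings into a binary matrix
## with zero-padded column names fp_0000, fp_0001, ...
expand_fingerprint_column <- function(bits, prefix = "fp") {
  vecs <- lapply(bits, parse_fingerprint)
  len <- lengths(vecs)
  tml_assert(length(unique(len)) == 1, "tml_format_error",
             "fingerprint bitstrings have inconsistent lengths (%s)",
             paste(unique(len), collapse = ", "))
  m <- do.call(rbind, vecs)
  width <- max(4, nchar(as.character(len[1] - 1)))
  colnames(m) <- sprintf("%s_%0*d", prefix, width, seq_len(ncol(m)) - 1)
  m
}
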