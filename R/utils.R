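#' @importFrom rlang abort %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols across n distinct pull rename if_else
#'   row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_lgl map2 map2_int pmap imap
#'   list_rbind
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# Reverse a character string (single element).
str_rev <- function(x) {
  intToUtf8(rev(utf8ToInt(x)))
}

# Complement / reverse-complement of a DNA string over {A,C,G,T}.
dna_complement <- function(x) chartr("ACGT", "TGCA", x)

dna_revcomp <- function(x) str_rev(dna_complement(x))

DNA_BASES <- c("A", "C", "G", "T")

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T}: %s",
                  what, paste(head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

# Truncated (floored) display value, the convention used for cohort-level
# frequency columns; a tiny epsilon guards against binary representation of
# exact decimals landing just below an integer grid point.
trunc_digits <- function(x, digits) {
  floor(x * 10^digits + 1e-9) / 10^digits
}

round_digits <- function(x, digits) {
  round(x + 1e-12, digits)
}

# 0-based index of the first differing character of two strings, or NA if one
# is a prefix of the other (then the caller uses the shorter length), or NA
# when identical.
first_mismatch <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0L) {
    ra <- utf8ToInt(substr(a, 1L, n))
    rb <- utf8ToInt(substr(b, 1L, n))
    i <- which(ra != rb)
    if (length(i)) return(i[1L] - 1L)
  }
  if (nchar(a) == nchar(b)) NA_integer_ else n
}
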