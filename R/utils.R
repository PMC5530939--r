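# Internal helpers shared across the package.

# Read a '#'-commented, tab-separated file into a character data frame with
# exactly n_fields columns, reporting the 1-based line number of the first
# malformed row.
read_tsv_fields <- function(path, n_fields, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, paste(path, collapse = ", ")),
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(keep)) {
    out <- as.data.frame(matrix(character(), 0L, n_fields),
                         stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != n_fields)
  if (length(bad)) {
    stop(sprintf(
      "malformed line %d in %s: expected %d tab-separated fields, found %d",
      keep[bad[1L]], path, n_fields, lengths(fields)[bad[1L]]),
      call. = FALSE)
  }
  as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
}

# Jaccard index of two sets given as character vectors.
jaccard_index <- function(x, y) {
  length(intersect(x, y)) / length(union(x, y))
}

# Locale-independent lexicographic minimum (radix sort ignores collation).
lex_min <- function(x) sort(x, method = "radix")[1L]

lex_sort <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
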