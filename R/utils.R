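#' @keywords internal
"_PACKAGE"

## Shared internal helpers.

# stop() without the call, used for user-facing contract errors
ykc_stop <- function(...) stop(..., call. = FALSE)

ykc_assert <- function(cond, ...) if (!isTRUE(cond)) ykc_stop(...)

# Normalise a diagnosis/procedure code for prefix matching: upper case,
# dots removed, surrounding whitespace stripped.
norm_code <- function(x) gsub(".", "", toupper(trimws(x)), fixed = TRUE)

# TRUE where `code` starts with any entry of `prefixes` (both normalised)
match_any_prefix <- function(code, prefixes) {
  if (length(prefixes) == 0L || length(code) == 0L) {
    return(rep(FALSE, length(code)))
  }
  code <- norm_code(code)
  prefixes <- norm_code(prefixes)
  out <- rep(FALSE, length(code))
  for (p in prefixes) out <- out | startsWith(code, p)
  out
}

# Expand an ICD/OPCS style range "I21-I23" or "K40-K46" into its members.
# Entries without a dash pass through unchanged.
expand_code_range <- function(x) {
  out <- lapply(x, function(entry) {
    entry <- trimws(entry)
    if (!grepl("^([A-Za-z]+)([0-9]+)-\\1?([0-9]+)$", entry)) {
      return(entry)
    }
    m <- regmatches(entry, regexec("^([A-Za-z]+)([0-9]+)-[A-Za-z]*([0-9]+)$", entry))[[1]]
    lo <- as.integer(m[3]); hi <- as.integer(m[4])
    ykc_assert(lo <= hi, "invalid code range: ", entry)
    width <- nchar(m[3])
    paste0(m[2], formatC(lo:hi, width = width, flag = "0"))
  })
  unlist(out, use.names = FALSE)
}

# 95% Wald interval half-width multiplier used throughout (gamma +/- 1.96 se)
Z95 <- 1.96
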