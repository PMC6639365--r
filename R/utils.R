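# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a parent seed and one or more integer
# tags, staying inside the 32-bit integer range.
child_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (t in tags) x <- (x * 69069 + as.double(t)) %% 2147483647
  as.integer(x)
}

stop_bad_line <- function(path, lineno, line, expected) {
  stop(sprintf("malformed line %d in '%s' (expected %s): %s",
               lineno, path, expected, line), call. = FALSE)
}

# Read a whitespace/tab-delimited text file, dropping '#' comments and blank
# lines; returns a list of character vectors plus original line numbers.
read_delim_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  list(fields = fields, lineno = which(keep), raw = lines[keep])
}
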