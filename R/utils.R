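#' @useDynLib promoscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbinom rpois rnorm rbeta rgamma runif setNames wilcox.test aggregate
#' @importFrom utils combn read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Encode a DNA string as integers 1..4; lowercase (soft-masked), N/n and any
# other IUPAC ambiguity code become 0 and score zero in every window.
encode_seq <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  m <- match(chars, DNA_BASES)
  m[is.na(m)] <- 0L
  as.integer(m)
}

decode_seq <- function(v, masked_char = "n") {
  out <- c(masked_char, DNA_BASES)[v + 1L]
  paste(out, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic sub-stream seed derived from a global seed and a string key,
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores
# (or removes) the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Merge a set of half-open intervals (two-column matrix/data.frame) into
# disjoint sorted intervals.
merge_intervals <- function(start, end) {
  if (length(start) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] > me) {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    } else {
      me <- max(me, end[i])
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
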