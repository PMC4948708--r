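# Internal helpers: structured errors, bitset fingerprints, seeded RNG scope.

# Byte-wise popcount table, built once at install time.
POPCOUNT8 <- vapply(0:255, function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:7)) != 0L), integer(1))

tree_error <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "phylocompare_error")))
}

# Sum of two possibly-absent branch lengths; absent + absent stays absent.
na_sum <- function(a, b) {
  if (is.na(a) && is.na(b)) NA_real_ else sum(c(a, b), na.rm = TRUE)
}

# Pack 1-based leaf slots into a raw-vector bitset sized for n_leaves.
fp_build <- function(slots, n_leaves) {
  nb <- max(1L, as.integer(ceiling(n_leaves / 8)))
  bits <- logical(nb * 8L)
  bits[slots] <- TRUE
  packBits(bits, "raw")
}

fp_count <- function(fp) {
  sum(POPCOUNT8[as.integer(fp) + 1L])
}

fp_slots <- function(fp) {
  which(as.logical(rawToBits(fp)))
}

fp_key <- function(fp) {
  paste(as.character(fp), collapse = "")
}

# TRUE when a label would be parsed as a number (internal support values).
label_is_numeric <- function(lab) {
  grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", lab)
}

fmt_num <- function(x) sprintf("%.10g", x)

# sample() without the length-1 integer expansion trap
sample_one <- function(x) x[sample.int(length(x), 1L)]

is_scalar_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == as.integer(x)
}
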