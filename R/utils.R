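# Internal helpers shared across modules.

# Deterministic sub-stream seed derived from a root seed and an index.
# Exact in double arithmetic (all intermediates < 2^53), result < 2^31.
derive_seed <- function(root, index, salt = 0L) {
  root <- as.numeric(root) %% 2147483647
  x <- (root * 48271 + as.numeric(index) * 69621 + as.numeric(salt) * 16807) %%
    2147483647
  as.integer(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Cumulative G+C and non-N counts for O(1) window GC lookups.
# Returns 0-prepended cumsums so window [a, b) (0-based half-open) is
# cum[b + 1] - cum[a + 1].
seq_cumcounts <- function(sequence) {
  r <- charToRaw(sequence)
  is_gc <- r == as.raw(71L) | r == as.raw(67L) # G, C
  is_n <- r == as.raw(78L) # N
  list(
    gc = c(0L, cumsum(is_gc)),
    valid = c(0L, cumsum(!is_n)),
    len = length(r)
  )
}

window_gc <- function(cum, start, end) {
  # start/end 0-based half-open, already clipped to [0, len]
  valid <- cum$valid[end + 1L] - cum$valid[start + 1L]
  if (valid < 1L) {
    return(c(gc = NA_real_, n = 0))
  }
  gc <- cum$gc[end + 1L] - cum$gc[start + 1L]
  c(gc = gc / valid, n = valid)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
    call. = FALSE
  )
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config(field, "must be a single fraction in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
    x != as.integer(x)) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

# Normalisation shared by all sequence readers: uppercase, U -> T.
normalize_nt <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path,
    sep = "\t", quote = "", colClasses = colClasses,
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

pair_key <- function(family_id, gene_id) paste(family_id, gene_id, sep = "\r")
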