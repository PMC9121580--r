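# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  `seed = NULL` leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range.  Used for the master -> cell -> replication hierarchy.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 8191) %% 2147483587) + 1L
}

# Column names of the six FTND items in a dataset data.frame.
ftnd_item_cols <- function() paste0("item", 1:6)

# Maximum score per item: items 1 and 4 run 0..3, the rest are binary.
ftnd_item_ranges <- function() c(3L, 1L, 1L, 3L, 1L, 1L)

# Extract the n x 6 integer matrix of item scores from a dataset.
ftnd_items <- function(data) {
  cols <- ftnd_item_cols()
  if (!all(cols %in% names(data))) {
    stop("`data` must contain columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(data[, cols])
}

# Row sums of the item matrix; NA wherever any item is missing.
ftnd_totals <- function(data) rowSums(ftnd_items(data))

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`", name, "` must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
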