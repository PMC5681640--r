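# Internal utilities shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state so that seeded helpers do not
# disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-replicate seed from a base seed; kept within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 1664525 * as.double(index)) %% 2147483646L) + 1L
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_expression_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix (features x samples)", name),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("'%s' must have feature rownames and sample colnames", name),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(sprintf("'%s' has duplicated feature ids; collapse them first ",
                 name), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(sprintf("'%s' has duplicated sample ids", name), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' contains missing or non-finite values", name),
         call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("'%s' contains negative expression values", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_survival_table <- function(x, name = deparse(substitute(x))) {
  req <- c("sample_id", "time", "event")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    stop(sprintf("'%s' must be a data.frame with columns %s", name,
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(x$sample_id)) {
    stop(sprintf("'%s' has duplicated sample ids", name), call. = FALSE)
  }
  if (any(!is.finite(x$time)) || any(x$time <= 0)) {
    stop(sprintf("'%s' has non-positive or missing survival times", name),
         call. = FALSE)
  }
  if (!all(x$event %in% c(0, 1))) {
    stop(sprintf("'%s' event indicator must be 0/1", name), call. = FALSE)
  }
  invisible(x)
}
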