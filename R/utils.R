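#' @keywords internal
"_PACKAGE"

## Typed conditions so callers/tests can distinguish failure modes.
mn_stop <- function(msg, class = "mn_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "mn_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

mn_assert <- function(cond, msg, class = "mn_validation_error") {
  if (!isTRUE(cond)) mn_stop(msg, class = class)
  invisible(TRUE)
}

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of the pipeline consumes a named substream derived
#' from the master seed so that stages are independently reproducible and a
#' cohort can be extended without reshuffling earlier subjects. The derivation
#' is a small deterministic integer hash of the master seed and the extra
#' arguments (coerced to character), folded into the range `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... stream labels (strings or integers), e.g. `"subject"`, `7`.
#' @return a single integer usable with [set.seed()].
#' @examples
#' derive_seed(42, "subject", 3)
#' @export
derive_seed <- function(master, ...) {
  mn_assert(is.numeric(master) && length(master) == 1 && is.finite(master),
            "master seed must be a single finite number")
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(master) %% m
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0(":", paste(as.character(part), collapse = ","))))
      h <- (h * 31 + ch) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

## Evaluate expr under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## upper-triangle (i < j) index pairs of an n x n matrix, column-major order
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

## vector of upper-triangle values in the row-major (i<j by (i,j)) order
ut_values <- function(m) {
  p <- upper_pairs(nrow(m))
  m[cbind(p[, 1], p[, 2])]
}

## rebuild a symmetric matrix (zero diagonal) from upper-triangle values
ut_to_matrix <- function(v, n, roi_ids = NULL) {
  p <- upper_pairs(n)
  m <- matrix(0, n, n)
  m[cbind(p[, 1], p[, 2])] <- v
  m <- m + t(m)
  if (!is.null(roi_ids)) dimnames(m) <- list(roi_ids, roi_ids)
  m
}
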