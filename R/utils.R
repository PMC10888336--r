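# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logarithmically spaced sequence
#'
#' @param from,to positive endpoints.
#' @param length.out number of points.
#' @return numeric vector.
#' @export
logseq <- function(from, to, length.out) {
  stopifnot(from > 0, to > 0, length.out >= 1)
  if (length.out == 1) return(from)
  exp(seq(log(from), log(to), length.out = length.out))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = env)
      } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic sub-seed derivation so that pipeline stages get independent
# streams from one master seed. Kept well below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7907 + as.double(offset) * 2677) %% 2147483629)
}

stop_if_not_square <- function(A, what = "adjacency") {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  }
  if (any(diag(A) != 0)) {
    stop(sprintf("%s must have a zero diagonal (no self-edges)", what), call. = FALSE)
  }
  invisible(A)
}

# JSON sidecar with parameters and input checksums, written next to `path`.
write_sidecar <- function(path, params = list(), inputs = character()) {
  side <- paste0(path, ".json")
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(file = basename(path), params = params, input_md5 = sums,
         written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    side, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(side)
}
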