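#' Derive a reproducible 32-bit seed from components
#'
#' Mixes a base seed with integer components (combo id, replicate number, ...)
#' into a seed suitable for [set.seed()]. The mix is a splitmix-style integer
#' hash so nearby inputs give unrelated streams; results stay below 2^31.
#'
#' @param base_seed integer base seed.
#' @param ... further integer components.
#' @return a single integer in `[0, 2^31 - 1]`.
#' @export
#' @examples
#' hash_seed(1, 42, 3)
hash_seed <- function(base_seed, ...) {
  parts <- c(base_seed, ...)
  stopifnot(length(parts) >= 1, all(is.finite(parts)))
  h <- 0
  for (p in as.double(parts)) {
    # 64-bit-safe modular mixing in doubles (exact below 2^53)
    h <- (h * 2654435761 + (p %% 2147483647) * 40503 + 2147483587) %% 2147483647
    h <- (h * 69069 + 1) %% 2147483647
  }
  as.integer(h)
}

stop_with <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_with("`%s` must be a probability in [0, 1], got %s", name,
              paste(format(x), collapse = ", "))
  invisible(x)
}

# modified-list update with unknown-name checking, used by all param builders
update_params <- function(defaults, dots, what) {
  if (length(dots) == 0) return(defaults)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0)
    stop_with("unknown %s parameter(s): %s", what, paste(unknown, collapse = ", "))
  defaults[names(dots)] <- dots
  defaults
}
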