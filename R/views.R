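#' The three standard specimen views
#'
#' Mounted specimens are photographed from three canonical perspectives:
#' the head (frontal), the dorsum (top) and the profile (lateral). All
#' functions in the package enumerate views in this fixed canonical order.
#'
#' @return A character vector `c("head", "dorsum", "profile")`.
#' @export
#' @examples
#' mv_views()
mv_views <- function() c("head", "dorsum", "profile")

#' Validate and canonicalise view labels
#'
#' @param view Character vector of view labels.
#' @param several_ok Allow more than one value?
#' @return The validated view label(s), as a character vector.
#' @keywords internal
as_view <- function(view, several_ok = FALSE) {
  if (!is.character(view) || length(view) < 1L) {
    stop("`view` must be a character vector of view labels", call. = FALSE)
  }
  if (!several_ok && length(view) != 1L) {
    stop("exactly one view label expected", call. = FALSE)
  }
  bad <- setdiff(view, mv_views())
  if (length(bad) > 0L) {
    stop(
      "unknown view label(s): ", paste(shQuote(bad), collapse = ", "),
      " (admissible: head, dorsum, profile)",
      call. = FALSE
    )
  }
  view
}

# Evaluate an expression under a temporary, isolated RNG state seeded with
# `seed`; the caller's .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of a seed plus a character tag, used to derive
# per-sample seeds that do not depend on generation order. Polynomial rolling
# hash modulo the Mersenne prime 2^31 - 1; arithmetic kept exact by splitting
# products so intermediates stay below 2^53.
hash_seed <- function(seed, ...) {
  m <- 2147483647
  modmul <- function(a, b) {
    # a, b < 2^31; split a into high/low 16-bit halves
    a_hi <- a %/% 65536
    a_lo <- a %% 65536
    (((a_hi * b) %% m) * 65536 + a_lo * b) %% m
  }
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "")
  h <- (as.numeric(seed) %% m + m) %% m
  for (code in utf8ToInt(tag)) {
    h <- (modmul(h, 257) + code) %% m
  }
  h <- modmul(h + 1, 48271)
  as.integer(h %% 2147483629 + 1)  # keep strictly positive, below 2^31
}
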