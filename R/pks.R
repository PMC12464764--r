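## Combinatorial capacity of an idealized polyketide assembly line.
##
## Each malonyl-CoA chain-extension unit of a reducing PKS can end in one
## of five oxidation states (keto, R-alcohol, S-alcohol, olefin, fully
## saturated), so a chain of k independently variable units spans 5^k
## products. Counts are kept exact with a small base-1e7 bignum, since
## they overflow doubles long before the chain lengths of interest.

# -- exact nonnegative integers as little-endian base-1e7 digit vectors --

.big_from_int <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0)
  digits <- numeric(0)
  while (x > 0) {
    digits <- c(digits, x %% 1e7)
    x <- x %/% 1e7
  }
  digits
}

.big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    # largest partial product: (1e7-1)^2 + carries < 2^53, exact in doubles
    carry <- 0
    for (j in seq_along(b)) {
      v <- res[i + j - 1] + a[i] * b[j] + carry
      res[i + j - 1] <- v %% 1e7
      carry <- v %/% 1e7
    }
    k <- i + length(b)
    while (carry > 0) {
      v <- res[k] + carry
      res[k] <- v %% 1e7
      carry <- v %/% 1e7
      k <- k + 1
    }
  }
  while (length(res) > 1 && res[length(res)] == 0) res <- res[-length(res)]
  res
}

.big_pow <- function(base, exp) {
  result <- .big_from_int(1)
  b <- .big_from_int(base)
  for (i in seq_len(exp)) result <- .big_mul(result, b)
  result
}

.big_to_string <- function(digits) {
  n <- length(digits)
  head <- format(digits[n], scientific = FALSE)
  rest <- if (n > 1) sprintf("%07.0f", rev(digits[-n])) else character(0)
  paste0(head, paste(rest, collapse = ""))
}

#' Number of products of an idealized PKS assembly line
#'
#' Counts `n_states_per_unit ^ n_variable_units` exactly: the number of
#' distinct polyketide products reachable when every variable
#' chain-extension unit independently adopts one of the per-unit outcome
#' states. With the default five states (keto, R-alcohol, S-alcohol,
#' olefin, saturated) and the seven variable units of a 16-membered
#' macrolactone, this is 5^7 = 78,125.
#'
#' @param n_states_per_unit Outcome states per chain-extension unit
#'   (default 5).
#' @param n_variable_units Number of independently variable units.
#' @return An object of class `np_bigcount`; `as.character()` gives the
#'   exact decimal digits, `as.numeric()` the (possibly rounded) double.
#' @examples
#' pks_state_count(5, 7)  # 78125
#' @export
pks_state_count <- function(n_states_per_unit = 5L, n_variable_units) {
  n_states_per_unit <- as.integer(n_states_per_unit)
  n_variable_units <- as.integer(n_variable_units)
  if (is.na(n_states_per_unit) || n_states_per_unit < 1)
    rlang::abort("`n_states_per_unit` must be a positive integer")
  if (is.na(n_variable_units) || n_variable_units < 0)
    rlang::abort("`n_variable_units` must be a nonnegative integer")
  digits <- .big_pow(n_states_per_unit, n_variable_units)
  structure(
    list(digits = digits,
         n_states_per_unit = n_states_per_unit,
         n_variable_units = n_variable_units),
    class = "np_bigcount")
}

#' @export
as.character.np_bigcount <- function(x, ...) .big_to_string(x$digits)

#' @export
as.double.np_bigcount <- function(x, ...) {
  sum(x$digits * 1e7^(seq_along(x$digits) - 1))
}

#' @export
print.np_bigcount <- function(x, ...) {
  cat(x$n_states_per_unit, "^", x$n_variable_units, " = ",
      .big_to_string(x$digits), "\n", sep = "")
  invisible(x)
}

#' Variable chain-extension units of an N-membered macrolactone
#'
#' A macrolactone of `ring_size` atoms built from `unit_length`-carbon
#' extender units requires `ring_size / unit_length` units, one of which
#' is retained as the anchoring keto group for macrolactonization; the
#' rest are free to vary. For the 16-membered macrolactone with two-carbon
#' malonyl-CoA units this gives 8 units, 7 of them variable.
#'
#' @param ring_size Macrolactone ring size in atoms.
#' @param unit_length Atoms contributed per extension unit (default 2).
#' @return Integer count of variable units.
#' @examples
#' macrolactone_variable_units(16)  # 7
#' @export
macrolactone_variable_units <- function(ring_size, unit_length = 2L) {
  ring_size <- as.integer(ring_size)
  unit_length <- as.integer(unit_length)
  if (ring_size < unit_length || unit_length < 1)
    rlang::abort("`ring_size` must be >= `unit_length` >= 1")
  if (ring_size %% unit_length != 0)
    rlang::abort(paste0("`ring_size` (", ring_size,
                        ") is not divisible by `unit_length` (", unit_length, ")"))
  ring_size %/% unit_length - 1L
}
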