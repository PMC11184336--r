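# Minimal exact non-negative big-integer arithmetic (base 1e9 limbs,
# little-endian). Only what combinatorial_space() needs: add, subtract a
# small constant, multiply/divide by a small integer. Division is only
# ever exact here (binomial coefficients are integers at every step of
# the multiplicative recurrence).

big_from_int <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 1e9)
  structure(list(limbs = as.numeric(x)), class = "bigint")
}

big_norm <- function(limbs) {
  carry <- 0
  for (i in seq_along(limbs)) {
    v <- limbs[i] + carry
    limbs[i] <- v %% 1e9
    carry <- (v - limbs[i]) / 1e9
  }
  while (carry > 0) {
    limbs <- c(limbs, carry %% 1e9)
    carry <- (carry - limbs[length(limbs)]) / 1e9
  }
  while (length(limbs) > 1 && limbs[length(limbs)] == 0)
    limbs <- limbs[-length(limbs)]
  limbs
}

big_add <- function(a, b) {
  n <- max(length(a$limbs), length(b$limbs))
  la <- c(a$limbs, rep(0, n - length(a$limbs)))
  lb <- c(b$limbs, rep(0, n - length(b$limbs)))
  structure(list(limbs = big_norm(la + lb)), class = "bigint")
}

# multiply by small non-negative integer k (k < 2^22 keeps limb*k exact
# in doubles: 1e9 * 4e6 < 2^53)
big_mul_small <- function(a, k) {
  stopifnot(k >= 0, k < 4e6)
  structure(list(limbs = big_norm(a$limbs * k)), class = "bigint")
}

# exact division by small positive integer k; stops if a remainder is left
big_div_small <- function(a, k) {
  stopifnot(k >= 1, k < 1e9)
  limbs <- a$limbs
  rem <- 0
  for (i in rev(seq_along(limbs))) {
    cur <- rem * 1e9 + limbs[i]
    limbs[i] <- cur %/% k
    rem <- cur %% k
  }
  if (rem != 0) stop("big_div_small: division not exact")
  structure(list(limbs = big_norm(limbs)), class = "bigint")
}

big_sub_small <- function(a, k) {
  stopifnot(k >= 0, k < 1e9)
  limbs <- a$limbs
  limbs[1] <- limbs[1] - k
  i <- 1
  while (limbs[i] < 0) {
    limbs[i] <- limbs[i] + 1e9
    limbs[i + 1] <- limbs[i + 1] - 1
    i <- i + 1
  }
  structure(list(limbs = big_norm(limbs)), class = "bigint")
}

big_to_string <- function(a) {
  n <- length(a$limbs)
  paste0(format(a$limbs[n], scientific = FALSE),
         paste(sprintf("%09.0f", rev(a$limbs[-n])), collapse = ""))
}

big_to_num <- function(a) sum(a$limbs * 1e9^(seq_along(a$limbs) - 1))

#' @export
format.bigint <- function(x, ...) big_to_string(x)

#' @export
print.bigint <- function(x, ...) {
  cat(big_to_string(x), "\n")
  invisible(x)
}
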