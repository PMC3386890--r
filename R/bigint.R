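# Exact non-negative integer arithmetic on decimal strings.  Symmetry-
# compressed invariant counts overflow machine integers (a 10x10 classic
# ring already has 10^10 minimal P-invariants), and machine-readable
# reports serialize counts as strings, so the accumulator works on
# decimal digits directly.

big_from_num <- function(n) {
  stopifnot(n >= 0, n == floor(n))
  format(n, scientific = FALSE)
}

big_digits <- function(s) rev(as.integer(strsplit(s, "")[[1]]))

big_string <- function(d) {
  while (length(d) > 1 && d[length(d)] == 0L) d <- d[-length(d)]
  paste(rev(d), collapse = "")
}

big_add <- function(a, b) {
  da <- big_digits(a); db <- big_digits(b)
  n <- max(length(da), length(db))
  da <- c(da, integer(n - length(da)))
  db <- c(db, integer(n - length(db)))
  s <- da + db
  carry <- 0L
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 10L
    s[i] <- s[i] %% 10L
  }
  if (carry > 0L) s <- c(s, big_digits(as.character(carry)))
  big_string(s)
}

big_mul <- function(a, b) {
  da <- big_digits(a); db <- big_digits(b)
  if (identical(a, "0") || identical(b, "0")) return("0")
  prod <- integer(length(da) + length(db))
  for (i in seq_along(da)) {
    if (da[i] == 0L) next
    prod[i + seq_along(db) - 1L] <- prod[i + seq_along(db) - 1L] + da[i] * db
  }
  carry <- 0L
  for (i in seq_along(prod)) {
    v <- prod[i] + carry
    prod[i] <- v %% 10L
    carry <- v %/% 10L
  }
  while (carry > 0L) {
    prod <- c(prod, carry %% 10L)
    carry <- carry %/% 10L
  }
  big_string(prod)
}
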