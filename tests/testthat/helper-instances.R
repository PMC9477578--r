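# Shared fixture builders: random search instances drawn from the current
# RNG stream (tests set their own seed).

rand_string <- function(n, sigma = c("A", "C", "G", "T")) {
  if (n == 0) "" else paste(sample(sigma, n, replace = TRUE), collapse = "")
}

rand_instance <- function(ls_max = 1000, lp_max = 30, ls_min = 1,
                          sigma = c("A", "C", "G", "T")) {
  ls <- sample(ls_min:ls_max, 1)
  lp <- sample(1:lp_max, 1)
  list(seq = rand_string(ls, sigma), pat = rand_string(lp, sigma))
}

# all strings of the given lengths over a binary alphabet
binary_patterns <- function(max_len) {
  unlist(lapply(seq_len(max_len), function(l) {
    grid <- do.call(expand.grid, rep(list(c("A", "C")), l))
    apply(grid, 1, paste, collapse = "")
  }))
}

# reference hit starts by direct window comparison
brute_exact_starts <- function(s, p) {
  ls <- nchar(s); lp <- nchar(p)
  if (lp > ls) return(integer(0))
  w <- substring(s, 1:(ls - lp + 1), lp:ls)
  which(w == p) - 1L
}
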