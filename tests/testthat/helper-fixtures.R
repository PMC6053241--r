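# Shared helpers: small networks and planted rasters used across tests.

small_pops <- c(PY = 60, IN = 12, TC = 12, RE = 12)

small_net <- function(...) tc_network(small_pops, ...)

# Brute-force string match: direct positional lookup, independent of the
# package implementation.
sm_bruteforce <- function(s1, s, normalize = TRUE) {
  s1 <- strsplit(s1, "")[[1]]
  s <- strsplit(s, "")[[1]]
  s1 <- unique(s1)
  s1 <- s1[s1 %in% s]
  if (!length(s1)) return(0)
  s2 <- s[s %in% s1]
  tot <- 0
  for (i in seq_along(s2)) {
    loc <- which(s1 == s2[i])
    tot <- tot + abs(loc - i)
  }
  raw <- 2 * length(s1) - tot
  if (normalize) raw / (2 * length(s)) else raw
}

random_sequence_pair <- function() {
  n <- sample(3:8, 1)
  s <- paste(LETTERS[1:n], collapse = "")
  k <- sample(0:n, 1)
  s1 <- paste(sample(LETTERS[1:n], k), collapse = "")
  list(s1 = s1, s = s)
}
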