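# Independent oracles, deliberately naive: these re-derive expected
# values by enumeration or per-base counting and must stay free of the
# package's own code paths.

# Sliding-window dictionary k-mer count.
naive_kmer_count <- function(seq, k, canonical = FALSE) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  out <- new.env(parent = emptyenv())
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  for (i in seq_len(n - k + 1)) {
    km <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", km)) next
    if (canonical) km <- min(km, rc(km))
    out[[km]] <- (if (is.null(out[[km]])) 0L else out[[km]]) + 1L
  }
  v <- unlist(as.list(out))
  if (is.null(v)) integer(0) else v[order(names(v))]
}

# Textbook Needleman-Wunsch optimal score (score only).
naive_nw_score <- function(x, y, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * gap
  S[1, ] <- (0:m) * gap
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (a[i] == b[j]) match else mismatch,
      S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  S[n + 1, m + 1]
}

# Probability of one HMM state path given symbols (missing emits 1).
hmm_path_logprob <- function(model, symbols, path) {
  lp <- log(model$start_probs[[path[1]]])
  if (symbols[1] != "missing") lp <- lp + log(model$emission[path[1], symbols[1]])
  for (t in seq_along(symbols)[-1]) {
    lp <- lp + log(model$transition[path[t - 1], path[t]])
    if (symbols[t] != "missing") lp <- lp + log(model$emission[path[t], symbols[t]])
  }
  unname(lp)
}

# Exhaustive Viterbi: max log-probability over all 2^n paths.
brute_viterbi_logprob <- function(model, symbols) {
  n <- length(symbols)
  paths <- expand.grid(rep(list(c("A", "B")), n), stringsAsFactors = FALSE)
  max(apply(paths, 1, function(p) hmm_path_logprob(model, symbols, p)))
}

# Fisher 2x2 by direct enumeration with exact binomial coefficients.
brute_fisher_two_sided <- function(m) {
  m1 <- m[1, 1] + m[1, 2]; m2 <- m[2, 1] + m[2, 2]; n1 <- m[1, 1] + m[2, 1]
  N <- m1 + m2
  if (m1 == 0 || m2 == 0 || n1 == 0 || n1 == N) return(1)
  xs <- max(0, n1 - m2):min(n1, m1)
  pr <- choose(m1, xs) * choose(m2, n1 - xs) / choose(N, n1)
  obs <- pr[xs == m[1, 1]]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Longest monotone anchor chain by recursive search with memoisation on
# the chain head (both orientations), honouring the gap cap; returns the
# best chain length. Independent of the package's iterative DP.
brute_longest_chain <- function(rx, ry, max_gap) {
  n <- length(rx)
  one_sign <- function(sign) {
    memo <- rep(NA_integer_, n)
    from <- function(i) {
      if (!is.na(memo[i])) return(memo[i])
      best <- 1L
      for (j in seq_len(n)) {
        dx <- rx[j] - rx[i]; dy <- sign * (ry[j] - ry[i])
        if (dx > 0 && dy > 0 && dx <= max_gap && dy <= max_gap) {
          best <- max(best, 1L + from(j))
        }
      }
      memo[i] <<- best
      best
    }
    if (n == 0) 0L else max(vapply(seq_len(n), from, integer(1)))
  }
  max(one_sign(1L), one_sign(-1L))
}

# Per-base occupancy density of a window over TE intervals.
naive_flank_density <- function(tes_df, scaffold, s, e) {
  if (e <= s) return(NA_real_)
  occ <- rep(FALSE, e - s)
  sel <- tes_df$scaffold == scaffold
  for (i in which(sel)) {
    a <- max(tes_df$start[i], s); b <- min(tes_df$end[i], e)
    if (b > a) occ[(a - s + 1):(b - s)] <- TRUE
  }
  mean(occ)
}
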