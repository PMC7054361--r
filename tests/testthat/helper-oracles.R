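# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own simulation/classification code paths.

# Exhaustive distribution of per-trial percent rightward for an n-turn
# persistence chain: first direction a fair coin, each later turn repeating
# the previous with probability p_same. Enumerates all 2^n sequences.
enum_chain_dist <- function(n, p_same) {
  seqs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  prob <- apply(seqs, 1, function(s) {
    pr <- 0.5
    if (n > 1) {
      for (t in 2:n) pr <- pr * (if (s[t] == s[t - 1]) p_same else 1 - p_same)
    }
    pr
  })
  pct <- 100 * rowMeans(seqs == 1)
  agg <- tapply(prob, round(pct, 6), sum)
  data.frame(pct = as.numeric(names(agg)), prob = as.vector(agg))
}

# Total-variation distance between an empirical sample and an enumerated
# distribution over the same (rounded) support.
tv_from_enum <- function(sample, enum) {
  emp <- table(factor(round(sample, 6), levels = round(enum$pct, 6)))
  0.5 * sum(abs(as.vector(emp) / length(sample) - enum$prob))
}

# Dynamic-programming probability of at least one success run of length
# >= r in m iid Bernoulli(q) trials. State: current run length 0..r-1.
run_prob_oracle <- function(m, q, r) {
  state <- c(1, rep(0, r - 1))
  absorbed <- 0
  for (i in seq_len(m)) {
    new <- numeric(r)
    new[1] <- sum(state) * (1 - q)
    if (r > 1) new[2:r] <- state[1:(r - 1)] * q
    absorbed <- absorbed + state[r] * q
    state <- new
  }
  absorbed
}

# Brute-force dominance statistic (#{x > y} - #{x < y}) / (nx * ny).
dominance_r <- function(x, y) {
  gt <- sum(outer(x, y, ">"))
  lt <- sum(outer(x, y, "<"))
  (gt - lt) / (length(x) * length(y))
}

# Small turn-count table for null-model tests.
make_counts <- function(n_larvae, trials = 4L, n_turns = 8L) {
  tibble::tibble(larva_id = rep(seq_len(n_larvae), each = trials),
                 trial = rep(seq_len(trials), n_larvae),
                 n_turns = rep_len(n_turns, n_larvae * trials))
}
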