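# Shared builders and closed-form oracles for the suite.

# Two-sample incident: start at h0, floor at time T.
two_point_incident <- function(T, h0 = 1.72, label = NA_character_,
                               id = "tp") {
  incident(id, c(0, T), c(h0, 0), label = label)
}

# Linear descent h(t) = h0 (1 - t/T) sampled on n points.
linear_incident <- function(h0 = 1, T = 1, n = 11L, id = "lin",
                            label = NA_character_) {
  t <- seq(0, T, length.out = n)
  incident(id, t, h0 * (1 - t / T), label = label)
}

# Analytic first-crossing times of the simulator's kinematic profiles.
fall_crossing <- function(level, T, h0) T * sqrt(1 - level / h0)
bend_crossing <- function(level, T, h0) T * (1 - sqrt(level / h0))

# Aligned truth/prediction vectors with given discordance counts:
# b incidents where A is wrong and B right, c the reverse, plus n_both
# concordant-correct pairs.
discordance_vectors <- function(b, c, n_both = 0L) {
  n <- b + c + n_both
  truth <- rep("FALL", n)
  pa <- rep("FALL", n)
  pb <- rep("FALL", n)
  if (b > 0) pa[seq_len(b)] <- "BEND"
  if (c > 0) pb[b + seq_len(c)] <- "BEND"
  list(truth = truth, a = pa, b = pb)
}
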