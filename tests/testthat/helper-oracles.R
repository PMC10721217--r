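# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: exact expectations come from exhaustive enumeration
# or closed-form probability, never from the simulator or the package's own
# statistics.

# Exact expected SF (per starter) and IF for a circuit with few synaptic
# contacts, by enumerating all 2^C crossing patterns with their Bernoulli(U)
# probabilities. C = total individual contacts; keep <= 14.
enumerate_spread_exact <- function(circuit, U) {
  ct <- circuit$contacts
  C <- sum(ct$n_contacts)
  stopifnot(C <= 14)
  conn_of <- rep.int(seq_len(nrow(ct)), ct$n_contacts)
  starters <- circuit$starters$id
  S <- vapply(starters, function(s) sum(ct$n_contacts[ct$starter_id == s]),
              numeric(1))
  sf_exp <- setNames(numeric(length(starters)), starters)
  if_exp <- 0
  for (pattern in 0:(2^C - 1)) {
    crossed <- as.logical(bitwAnd(pattern, 2^(seq_len(C) - 1)))
    prob <- prod(ifelse(crossed, U, 1 - U))
    if (prob == 0) next
    conn_crossed <- tapply(crossed, conn_of, any)
    labeled_inputs <- unique(ct$input_id[as.logical(conn_crossed)])
    lab <- ct$input_id %in% labeled_inputs
    for (k in seq_along(starters)) {
      sel <- ct$starter_id == starters[k]
      sf_exp[k] <- sf_exp[k] + prob * sum(ct$n_contacts[sel & lab]) / S[k]
    }
    if_exp <- if_exp + prob * length(labeled_inputs) / length(circuit$inputs)
  }
  list(sf = sf_exp, if_overall = if_exp)
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n_a + n_b, n_a) rank assignments (no ties assumed).
rank_sum_enum_p <- function(a, b) {
  n_a <- length(a)
  N <- n_a + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n_a)])
  sets <- utils::combn(N, n_a)
  sums <- colSums(matrix(seq_len(N)[sets], nrow = n_a))
  p_le <- mean(sums <= W)
  p_ge <- mean(sums >= W)
  min(1, 2 * min(p_le, p_ge))
}

# Hand-built circuit: one starter, n1 inputs at multiplicity Ma and n2 at
# multiplicity Mb, no sharing.
make_two_pop_circuit <- function(n1, n2, Ma, Mb) {
  synthetic_circuit(
    starters = data.frame(id = "s1", x_um = 0, y_um = 0, z_um = 0),
    contacts = data.frame(
      input_id = sprintf("i%d", seq_len(n1 + n2)),
      starter_id = "s1",
      n_contacts = c(rep(Ma, n1), rep(Mb, n2))))
}

# Two starters; starter s1 has n own inputs (multiplicity 1) of which the
# first round(s * n) also contact s2; s2 additionally has n private inputs.
# s1's planted shared-input fraction is exactly round(s * n) / n.
make_shared_circuit <- function(n, s) {
  n_shared <- round(s * n)
  own <- data.frame(input_id = sprintf("a%d", seq_len(n)),
                    starter_id = "s1", n_contacts = 1L)
  shared <- data.frame(input_id = sprintf("a%d", seq_len(n_shared)),
                       starter_id = "s2", n_contacts = 1L)
  other <- data.frame(input_id = sprintf("b%d", seq_len(n)),
                      starter_id = "s2", n_contacts = 1L)
  synthetic_circuit(
    starters = data.frame(id = c("s1", "s2"), x_um = c(0, 40),
                          y_um = 0, z_um = 0),
    contacts = rbind(own, shared, other))
}
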