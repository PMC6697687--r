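# Small fixtures built in code, shared across test files.

# directed chain 1 -> 2 -> ... -> n as an influence network
chain_network <- function(n, sign = 1) {
  influence_network(n, data.frame(from = seq_len(n - 1),
                                  to = seq_len(n - 1) + 1,
                                  sign = sign, weight = 1),
                    model_id = "chain")
}

# two-species linear relay: dx1 = -x1, dx2 = x1 - x2 around ss = (1, 1)
relay_model <- function() {
  J <- matrix(c(-1, 1, 0, -1), 2, 2)
  dynamical_model(J, steady_state = c(1, 1),
                  rhs = function(x) as.numeric(J %*% (x - c(1, 1))),
                  model_id = "relay")
}

# fully decoupled stable system
decoupled_model <- function(n = 4) {
  dynamical_model(diag(-1, n), model_id = "decoupled")
}

# independent midrank Spearman oracle: explicit cov / (sd * sd) formula
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(mean((rx - mean(rx))^2) * mean((ry - mean(ry))^2))
}
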