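# Independent oracles used across the suite. These never call the package
# paths they check.

# Term-by-term stiffness assembly: loop the coupled equations of motion for a
# star model (body = first label with role 'body') and accumulate entries.
oracle_assemble_K <- function(segments, joints) {
  n <- nrow(segments)
  labels <- segments$label
  K <- matrix(0, n, n, dimnames = list(labels, labels))
  body <- labels[segments$role == "body"]
  for (j in seq_len(nrow(joints))) {
    k <- joints$stiffness[j]
    a <- joints$from[j]
    if (joints$to[j] == "GROUND") {
      K[a, a] <- K[a, a] + k
    } else {
      # spring between appendage a and body: energy k/2 (x_a - x_b)^2
      K[a, a] <- K[a, a] + k
      K[body, body] <- K[body, body] + k
      K[a, body] <- K[a, body] - k
      K[body, a] <- K[body, a] - k
    }
  }
  unname(K)
}

# Characteristic-polynomial eigenvalue oracle for n <= 4: interpolate the
# degree-n polynomial det(K - lambda M) at n+1 points and take polyroot().
oracle_char_poly_omega <- function(M, K) {
  n <- nrow(M)
  stopifnot(n <= 4)
  scale <- max(diag(K) / diag(M))
  # interpolate in the scaled variable mu = lambda / scale for conditioning
  mu_pts <- seq(0, 1.5, length.out = n + 1)
  dets <- vapply(mu_pts, function(mu) det(K - mu * scale * M), numeric(1))
  V <- outer(mu_pts, 0:n, `^`)
  coefs <- solve(V, dets)
  mu <- polyroot(coefs)
  mu <- sort(Re(mu[abs(Im(mu)) < 1e-6 * pmax(1, abs(mu))]))
  sqrt(pmax(mu * scale, 0))
}

# Closed-form steady-state amplitude of a damped SDOF under force F0 sin(wt).
oracle_sdof_amplitude <- function(m, k, zeta, F0, w) {
  wn <- sqrt(k / m)
  F0 / k / sqrt((1 - (w / wn)^2)^2 + (2 * zeta * w / wn)^2)
}

random_fixture_like <- function(seed) {
  generate_random_model(n_appendage_pairs = 2, seed = seed)
}
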