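# Shared generators and independent oracles for the test suite.

random_point <- function(half = 50) stats::runif(3, -half, half)

# uniform random rotation via QR of a Gaussian matrix, det fixed to +1
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_rigid <- function() {
  rigid_transform(random_rotation(), stats::runif(3, -30, 30))
}

transform_landmark_set <- function(lm, tr) {
  coords <- t(apply(lm$coords, 1, function(p) apply_rigid(tr, p)))
  # bypass the LPS side check: a whole-head rotation may reorient left/right
  structure(list(subject_id = lm$subject_id, coords = coords),
            class = "landmark_set")
}

# exhaustive Fisher oracle: enumerate the hypergeometric support with choose()
# and sum probabilities no larger than the observed table's (same relative
# tie tolerance as the implementation's reference algorithm)
fisher_oracle_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(r1, ks) * choose(n - r1, c1 - ks) / choose(n, c1)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

shipped_presets <- c("normal_sinus", "normal_ci", "cholesteatoma")
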