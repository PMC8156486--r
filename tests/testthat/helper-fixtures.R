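# shared fixtures and independent oracles

# matrix-exponential solution of dp/dt = L p (oracle for simulate_master)
expm_solution <- function(L, p0, times) {
  M <- if (inherits(L, "rate_matrix")) L$entries else L
  t(vapply(times, function(t)
    as.numeric(Matrix::expm(Matrix::Matrix(M * t)) %*% p0),
    numeric(length(p0))))
}

# null-space steady state by direct linear solve (oracle for steady_state):
# replace one balance equation by the normalization constraint
nullspace_steady_state <- function(L) {
  M <- if (inherits(L, "rate_matrix")) L$entries else L
  n <- nrow(M)
  A <- rbind(M[-n, , drop = FALSE], rep(1, n))
  as.numeric(solve(A, c(rep(0, n - 1), 1)))
}

two_state_L <- function(k12 = 1, k21 = 1)
  rate_matrix(matrix(c(-k21, k21, k12, -k12), 2))

# brute-force conditional-independence check: is `target` independent of
# all species outside `blanket` given every positive-probability blanket
# configuration?
blanket_suffices <- function(model, target, blanket, tol = 1e-9) {
  p <- joint_steady_state(model)$probs
  n <- length(model$species)
  grid <- catflow:::joint_states(n)
  ti <- match(target, model$species)
  bi <- match(blanket, model$species)
  oi <- setdiff(seq_len(n), c(ti, bi))
  if (length(oi) == 0) return(TRUE)
  bcfg <- apply(grid[, bi, drop = FALSE], 1, paste, collapse = "")
  ocfg <- apply(grid[, oi, drop = FALSE], 1, paste, collapse = "")
  for (b in unique(bcfg)) {
    sel <- bcfg == b
    if (sum(p[sel]) < tol) next
    # P(target present | blanket) overall
    p_ref <- sum(p[sel & grid[, ti] == 1]) / sum(p[sel])
    for (o in unique(ocfg[sel])) {
      s2 <- sel & ocfg == o
      if (sum(p[s2]) < tol) next
      p_cond <- sum(p[s2 & grid[, ti] == 1]) / sum(p[s2])
      if (abs(p_cond - p_ref) > 1e-8) return(FALSE)
    }
  }
  TRUE
}
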