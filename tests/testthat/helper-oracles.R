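# Independent oracles the implementation is checked against.

# Euler-Lotka root: solve sum(lambda^-x * l_x * m_x) = 1 by uniroot.
euler_lotka_lambda <- function(l_x, m_x, x = seq_along(l_x)) {
  f <- function(lam) sum(lam^(-x) * l_x * m_x) - 1
  stats::uniroot(f, c(1e-4, 10), tol = 1e-12)$root
}

# Long-run growth factor of repeated projection of a positive start vector.
power_iteration_lambda <- function(A, iters = 20000) {
  v <- rep(1, nrow(A))
  lam <- NA_real_
  for (i in seq_len(iters)) {
    v2 <- A %*% v
    lam_new <- sum(v2) / sum(v)
    v <- v2 / sum(v2)
    if (i > 10 && abs(lam_new - lam) < 1e-13) return(lam_new)
    lam <- lam_new
  }
  lam
}

# Central finite differences of log(lambda) wrt log(a_ij): elasticities.
fd_elasticities <- function(A, h = 1e-3) {
  lam <- function(M) max(Re(eigen(M, only.values = TRUE)$values))
  E <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    if (A[i, j] == 0) next
    up <- A; up[i, j] <- A[i, j] * (1 + h)
    dn <- A; dn[i, j] <- A[i, j] * (1 - h)
    E[i, j] <- (log(lam(up)) - log(lam(dn))) / (2 * h)
  }
  E
}

# A random but valid Leslie model built through the package constructor.
random_leslie_model <- function() {
  t_max <- sample(5:15, 1)
  t_mat <- sample(2:(t_max - 2), 1)
  lh <- life_history(growth = growth_params(100, runif(1, 0.05, 0.4), -1),
                     L_mat = 50, t_mat = t_mat + runif(1, 0.05, 0.9),
                     t_max = t_max, m_bar = runif(1, 0.5, 5))
  M_x <- runif(t_max + 1, 0.05, 0.6)
  F_x <- if (runif(1) < 0.5) rep(0, t_max + 1)
  else ifelse(0:t_max >= sample(1:t_mat, 1), runif(1, 0, 0.5), 0)
  build_leslie(lh, M_x, fishing_scenario("rand", F_schedule = F_x),
               t_mat = t_mat, t_max = t_max)
}

porosus_growth <- function() growth_params(136.4, 0.077, -3.27)
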