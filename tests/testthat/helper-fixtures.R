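# Shared fixtures and independent oracles used across the test files.

# Stage plan constructed directly (bypassing the planning chain) so that
# covariance limits etc. can be probed at arbitrary stage sizes.
make_plan <- function(n_e, n_c, n_e2, n_c2, design) {
  structure(list(n_e = as.integer(n_e), n_c = as.integer(n_c),
                 n_e2 = as.integer(n_e2), n_c2 = as.integer(n_c2),
                 cap_n_e = as.integer(n_e + n_e2), cap_n_c = as.integer(n_c + n_c2),
                 n_fiu = as.integer(n_e + n_e2 + n_c + n_c2),
                 gamma = n_c / (n_c + n_c2), avn = NA_integer_, design = design),
            class = "fiu_plan")
}

# Independent oracle for the balanced stage-1 fraction: numeric root of the
# information-matching equation gamma*N*(n_H + gamma*N)/(gamma*2N + n_H) = N/2
# (equal levels, balanced groups), solved without the closed form.
gamma_oracle <- function(N, n_h) {
  if (n_h == 0) return(1)
  f <- function(g) g * N * (n_h + g * N) / (g * 2 * N + n_h) - N / 2
  stats::uniroot(f, c(1e-9, 1), tol = 1e-12)$root
}

# Grid oracle for the variance-minimizing pooling weight.
weight_oracle <- function(n_h, n_c, grid = seq(0, 1, by = 1e-4)) {
  v <- ifelse(grid > 0, grid^2 / n_h, 0) + ifelse(grid < 1, (1 - grid)^2 / n_c, 0)
  grid[which.min(v)]
}

# Moderate-size balanced dataset summary drawn at given means.
random_summary <- function(n_e = 40, n_c = 40, n_h = 200, mu_e = 0, mu_c = 0,
                           mu_h = 0, full = FALSE, n2 = 30) {
  y_e <- rnorm(n_e, mu_e); y_c <- rnorm(n_c, mu_c); y_h <- rnorm(n_h, mu_h)
  s <- group_summary(mean(y_e), mean(y_c), mean(y_h), n_e, n_c, n_h)
  if (full) {
    y_e2 <- rnorm(n2, mu_e); y_c2 <- rnorm(n2, mu_c)
    s$mean_e2 <- mean(c(y_e, y_e2)); s$mean_c2 <- mean(c(y_c, y_c2))
    s$n_e2_total <- n_e + n2; s$n_c2_total <- n_c + n2
  }
  attr(s, "raw") <- list(y_e = y_e, y_c = y_c, y_h = y_h)
  s
}

ft_design <- function(alpha_ept = 0.05, margin = 0.22, power = 0.8,
                      delta = 0.275) {
  fiu_design(delta, alpha_ept = alpha_ept, n_h = 500,
             beta_s1 = 1 - power, beta_s2 = 1 - power, margin = margin)
}
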