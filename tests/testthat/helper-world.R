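# shared fixtures, all built in code at test time

tiny_grid <- function(nr = 20, nc = 30, ...) grid_spec(nr, nc, ...)

# a small world with one narrow-niche species; used by several files
small_world <- function(seed = 11, nr = 36, nc = 54, n_species = 1,
                        driver_vars = c("Bio1", "Bio4", "Bio12"),
                        breadth_frac = 0.1) {
  grid <- grid_spec(nr, nc)
  current <- generate_climate(grid, seed)
  niches <- synth_species(n_species, current, seed,
                          driver_vars = driver_vars,
                          breadth_frac = breadth_frac)
  list(grid = grid, current = current, niches = niches, seed = seed)
}

# hand-rolled OLS for regression oracles
ols_oracle <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  se_b <- sqrt(ss_res / (n - 2) / sum((x - mean(x))^2))
  t_stat <- b / se_b
  list(slope = b, intercept = a, r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 2))
}

scale_mat <- function(m) (m - mean(m)) / stats::sd(m)
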