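# shared fixtures, built in code

# small two-cohort adult-liver design
adult_design <- function(n_a = 40, n_b = 40) {
  data.frame(cohort = c("A", "B"), group = "adult", tissue = "liver",
             n = c(n_a, n_b))
}

# a small study with planted effects of every kind
small_sim <- function(seed = 42, ...) {
  args <- list(design = adult_design(), n_snps = 200, n_cpgs = 200,
               n_probes = 100, fraction_dm = 0, fraction_de = 0, seed = seed)
  args <- utils::modifyList(args, list(...))
  simulate_study(do.call(sim_config, args))
}

# brute-force average-rank Spearman used as the independent oracle
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent step-up BH implementation
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# chi-squared statistic computed cell by cell
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# R^2 through the normal equations
oracle_r2 <- function(y, x) {
  X <- cbind(1, as.matrix(x))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- X %*% beta
  1 - sum((y - fit)^2) / sum((y - mean(y))^2)
}
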