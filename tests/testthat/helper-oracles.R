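# Independent brute-force oracle for the exact 2x2 test, built directly on
# the noncentral hypergeometric likelihood: log-pmf assembled from lchoose,
# two-sided p by direct tail summation, and the conditional-MLE odds ratio
# by solving the conditional mean equation (coarse grid bracket + uniroot
# refinement). Shares no code path with fisher_exact().

oracle_support <- function(m, n, k) {
  seq.int(max(0L, k - n), min(k, m))
}

# pmf of the conditional distribution of cell `a` at odds ratio psi
oracle_pmf <- function(m, n, k, log_psi = 0) {
  x <- oracle_support(m, n, k)
  lw <- lchoose(m, x) + lchoose(n, k - x) + x * log_psi
  w <- exp(lw - max(lw))
  w / sum(w)
}

oracle_p_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- oracle_support(m, n, k)
  pr <- oracle_pmf(m, n, k, 0)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

oracle_cmle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- oracle_support(m, n, k)
  if (length(x) == 1L) return(NA_real_)  # degenerate: OR not identifiable
  if (a == min(x)) return(0)
  if (a == max(x)) return(Inf)
  cond_mean <- function(lp) sum(x * oracle_pmf(m, n, k, lp))
  grid <- seq(-40, 40, by = 2)
  vals <- vapply(grid, cond_mean, numeric(1)) - a
  i <- which(vals[-length(vals)] <= 0 & vals[-1] >= 0)[1]
  root <- stats::uniroot(function(lp) cond_mean(lp) - a,
                         c(grid[i], grid[i + 1]), tol = 1e-10)
  exp(root$root)
}

# Vectorised conditional MLE for every admissible `a` of a margin triple
# (used by the exhaustive sweep): damped Newton on log-psi, solving
# conditional mean = a; boundary cells get 0 / Inf.
oracle_cmle_all <- function(m, n, k) {
  x <- oracle_support(m, n, k)
  s <- length(x)
  out <- numeric(s)
  if (s == 1L) return(NA_real_)
  out[1] <- 0; out[s] <- Inf
  if (s == 2L) return(out)
  a <- x[2:(s - 1)]
  lw0 <- lchoose(m, x) + lchoose(n, k - x)
  theta <- rep(0, length(a))
  for (it in 1:40) {
    lw <- outer(x, theta) + lw0          # support x targets
    lw <- sweep(lw, 2, apply(lw, 2, max))
    w <- exp(lw)
    w <- sweep(w, 2, colSums(w), "/")
    mu <- colSums(w * x)
    v <- colSums(w * x^2) - mu^2
    step <- (a - mu) / pmax(v, 1e-12)
    theta <- pmin(pmax(theta + pmin(pmax(step, -4), 4), -60), 60)
  }
  out[2:(s - 1)] <- exp(theta)
  out
}

# Vectorised two-sided p for every admissible `a` of a margin triple.
oracle_p_all <- function(m, n, k) {
  pr <- oracle_pmf(m, n, k, 0)
  vapply(seq_along(pr), function(i) sum(pr[pr <= pr[i] * (1 + 1e-7)]),
         numeric(1))
}
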