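# shared fixture builders (all data generated in code)

# trace following exact polynomials: pre poly before t0, pre + step (+ post
# delta anchored at the midpoint) after t1, linear ramp in between
make_poly_trace <- function(baseline = 297.7, pre = c(0, 0), step = 0.01,
                            post_delta = c(0, 0), t0 = 120, t1 = 120.6,
                            run_length = 240, rate = 5) {
  times <- seq(0, run_length, by = 1 / rate)
  tm <- (t0 + t1) / 2
  temp <- baseline + pre[1L] * times + pre[2L] * times^2
  during <- times > t0 & times < t1
  after <- times >= t1
  temp[during] <- temp[during] + step * (times[during] - t0) / (t1 - t0)
  temp[after] <- temp[after] + step + post_delta[1L] * (times[after] - tm) +
    post_delta[2L] * (times[after] - tm)^2
  temperature_trace(times, temp, t0, t1, sample_rate = rate)
}

# independently coded normal-equations quadratic fit (oracle for fit_drift)
normal_equations_quadratic <- function(t, y) {
  X <- cbind(1, t, t^2)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - 3L)
  list(beta = drop(beta), se = sqrt(diag(s2 * solve(XtX))))
}

# inverse-CDF sampler for the triangular distribution (oracle for
# triangular_std_uncertainty)
rtriangular <- function(n, lower, mode, upper) {
  u <- stats::runif(n)
  fm <- (mode - lower) / (upper - lower)
  ifelse(u < fm,
         lower + sqrt(u * (upper - lower) * (mode - lower)),
         upper - sqrt((1 - u) * (upper - lower) * (upper - mode)))
}
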