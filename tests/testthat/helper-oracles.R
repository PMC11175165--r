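# Independent brute-force oracles: explicit loops and closed forms, kept
# deliberately free of any package internals they are used to check.

oracle_cv_pct <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v
  m <- m / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  100 * sqrt(ss / (n - 1)) / m
}

# closed-form simple linear regression via normal equations + Pearson r^2
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y); syy <- sum(y * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  denom <- (n * sxx - sx^2) * (n * syy - sy^2)
  r2 <- if (denom <= 0) 0 else (n * sxy - sx * sy)^2 / denom
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# LLOD scan: loads ascending, intensities_by_load is a list of numeric
# vectors (detected replicate intensities per load)
oracle_llod <- function(loads, intensities_by_load, min_det = 2, cv_limit = 20) {
  ord <- order(loads)
  for (i in ord) {
    vals <- intensities_by_load[[i]]
    if (length(vals) < min_det) next
    if (oracle_cv_pct(vals) < cv_limit) return(loads[i])
  }
  NA_real_
}

oracle_lloq <- function(loads, intensities_by_load, slope, intercept, r2,
                        min_det = 2, cv_limit = 20, r2_min = 0.8,
                        dev_max = 0.2) {
  if (is.na(r2) || r2 <= r2_min || is.na(slope) || slope == 0) return(NA_real_)
  ord <- order(loads)
  for (i in ord) {
    vals <- intensities_by_load[[i]]
    if (length(vals) < min_det) next
    if (oracle_cv_pct(vals) >= cv_limit) next
    devs <- numeric(length(vals))
    for (j in seq_along(vals)) {
      devs[j] <- abs((vals[j] - intercept) / slope - loads[i]) / loads[i]
    }
    if (mean(devs) <= dev_max) return(loads[i])
  }
  NA_real_
}

oracle_union_size <- function(a, b) {
  length(a) + length(b) - sum(a %in% b)
}
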