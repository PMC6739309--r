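# Shared fixtures, built in code.

toy_cohort <- function() {
  cohort_table(
    data.frame(subject_id = paste0("P", 1:8),
               outcome = c(0, 0, 0, 0, 1, 1, 1, 0),
               time = c(rep(28, 4), 3, 7, 12, 28),
               event = c(0, 0, 0, 0, 1, 1, 1, 0),
               eNAPRT = c(1, 1, 2, 2, 10, 10, 11, 12),
               stringsAsFactors = FALSE),
    biomarkers = "eNAPRT")
}

# Independent Fisher oracle: full enumeration of the conditional
# hypergeometric support in exact integer arithmetic (binomial coefficients
# of tables with n <= 40 are exactly representable in doubles).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  num <- choose(r1, ks) * choose(r2, c1 - ks)   # exact integers
  obs <- choose(r1, a) * choose(r2, c1 - a)
  sum(num[num <= obs]) / choose(r1 + r2, c1)
}

# KM oracle: hand product-limit over distinct event times.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ts, survival = out)
}
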