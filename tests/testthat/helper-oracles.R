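# Independent brute-force oracles for the trajectory filters. These follow
# the rules from first principles (normal equations, exhaustive pair
# scans) and deliberately share no code with the package internals.

oracle_f1 <- function(day, w, sd_mult = 3, abs_lb = 10) {
  n <- length(day)
  if (n < 3) return(integer(0))
  t <- day - mean(day) # centering for conditioning only
  X <- cbind(1, t, t^2)
  beta <- solve(t(X) %*% X, t(X) %*% w)
  r <- as.numeric(w - X %*% beta)
  s <- sqrt(sum((r - mean(r))^2) / (n - 1))
  if (s == 0) return(integer(0))
  which(abs(r) > sd_mult * s & abs(r) > abs_lb)
}

oracle_f2 <- function(day, w, rate = 0.02) {
  n <- length(day)
  if (n < 3) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - 1)) {
    if (abs(w[i + 1] - w[i]) / (w[i] * (day[i + 1] - day[i])) > rate)
      hits <- c(hits, i, i + 1)
  }
  sort(unique(hits))
}

oracle_f3 <- function(day, w, jump = 50) {
  n <- length(day)
  if (n < 3) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(w[j] - w[i]) >= jump) hits <- c(hits, i, j)
  }
  sort(unique(hits))
}

oracle_f4 <- function(day, w, range_lb = 100) {
  if (length(day) < 2) return(FALSE)
  max(w) - min(w) >= range_lb
}

oracle_kappa <- function(a, b, c, d) {
  n <- a + b + c + d
  p_o <- (a + d) / n
  p_e <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  (p_o - p_e) / (1 - p_e)
}

# random member series for property tests: mixture of smooth trajectories
# and occasional wild values so every filter fires sometimes
random_series <- function(n_entries) {
  day <- sort(sample.int(400, n_entries))
  base <- runif(1, 120, 280)
  w <- base + cumsum(rnorm(n_entries, 0, runif(1, 0.5, 8)))
  wild <- runif(n_entries) < 0.08
  w[wild] <- w[wild] + sample(c(-1, 1), sum(wild), TRUE) *
    runif(sum(wild), 20, 250)
  w <- pmax(round(w, 1), 40)
  data.frame(member_id = "M1", day = day, weight_lb = w,
             entry_id = sprintf("E%03d", seq_len(n_entries)),
             stringsAsFactors = FALSE)
}

tiny_members <- function(ids, height = 65, weight = 180, age = 35,
                         reg_day = 0) {
  data.frame(member_id = ids, age = age, sex = "female",
             height_in = height, weight_lb = weight, reg_day = reg_day,
             reg_source = "other", region = "US-South",
             stringsAsFactors = FALSE)
}

tiny_entries <- function(member_id, day, weight_lb) {
  data.frame(member_id = member_id, day = day, weight_lb = weight_lb,
             entry_id = sprintf("%s-%03d", member_id, seq_along(day)),
             stringsAsFactors = FALSE)
}
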