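# shared fixtures: all built in code, no stored data

fast_config <- function(seed = 1, iterations = 1200, burn_in = 600, thin = 2,
                        adapt = 300) {
  run_config(iterations = iterations, burn_in = burn_in, thin = thin,
             chains = 2, adapt = adapt, seed = seed)
}

write_temp_csv <- function(df, na = "") {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = na)
  path
}

# minimal valid lek-count table
lek_df <- function() {
  data.frame(lek_id = c("L1", "L1", "L2"),
             region_id = c("R1", "R1", "R1"),
             year = c(2010L, 2011L, 2010L),
             count = c(12L, NA, 30L))
}

# minimal valid nest encounter history: three intervals, failure terminal
nest_df <- function() {
  data.frame(unit_id = rep("N1", 3), site_id = rep("S1", 3),
             interval_start_doy = c(120L, 127L, 132L),
             interval_end_doy = c(127L, 132L, 135L),
             exposure_days = c(7L, 5L, 3L),
             outcome = c(1L, 1L, 0L),
             x1 = c(0.1, -0.2, 0.3))
}

# independent day-by-day Bernoulli-product log-likelihood oracle:
# survival of a t-day interval is the product of t daily survivals
loglik_oracle <- function(beta, X, t, y) {
  X <- as.matrix(X)
  total <- 0
  for (j in seq_len(nrow(X))) {
    dsr <- 1 / (1 + exp(-sum(X[j, ] * beta)))
    surv <- 1
    for (d in seq_len(t[j])) surv <- surv * dsr
    total <- total + if (y[j] == 1) log(surv) else log(1 - surv)
  }
  total
}

# construct three columns with exact sample correlations
# cor(A,B)=rab, cor(B,C)=rbc, cor(A,C)=rab*rbc (A and C linked only through B)
correlated_triplet <- function(n = 400, rab = 0.9, rbc = 0.7, seed = 11) {
  set.seed(seed)
  raw <- matrix(rnorm(n * 3), n, 3)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(raw))          # orthonormal columns
  u1 <- q[, 1]; u2 <- q[, 2]; u3 <- q[, 3]
  B <- u1
  A <- rab * u1 + sqrt(1 - rab^2) * u2
  C <- rbc * u1 + sqrt(1 - rbc^2) * u3
  data.frame(A = A, B = B, C = C)
}
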