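# Shared fixtures: random DMU instances and the single-ratio closed form.

# random DMU set with positive data shaped like the cohort features
# (one input around 36, one around 4e-4 when m = 2; output around 1/23)
rand_dmus <- function(n, m = 2L, s = 1L, seed = 1L, cohort_like = TRUE) {
  set.seed(seed)
  if (cohort_like && m == 2L && s == 1L) {
    X <- cbind(runif(n, 25, 75), 1 / runif(n, 1500, 3500))
    Y <- cbind(1 / runif(n, 16, 35))
  } else {
    X <- matrix(runif(n * m, 0.5, 10), n, m)
    Y <- matrix(runif(n * s, 0.5, 10), n, s)
  }
  dmu_set(sprintf("D%03d", seq_len(n)), X, Y)
}

# closed-form CCR scores for the single-input single-output CRS case
closed_form_scores <- function(dmus) {
  ratio <- dmus$outputs[, 1L] / dmus$inputs[, 1L]
  stats::setNames(ratio / max(ratio), dmus$ids)
}

# independent envelopment-form solve via pracma's LP routine
linprog_theta <- function(dmus, target_id) {
  o <- match(target_id, dmus$ids)
  X <- t(dmus$inputs / rep(colMeans(dmus$inputs), each = nrow(dmus$inputs)))
  Y <- t(dmus$outputs / rep(colMeans(dmus$outputs), each = nrow(dmus$outputs)))
  n <- ncol(X)
  # min theta st. sum lam x - theta x_o <= 0 ; -sum lam y <= -y_o
  A <- rbind(cbind(-X[, o, drop = FALSE], X),
             cbind(rep(0, nrow(Y)), -Y))
  b <- c(rep(0, nrow(X)), -Y[, o])
  sol <- pracma::linprog(cc = c(1, rep(0, n)), A = A, b = b,
                         maxiter = 100L * (n + 5L))
  sol$x[1L]
}

# tiny cohort table used by the feature tests
toy_cohort <- function() {
  data.frame(
    subject_id = c("s1", "s2", "s3", "s4"),
    age = c(45L, 62L, 70L, 55L),
    sex = c("man", "woman", "woman", "man"),
    bmi_baseline = c(23.0, 26.0, 17.9, 24.0),
    energy_intake_kcal = c(2257, 1900, 2500, 2100),
    energy_expenditure_mets_h = c(36.2, 30.0, 41.0, 33.5),
    bmi_followup = c(24.1, 25.5, NA, 22.9),
    followup_years = c(5.5, 6.0, NA, 5.0),
    stringsAsFactors = FALSE
  )
}
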