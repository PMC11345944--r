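# Independent oracles and small shared fixtures.

# Closed-form solution of the linear two-compartment oral system via the
# matrix exponential (independent of the package's ODE route).
oracle_plasma <- function(ind, dose, times) {
  th <- ind$theta
  k10 <- th[["CL"]] / th[["V1"]]
  k12 <- th[["Q"]] / th[["V1"]]
  k21 <- th[["Q"]] / th[["V2"]]
  A <- matrix(c(-th[["ka"]], 0, 0,
                th[["ka"]], -(k10 + k12), k21,
                0, k12, -k21),
              nrow = 3, byrow = TRUE)
  vapply(times, function(t) {
    tau <- t - th[["tlag"]]
    if (tau <= 0) return(0)
    y <- as.matrix(Matrix::expm(A * tau)) %*% c(dose, 0, 0)
    y[2] / th[["V1"]]
  }, numeric(1))
}

# Random (but physiologic) individual parameter sets for property loops.
random_individual <- function() {
  individual_pk_params(
    subject = 1L, weight = 70,
    tlag = stats::runif(1, 0, 0.5),
    ka = stats::runif(1, 0.5, 10),
    CL = stats::runif(1, 20, 150),
    V1 = stats::runif(1, 30, 150),
    Q = stats::runif(1, 10, 80),
    V2 = stats::runif(1, 10, 80))
}

typical_tablet <- function() covariate_scale(default_poppk("tablet"), 70)
typical_capsule <- function() covariate_scale(default_poppk("capsule"), 70)

# Largest-remainder apportionment computed independently (sort-based).
lr_counts <- function(n, prev) {
  q <- n * prev
  fl <- floor(q)
  rem <- n - sum(fl)
  if (rem > 0) {
    idx <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}
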