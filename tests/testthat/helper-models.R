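## small model fixtures built in code

## single harmonic surface (second state parked far away, uncoupled)
harmonic_model <- function(mu = 2000, omega = 0.01, x0 = 0) {
  m <- diabatic_model(2, masses = mu, terms = list(
    list(i = 1, j = 1, type = "harmonic", k = mu * omega^2, x0 = x0),
    list(i = 2, j = 2, type = "const", c = 10)
  ), name = "harmonic")
  m$grid <- c(x0 - 1.5, x0 + 1.5, 512)
  m
}

## two flat surfaces with constant coupling (Rabi fixture)
flat_coupled_model <- function(v12 = 0.005, gap = 0, mu = 2000) {
  m <- diabatic_model(2, masses = mu, terms = list(
    list(i = 1, j = 1, type = "const", c = 0),
    list(i = 2, j = 2, type = "const", c = gap),
    list(i = 1, j = 2, type = "const", c = v12)
  ), name = "flat_coupled")
  m$grid <- c(-20, 20, 256)
  m
}

## two uncoupled 1-D diabats with configurable slopes (dephasing fixture)
sloped_uncoupled_model <- function(k1 = 0, k2 = 0, gap = 0.05, mu = 2000) {
  diabatic_model(2, masses = mu, terms = list(
    list(i = 1, j = 1, type = "linear", k = k1, x0 = 0),
    list(i = 2, j = 2, type = "const", c = gap),
    list(i = 2, j = 2, type = "linear", k = k2, x0 = 0)
  ), name = "sloped_uncoupled")
}

## uncoupled 2-state LVC with per-state diagonal slopes (coherence fixtures)
lvc_uncoupled_model <- function(gap, slopes1, slopes2,
                                omega = c(0.004, 0.006, 0.009)) {
  nm <- length(omega)
  w <- array(0, c(2, 2, nm))
  for (a in seq_len(nm)) w[, , a] <- diag(c(slopes1[a], slopes2[a]))
  m <- diabatic_model(2, masses = rep(1, nm),
                      lvc = list(omega = omega, v0 = diag(c(0, gap)), w = w),
                      normal_modes = normal_mode_spec(omega),
                      name = "lvc_uncoupled")
  m$initial <- list(type = "harmonic_wigner",
                    diabatic_coefficients = c(1, 1) / sqrt(2))
  m$defaults <- list(dt_fs = 0.2, t_max_fs = 30)
  m
}

all_1d_presets <- c("avoided_crossing_2s", "ibr_surrogate_3s",
                    "tully3_sloped")

random_position <- function(model) {
  if (model$kind == "lvc") stats::rnorm(model$n_dof, sd = 5)
  else stats::runif(1, model$grid[1] + 0.5, model$grid[2] - 0.5)
}
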