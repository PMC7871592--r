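# Independent oracles and shared fixtures. Oracles deliberately avoid the
# package's own code paths: brute-force loops, quadrature, and explicit
# 2x2 complex algebra.

# O(n^2) pairwise debiased wPLI for one frequency column of a csd matrix
oracle_wpli <- function(im) {
  n <- length(im); num <- 0; den <- 0
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    num <- num + im[j] * im[k]
    den <- den + abs(im[j]) * abs(im[k])
  }
  if (den == 0) 0 else num / den
}

# O(n^2) pairwise phase consistency from phases
oracle_ppc <- function(phi) {
  n <- length(phi); acc <- 0
  for (j in seq_len(n - 1)) for (k in (j + 1):n)
    acc <- acc + cos(phi[j] - phi[k])
  acc / (n * (n - 1) / 2)
}

# 18-bin discretization of the density p(phi) proportional to 1 + m cos(phi)
oracle_mi <- function(m, nb = 18) {
  edges <- seq(-pi, pi, length.out = nb + 1)
  prof <- vapply(seq_len(nb), function(k)
    stats::integrate(function(p) 1 + m * cos(p),
                     edges[k], edges[k + 1])$value, numeric(1))
  p <- prof / sum(prof)
  h <- -sum(p * log(p))
  (log(nb) - h) / log(nb)
}

# closed-form bivariate spectral GC 1 -> 2 from true (A, Sigma), written
# with explicit 2x2 complex algebra (independent of the package routines)
oracle_gc_12 <- function(A, Sigma, freqs, rate) {
  vapply(freqs, function(f) {
    z1 <- exp(-2i * pi * f / rate)
    Af <- diag(2) + 0i
    for (k in seq_along(A)) Af <- Af - A[[k]] * z1^k
    det_a <- Af[1, 1] * Af[2, 2] - Af[1, 2] * Af[2, 1]
    # H = Af^-1 explicitly
    H11 <- Af[2, 2] / det_a; H12 <- -Af[1, 2] / det_a
    H21 <- -Af[2, 1] / det_a; H22 <- Af[1, 1] / det_a
    S22 <- Re(H21 * Sigma[1, 1] * Conj(H21) + H21 * Sigma[1, 2] * Conj(H22) +
              H22 * Sigma[2, 1] * Conj(H21) + H22 * Sigma[2, 2] * Conj(H22))
    Htil <- H21 + (Sigma[2, 1] / Sigma[1, 1]) * H22
    s11c <- Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2]
    log(S22 / (S22 - s11c * Mod(Htil)^2))
  }, numeric(1))
}

# canonical unidirectional stable VAR(2): channel 1 drives channel 2
unidir_var <- function(drive = 0.4) {
  list(A = list(matrix(c(0.55, 0, drive, 0.55), 2, 2, byrow = TRUE),
                matrix(c(-0.7, 0, 0, -0.7), 2, 2, byrow = TRUE)),
       Sigma = diag(2))
}

true_var_model <- function(sys, rate = 250) {
  structure(list(A = sys$A, Sigma = sys$Sigma, rate_hz = rate, n = 2,
                 stable = TRUE),
            class = "var_model")
}

# irregular (frequency-jittered) theta oscillation: realistic aperiodic
# cycles so offset profiles have a unique peak
gen_irregular_theta <- function(nt, rate, seed, f0 = 8) {
  set.seed(seed)
  f_inst <- f0 + lfpcoupling:::fir_bandpass(stats::rnorm(nt, sd = 20),
                                            0.2, 1.2, rate)
  ph <- 2 * pi * cumsum(f_inst) / rate
  lfp_recording(cos(ph), rate)
}

wrapd <- function(x) ((x + 180) %% 360) - 180
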