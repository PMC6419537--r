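# Shared fixtures and independent oracles for the test suite.

# A mid-release compartment state with exactly 5 % of reporter in the cilium.
state_5pct <- function() {
  compartment_state(time = 1.5, fractions = c(er = 0.05, apical = 0.50,
                                              basolateral = 0.40,
                                              cilium = 0.05))
}

# Compact rendering setup used where per-voxel cost matters more than
# resolution: the population profile with optionally coarser sampling.
fast_profile <- function(seed = 1L, voxel_size = c(0.4, 0.25, 0.25)) {
  population_profile(seed = seed, voxel_size = voxel_size)
}

render_fast <- function(state, seed = 1L, stained_side = "apical",
                        expression_level = 1, vox = NULL,
                        voxel_size = c(0.4, 0.25, 0.25), ...) {
  pr <- fast_profile(seed, voxel_size)
  render_stack(pr$geometry, state, pr$imaging, stained_side = stained_side,
               expression_level = expression_level, vox = vox, ...)
}

# --- independent oracles -------------------------------------------------

# Closed-form solution of the linear part of the trafficking model
# (no ciliary import): ER and basolateral pools.
oracle_er <- function(t, k_release) exp(-k_release * t)

oracle_bl <- function(t, k_release, phi_bl, k_transcytosis) {
  kr <- k_release; kt <- k_transcytosis
  if (abs(kr - kt) < 1e-12) {
    phi_bl * kr * t * exp(-kr * t)
  } else {
    phi_bl * kr / (kr - kt) * (exp(-kt * t) - exp(-kr * t))
  }
}

# Direct double-loop Manders coefficient over a 3D stack (no vectorized
# shortcuts shared with the implementation).
oracle_mcc <- function(gfp, mask, cell_mask = NULL, min_gfp = 0) {
  d <- dim(gfp)
  num <- 0; den <- 0
  for (iz in seq_len(d[1])) for (iy in seq_len(d[2])) for (ix in seq_len(d[3])) {
    v <- gfp[iz, iy, ix]
    in_cell <- is.null(cell_mask) || cell_mask[iz, iy, ix]
    if (v > min_gfp && in_cell) {
      den <- den + v
      if (mask[iz, iy, ix]) num <- num + v
    }
  }
  num / den
}

# OLS slope/intercept by direct summation.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; sxy <- sxy + x[i] * y[i]
  }
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  c(intercept = (sy - slope * sx) / n, slope = slope)
}

# Textbook paired t: t = dbar / (sd(d)/sqrt(n)), two-tailed p from the t
# distribution with n - 1 df.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  c(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1))
}

# Jaccard overlap of two logical masks.
jaccard <- function(a, b) sum(a & b) / sum(a | b)
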