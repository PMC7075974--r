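# Independent brute-force oracles and small fixtures used across tests.

# Plain probability-space WHAM fixed-point iteration, written independently
# of the package implementation (explicit loops, no log-space tricks).
# Only suitable for small problems.
wham_oracle <- function(windows, breaks, tol = 1e-12, max_iter = 500000) {
  temperature <- windows[[1]]$temperature
  kT <- 1.987204258640832e-3 * temperature
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  B <- length(centers)
  W <- length(windows)
  n <- matrix(0, B, W)
  for (i in seq_len(W)) {
    for (s in windows[[i]]$samples) {
      b <- findInterval(s, breaks, rightmost.closed = TRUE, all.inside = TRUE)
      n[b, i] <- n[b, i] + 1
    }
  }
  Ni <- colSums(n)
  cmat <- matrix(0, B, W)
  for (i in seq_len(W)) {
    pref <- if (windows[[i]]$bias_convention == "half_k") 0.5 else 1.0
    for (b in seq_len(B)) {
      U <- pref * windows[[i]]$force_constant * (centers[b] - windows[[i]]$center)^2
      cmat[b, i] <- exp(-U / kT)
    }
  }
  f <- rep(1, W)
  for (iter in seq_len(max_iter)) {
    p <- numeric(B)
    for (b in seq_len(B)) {
      den <- 0
      for (i in seq_len(W)) den <- den + Ni[i] * f[i] * cmat[b, i]
      p[b] <- if (den > 0) sum(n[b, ]) / den else 0
    }
    p <- p / sum(p)
    fnew <- numeric(W)
    for (i in seq_len(W)) fnew[i] <- 1 / sum(p * cmat[, i])
    fnew <- fnew / fnew[1]
    if (max(abs(kT * log(fnew / f))) < tol) { f <- fnew; break }
    f <- fnew
  }
  g <- ifelse(p > 0, -kT * log(p), NA_real_)
  g - min(g, na.rm = TRUE)
}

# Analytic turnover of a unidirectional single cycle: harmonic sum of the
# mean dwell times along the cycle.
cycle_turnover_oracle <- function(rates) 1 / sum(1 / rates)

# Minimal multi-model PDB text for reader tests.
make_test_pdb <- function(path, models) {
  fmt <- function(serial, name, resid, chain, resno, x, y, z, alt = " ",
                  occ = 1.0) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, paste0(" ", name), alt, resid, chain, resno, x, y, z,
            occ, 0.0)
  }
  lines <- character(0)
  for (m in seq_along(models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    df <- models[[m]]
    for (i in seq_len(nrow(df))) {
      lines <- c(lines, fmt(i, df$name[i], df$resid[i], df$chain[i],
                            df$resno[i], df$x[i], df$y[i], df$z[i],
                            alt = if ("alt" %in% names(df)) df$alt[i] else " ",
                            occ = if ("occ" %in% names(df)) df$occ[i] else 1))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Frame constructor for direct geometric tests.
make_frame <- function(resid, chain, resno, elety, x, y, z) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr.Q(qr(m))
}
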