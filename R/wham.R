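#' Weighted histogram analysis method (WHAM) for umbrella-sampling windows
#'
#' Combines biased reaction-coordinate histograms from a set of umbrella
#' windows into a single unbiased free-energy profile g(R) by iterating the
#' standard WHAM self-consistency equations
#' \deqn{p_b \propto \frac{\sum_i n_{ib}}{\sum_i N_i f_i c_{ib}}, \qquad
#'       f_i^{-1} = \sum_b p_b c_{ib},}
#' where \eqn{c_{ib} = \exp(-U_i(x_b)/k_BT)} is the bias Boltzmann factor of
#' window i evaluated at bin centre b. Iteration stops when the largest change
#' in any window free-energy constant \eqn{-k_BT\ln f_i} falls below `tol`
#' (default 1e-5 kcal mol^-1). The profile is anchored so its minimum over
#' populated bins is zero; empty bins carry `NA`.
#'
#' @param windows List of [umbrella_window()] objects sharing one temperature.
#' @param breaks Optional bin edges (Angstrom). If `NULL`, bins of width
#'   `bin_width` aligned to the default reaction-coordinate range
#'   (-2.9 to 2.6 A) and extended to cover all samples are used.
#' @param bin_width Bin width in Angstrom when `breaks` is `NULL`; default 0.1.
#' @param n_bins Optional number of bins spanning the sample range; overrides
#'   `bin_width` when given.
#' @param tol Convergence criterion on window constants, kcal mol^-1.
#' @param max_iter Maximum number of WHAM iterations.
#' @return An object of class `fep_profile`: list with `bin_centers`, `g`
#'   (anchored free energy, kcal mol^-1), `stderr` (`NA` until
#'   [bootstrap_profile()] is run), `counts`, `breaks`, `temperature`,
#'   `iterations` and `residual`.
#' @details Windows must form a single connected group: every window must
#'   share at least one populated bin with the rest, otherwise relative free
#'   energies between groups are undefined and an error is raised. No
#'   statistical-inefficiency correction is applied to the samples (see the
#'   package vignette); the `counts` slot lets callers apply one externally.
#' @export
wham_solve <- function(windows, breaks = NULL, bin_width = 0.1, n_bins = NULL,
                       tol = 1e-5, max_iter = 100000) {
  if (length(windows) < 1)
    stop_invalid("wham_solve: need at least one window")
  ok <- vapply(windows, inherits, logical(1), what = "umbrella_window")
  if (!all(ok))
    stop_invalid("wham_solve: all inputs must be umbrella_window objects")
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9)
    stop_invalid("wham_solve: all windows must share one temperature")
  temperature <- temps[1]
  kT <- kT_kcal(temperature)

  all_samples <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(breaks)) {
    if (!is.null(n_bins)) {
      breaks <- seq(min(all_samples), max(all_samples), length.out = n_bins + 1)
      # widen edges a hair so extreme samples fall inside
      breaks[1] <- breaks[1] - 1e-9
      breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
    } else {
      lo <- floor(min(c(all_samples, -2.9)) / bin_width) * bin_width
      hi <- ceiling(max(c(all_samples, 2.6)) / bin_width) * bin_width
      breaks <- seq(lo, hi, by = bin_width)
    }
  }
  if (length(breaks) < 3)
    stop_invalid("wham_solve: samples must span at least 2 bins")
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  B <- length(centers)
  W <- length(windows)

  counts <- vapply(windows, function(w) {
    s <- w$samples
    if (any(s < breaks[1] | s > breaks[length(breaks)]))
      stop_invalid("wham_solve: sample outside bin range [%g, %g]",
                   breaks[1], breaks[length(breaks)])
    tabulate(findInterval(s, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = B)
  }, numeric(B))
  counts <- matrix(counts, nrow = B, ncol = W)
  Ni <- colSums(counts)
  nb <- rowSums(counts)
  populated <- nb > 0
  if (sum(populated) < 2)
    stop_invalid("wham_solve: samples must span at least 2 bins")

  .check_window_connectivity(counts, populated)

  # bias Boltzmann factors at bin centres (B x W), in log space
  logc <- vapply(windows, function(w) -bias_potential(w, centers) / kT,
                 numeric(B))
  logc <- matrix(logc, nrow = B, ncol = W)

  logNi <- log(Ni)
  lognb <- ifelse(populated, log(nb), -Inf)
  logf <- rep(0, W)
  iter <- 0L
  residual <- Inf
  repeat {
    iter <- iter + 1L
    # log denominator per bin: log sum_i exp(logNi + logf_i + logc_bi)
    m <- logc + rep(logNi + logf, each = B)
    mmax <- apply(m, 1, max)
    logden <- mmax + log(rowSums(exp(m - mmax)))
    logp <- lognb - logden
    logp <- logp - logsumexp(logp[populated])
    # update window constants: f_i^{-1} = sum_b p_b c_{bi}
    t <- logp[populated] + logc[populated, , drop = FALSE]
    tmax <- apply(t, 2, max)
    logf_new <- -(tmax + log(colSums(exp(sweep(t, 2, tmax)))))
    logf_new <- logf_new - logf_new[1]          # fix gauge
    residual <- kT * max(abs(logf_new - logf))
    logf <- logf_new
    if (residual < tol) break
    if (iter >= max_iter)
      stop_invalid(
        "wham_solve: no convergence after %d iterations (residual %.3g kcal/mol)",
        iter, residual)
  }

  g <- rep(NA_real_, B)
  g[populated] <- -kT * logp[populated]
  g <- g - min(g, na.rm = TRUE)

  structure(
    list(bin_centers = centers, g = g, stderr = rep(NA_real_, B),
         counts = nb, breaks = breaks, temperature = temperature,
         iterations = iter, residual = residual),
    class = "fep_profile")
}

# Windows are connected when they can be chained through shared populated
# bins; otherwise their relative offsets are unidentifiable.
.check_window_connectivity <- function(counts, populated) {
  W <- ncol(counts)
  if (W == 1) return(invisible(TRUE))
  occ <- counts > 0
  comp <- seq_len(W)
  repeat {
    changed <- FALSE
    for (i in seq_len(W - 1)) {
      for (j in seq(i + 1, W)) {
        if (comp[i] != comp[j] && any(occ[, i] & occ[, j])) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1)
    stop_invalid(
      "wham_solve: windows form %d disconnected groups with no histogram overlap",
      length(unique(comp)))
  invisible(TRUE)
}

#' @export
print.fep_profile <- function(x, ...) {
  pop <- !is.na(x$g)
  cat(sprintf(
    "free-energy profile: %d bins (%d populated) over [%.2f, %.2f] A, T = %g K\n",
    length(x$g), sum(pop), x$breaks[1], x$breaks[length(x$breaks)],
    x$temperature))
  cat(sprintf("  max g = %.3f kcal/mol; converged in %d iterations (residual %.2g)\n",
              max(x$g, na.rm = TRUE), x$iterations, x$residual))
  invisible(x)
}

#' @export
as.data.frame.fep_profile <- function(x, ...) {
  data.frame(bin_center = x$bin_centers, g = x$g, stderr = x$stderr,
             count = x$counts)
}

#' Bootstrap errors for a WHAM free-energy profile
#'
#' Resamples each window's reaction-coordinate values with replacement,
#' re-solves WHAM, re-anchors each trial profile to min = 0, and returns the
#' per-bin standard deviation over trials. Ten Monte Carlo trials is the
#' conventional default for umbrella-sampling error bars.
#'
#' @inheritParams wham_solve
#' @param n_trials Number of bootstrap trials, default 10.
#' @param seed Integer seed; trials are reproducible given the seed.
#' @return The `fep_profile` from the full data with its `stderr` slot filled.
#'   Trials whose WHAM solve failed are recorded in
#'   `attr(, "failed_trials")` (a list of condition messages, possibly empty)
#'   and excluded from the standard deviation; at least two trials must
#'   succeed.
#' @export
bootstrap_profile <- function(windows, n_trials = 10, seed = 1,
                              breaks = NULL, bin_width = 0.1, n_bins = NULL,
                              tol = 1e-5, max_iter = 100000) {
  full <- wham_solve(windows, breaks = breaks, bin_width = bin_width,
                     n_bins = n_bins, tol = tol, max_iter = max_iter)
  set.seed(seed)
  B <- length(full$g)
  trials <- matrix(NA_real_, nrow = B, ncol = n_trials)
  failures <- list()
  for (t in seq_len(n_trials)) {
    wb <- lapply(windows, function(w) {
      w$samples <- sample(w$samples, length(w$samples), replace = TRUE)
      w
    })
    res <- tryCatch(
      wham_solve(wb, breaks = full$breaks, tol = tol, max_iter = max_iter),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        sprintf("trial %d: %s", t, conditionMessage(res))
    } else {
      trials[, t] <- res$g   # already anchored to min 0
    }
  }
  ok <- colSums(!is.na(trials)) > 0
  if (sum(ok) < 2)
    stop_invalid("bootstrap_profile: fewer than 2 bootstrap trials succeeded")
  if (length(failures) > 0)
    warning(sprintf("bootstrap_profile: %d of %d trials failed (see attr 'failed_trials')",
                    length(failures), n_trials), call. = FALSE)
  full$stderr <- apply(trials[, ok, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  full$stderr[is.na(full$g)] <- NA_real_
  attr(full, "failed_trials") <- failures
  attr(full, "n_trials") <- sum(ok)
  full
}

#' Free-energy barrier between a reactant and a transition-state region
#'
#' Computes the barrier height \eqn{\Delta G^\ddagger} as the maximum free
#' energy over `ts_range` minus the minimum over `reactant_range`, using only
#' populated bins. Ties are broken towards the lowest reaction-coordinate
#' value.
#'
#' @param profile A `fep_profile` from [wham_solve()].
#' @param reactant_range Length-2 numeric, reaction-coordinate interval (A)
#'   containing the reactant basin.
#' @param ts_range Length-2 numeric interval containing the barrier top.
#' @return A list of class `barrier_report` with `reactant_R`, `ts_R`
#'   (positions of the extrema) and `delta_g_barrier` (kcal mol^-1).
#' @export
barrier_height <- function(profile, reactant_range, ts_range) {
  stopifnot(inherits(profile, "fep_profile"))
  pick <- function(range, what) {
    inr <- profile$bin_centers >= min(range) &
      profile$bin_centers <= max(range) & !is.na(profile$g)
    if (!any(inr))
      stop_invalid("barrier_height: %s range [%g, %g] contains no populated bins",
                   what, min(range), max(range))
    inr
  }
  ri <- pick(reactant_range, "reactant")
  ti <- pick(ts_range, "transition-state")
  gr <- profile$g[ri]; xr <- profile$bin_centers[ri]
  gt <- profile$g[ti]; xt <- profile$bin_centers[ti]
  i_min <- which(gr == min(gr))[1]   # lowest-R extremum wins ties
  i_max <- which(gt == max(gt))[1]
  structure(
    list(reactant_R = xr[i_min], ts_R = xt[i_max],
         delta_g_barrier = gt[i_max] - gr[i_min]),
    class = "barrier_report")
}

#' @export
print.barrier_report <- function(x, ...) {
  cat(sprintf("barrier: dG = %.3f kcal/mol (reactant R = %.2f A, TS R = %.2f A)\n",
              x$delta_g_barrier, x$reactant_R, x$ts_R))
  invisible(x)
}
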