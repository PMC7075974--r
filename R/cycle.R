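#' Five-state kinetic model of the Hsp90 chaperone cycle
#'
#' Builds the unidirectional single-enzyme cycle
#' open -> closed1_ATP_inactive -> active -> closed2_ATP_active ->
#' closed2_ADP_Pi -> open. ATP binding is lumped into the first closing step
#' (saturating nucleotide) and reverse reactions are omitted. Default rates
#' are calibrated so that (i) the baseline turnover matches the measured
#' wild-type ADP-release scale (about 0.5 min^-1) and (ii) the closing
#' pathway and the catalytic step contribute comparably to the cycle time:
#' the three conformational (closing) steps at 3 min^-1 each, catalysis at
#' 1 min^-1 and product release at 60 min^-1 give a steady-state turnover of
#' \eqn{1/(3 \cdot 1/3 + 1 + 1/60) \approx 0.496} min^-1.
#'
#' @return An object of class `cycle_model`: list with `states` (character)
#'   and `reactions` (data frame with `from`, `to`, `rate` in min^-1, `tag`).
#' @export
build_default_model <- function() {
  states <- c("open", "closed1_ATP_inactive", "active",
              "closed2_ATP_active", "closed2_ADP_Pi")
  reactions <- data.frame(
    from = c("open", "closed1_ATP_inactive", "active",
             "closed2_ATP_active", "closed2_ADP_Pi"),
    to = c("closed1_ATP_inactive", "active", "closed2_ATP_active",
           "closed2_ADP_Pi", "open"),
    rate = c(3, 3, 3, 1, 60),
    tag = c("closing", "closing", "closing", "catalysis", "release"),
    stringsAsFactors = FALSE)
  cycle_model(states, reactions)
}

#' Construct a cycle model from states and reactions
#'
#' @param states Character vector of state names.
#' @param reactions Data frame with columns `from`, `to`, `rate` (min^-1,
#'   >= 0) and `tag` (one of closing, switching, catalysis, release,
#'   decoupled).
#' @return A `cycle_model`.
#' @export
cycle_model <- function(states, reactions) {
  req <- c("from", "to", "rate", "tag")
  if (!all(req %in% names(reactions)))
    stop_invalid("cycle_model: reactions need columns %s", paste(req, collapse = ", "))
  if (!all(reactions$from %in% states) || !all(reactions$to %in% states))
    stop_invalid("cycle_model: reaction endpoints must be model states")
  if (any(!is.finite(reactions$rate)) || any(reactions$rate < 0))
    stop_invalid("cycle_model: rates must be >= 0")
  tags <- c("closing", "switching", "catalysis", "release", "decoupled")
  if (!all(reactions$tag %in% tags))
    stop_invalid("cycle_model: unknown reaction tag")
  structure(list(states = states, reactions = reactions),
            class = "cycle_model")
}

#' @export
print.cycle_model <- function(x, ...) {
  cat(sprintf("chaperone cycle model: %d states, %d reactions\n",
              length(x$states), nrow(x$reactions)))
  for (i in seq_len(nrow(x$reactions)))
    cat(sprintf("  %-22s -> %-22s %8.3g min^-1  [%s]\n",
                x$reactions$from[i], x$reactions$to[i],
                x$reactions$rate[i], x$reactions$tag[i]))
  invisible(x)
}

#' Apply a decoupling-mutant perturbation to a cycle model
#'
#' Models a mutation that lowers the catalytic barrier while destabilising
#' the compact conformation: the catalysis rate is multiplied by `f_cat`,
#' every closing-tagged rate is divided by `f_close`, and an optional futile
#' open -> open hydrolysis branch (ATP turnover fully decoupled from closing)
#' is added at rate `k_decoupled`.
#'
#' @param model A `cycle_model`.
#' @param f_cat Fold increase of the catalytic rate (> 0).
#' @param f_close Fold reduction of all closing rates (> 0).
#' @param k_decoupled Rate (min^-1, >= 0) of the decoupled open-state
#'   hydrolysis branch; 0 omits the branch.
#' @return The perturbed `cycle_model`.
#' @export
build_variant <- function(model, f_cat = 1, f_close = 1, k_decoupled = 0) {
  stopifnot(inherits(model, "cycle_model"))
  if (!is.finite(f_cat) || f_cat <= 0 || !is.finite(f_close) || f_close <= 0)
    stop_invalid("build_variant: f_cat and f_close must be > 0")
  if (!is.finite(k_decoupled) || k_decoupled < 0)
    stop_invalid("build_variant: k_decoupled must be >= 0")
  rx <- model$reactions
  rx$rate[rx$tag == "catalysis"] <- rx$rate[rx$tag == "catalysis"] * f_cat
  rx$rate[rx$tag == "closing"] <- rx$rate[rx$tag == "closing"] / f_close
  if (k_decoupled > 0)
    rx <- rbind(rx, data.frame(from = "open", to = "open",
                               rate = k_decoupled, tag = "decoupled"))
  cycle_model(model$states, rx)
}

#' Stationary occupancies and turnover of a cycle model
#'
#' Solves the linear stationary master equation of the single-enzyme Markov
#' chain. Self-loop (decoupled) reactions do not alter occupancies; their
#' flux is reported separately. Turnover is the release flux:
#' release rate times the occupancy of its source state.
#'
#' @param model A `cycle_model` with strictly positive cycle rates.
#' @return List of class `steady_state_result` with `occupancy` (named,
#'   sums to 1), `turnover` (min^-1), `decoupled_flux` (min^-1) and
#'   `fluxes` (per reaction).
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "cycle_model"))
  st <- model$states
  K <- length(st)
  rx <- model$reactions
  proper <- rx$from != rx$to
  Q <- matrix(0, K, K, dimnames = list(st, st))
  for (i in which(proper)) {
    Q[rx$from[i], rx$to[i]] <- Q[rx$from[i], rx$to[i]] + rx$rate[i]
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  A <- t(Q)
  A[K, ] <- 1                      # replace one balance row by normalisation
  b <- c(rep(0, K - 1), 1)
  pi_ <- tryCatch(solve(A, b), error = function(e)
    stop_invalid("steady_state: singular stationary system (disconnected model?)"))
  if (any(pi_ < -1e-8))
    stop_invalid("steady_state: negative stationary occupancy; model is not a proper chain")
  pi_ <- pmax(pi_, 0); pi_ <- pi_ / sum(pi_)
  names(pi_) <- st
  fluxes <- rx$rate * pi_[rx$from]
  rel <- rx$tag == "release"
  dec <- rx$tag == "decoupled"
  structure(
    list(occupancy = pi_,
         turnover = sum(fluxes[rel]),
         decoupled_flux = sum(fluxes[dec]),
         fluxes = data.frame(rx[, c("from", "to", "tag")],
                             flux = unname(fluxes))),
    class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("steady state: turnover %.4g min^-1", x$turnover))
  if (x$decoupled_flux > 0)
    cat(sprintf(" (+ decoupled flux %.4g min^-1)", x$decoupled_flux))
  cat("\n  occupancies:\n")
  for (s in names(x$occupancy))
    cat(sprintf("    %-22s %.4f\n", s, x$occupancy[s]))
  invisible(x)
}

#' Stochastic simulation (Gillespie direct method) of the chaperone cycle
#'
#' Simulates `n_enzymes` independent single-enzyme trajectories of the
#' continuous-time Markov chain with the exact direct-method SSA, logging
#' every reaction event. Decoupled self-loop reactions are logged as events
#' without changing the state.
#'
#' @param model A `cycle_model`.
#' @param t_end Simulated time per enzyme, minutes (> 0).
#' @param n_enzymes Number of independent enzymes (>= 1).
#' @param seed Integer seed; the event log is bit-reproducible given the seed.
#' @param init_state Starting state, default `"open"`.
#' @return List of class `ssa_result` with `events` (data frame: `enzyme`,
#'   `time`, `tag`, `from`, `to`), `occupancy` (time-weighted fractions,
#'   sums to 1), `turnover` (release events per enzyme per minute),
#'   `turnover_sem` (between-enzyme SEM), `decoupled_events`, `seed`,
#'   `t_end` and `n_enzymes`.
#' @export
simulate_ssa <- function(model, t_end, n_enzymes = 1, seed = 1,
                         init_state = "open") {
  stopifnot(inherits(model, "cycle_model"))
  if (!is.finite(t_end) || t_end <= 0) stop_invalid("simulate_ssa: t_end must be > 0")
  if (n_enzymes < 1) stop_invalid("simulate_ssa: n_enzymes must be >= 1")
  if (all(model$reactions$rate == 0))
    stop_invalid("simulate_ssa: all rates are zero")
  if (!init_state %in% model$states)
    stop_invalid("simulate_ssa: unknown initial state '%s'", init_state)
  set.seed(seed)
  st <- model$states
  rx <- model$reactions
  # per-state outgoing reaction index
  out_idx <- lapply(st, function(s) which(rx$from == s))
  names(out_idx) <- st
  occ_time <- stats::setNames(numeric(length(st)), st)
  ev_time_l <- vector("list", n_enzymes)
  ev_rxn_l <- vector("list", n_enzymes)
  release_counts <- integer(n_enzymes)
  for (e in seq_len(n_enzymes)) {
    state <- init_state
    t <- 0
    cap <- 256L; nev <- 0L
    et <- numeric(cap); er <- integer(cap)
    repeat {
      idx <- out_idx[[state]]
      rates <- rx$rate[idx]
      tot <- sum(rates)
      if (tot <= 0) {              # absorbing state: sit until t_end
        occ_time[state] <- occ_time[state] + (t_end - t)
        break
      }
      dt <- stats::rexp(1, tot)
      if (t + dt >= t_end) {
        occ_time[state] <- occ_time[state] + (t_end - t)
        break
      }
      occ_time[state] <- occ_time[state] + dt
      t <- t + dt
      j <- if (length(idx) == 1) idx else
        idx[sample.int(length(idx), 1, prob = rates)]
      nev <- nev + 1L
      if (nev > cap) {             # grow by doubling
        cap <- cap * 2L
        et <- c(et, numeric(cap / 2L)); er <- c(er, integer(cap / 2L))
      }
      et[nev] <- t; er[nev] <- j
      if (rx$tag[j] == "release")
        release_counts[e] <- release_counts[e] + 1L
      state <- rx$to[j]
    }
    ev_time_l[[e]] <- et[seq_len(nev)]
    ev_rxn_l[[e]] <- er[seq_len(nev)]
  }
  ev_rxn <- unlist(ev_rxn_l)
  events <- data.frame(
    enzyme = rep(seq_len(n_enzymes), lengths(ev_time_l)),
    time = unlist(ev_time_l),
    tag = rx$tag[ev_rxn], from = rx$from[ev_rxn], to = rx$to[ev_rxn])
  per_enzyme_rate <- release_counts / t_end
  structure(
    list(events = events,
         occupancy = occ_time / sum(occ_time),
         turnover = mean(per_enzyme_rate),
         turnover_sem = if (n_enzymes > 1)
           stats::sd(per_enzyme_rate) / sqrt(n_enzymes) else NA_real_,
         decoupled_events = sum(events$tag == "decoupled"),
         seed = seed, t_end = t_end, n_enzymes = n_enzymes),
    class = "ssa_result")
}

#' @export
print.ssa_result <- function(x, ...) {
  cat(sprintf(
    "SSA: %d enzymes x %g min, %d events; turnover %.4g +/- %.2g min^-1\n",
    x$n_enzymes, x$t_end, nrow(x$events), x$turnover, x$turnover_sem))
  invisible(x)
}

#' Closing-rate reduction that buffers a catalytic rate increase
#'
#' The decoupling argument: a mutation may accelerate the catalytic step
#' `f_cat`-fold yet leave the observable ADP-release turnover unchanged if
#' the formation of the fully closed conformation is slowed at the same
#' time. This function root-finds (bisection on f_close in [1, 100]) the
#' closing-rate fold reduction for which the perturbed steady-state turnover
#' equals the baseline turnover. For the default calibration, f_cat = 100
#' needs only an approximately 2-fold closing reduction, because closing and
#' catalysis contribute comparably to the cycle time.
#'
#' @param model Baseline `cycle_model`.
#' @param f_cat Catalytic fold increase (> 0).
#' @param tol Absolute tolerance on the turnover match (min^-1).
#' @return The required `f_close` (dimensionless fold).
#' @export
required_closing_reduction <- function(model, f_cat, tol = 1e-9) {
  base <- steady_state(model)$turnover
  g <- function(f) steady_state(build_variant(model, f_cat, f, 0))$turnover - base
  lo <- 1; hi <- 100
  glo <- g(lo); ghi <- g(hi)
  if (abs(glo) <= tol) return(lo)
  if (glo < 0 || ghi > 0)
    stop_invalid(
      "required_closing_reduction: no root in [1, 100] (turnover offsets %.3g, %.3g)",
      glo, ghi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(gm) <= tol || (hi - lo) < 1e-12) return(mid)
    if (gm > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
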