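#' Ion-pair distance trace from labelled trajectory frames
#'
#' Measures the Euclidean distance between two named atoms (e.g. the Arg
#' guanidinium Cz and the Glu carboxylate Cd of an interdomain salt bridge)
#' in every frame of a trajectory.
#'
#' @param frames A `traj_frames` object from [read_pdb_models()] or
#'   [traj_frames()].
#' @param atomA,atomB Atom selections created with [atom_label()].
#' @return A `distance_trace`: data frame with columns `time_ns` and
#'   `distance_A`.
#' @export
sidechain_distance_trace <- function(frames, atomA, atomB) {
  stopifnot(inherits(frames, "traj_frames"))
  n <- length(frames$frames)
  d <- numeric(n)
  for (i in seq_len(n)) {
    a <- .find_atom(frames$frames[[i]], atomA, i)
    b <- .find_atom(frames$frames[[i]], atomB, i)
    d[i] <- sqrt(sum((a - b)^2))
  }
  if (any(d == 0))
    warning("sidechain_distance_trace: coincident atoms (distance 0) in some frames",
            call. = FALSE)
  distance_trace(frames$times, d, .allow_zero = TRUE)
}

#' Atom selection label
#'
#' @param chain Chain identifier (single character).
#' @param resno Residue number.
#' @param atom Atom name (PDB convention, e.g. `"CZ"`, `"OE1"`).
#' @param resid Optional residue name for cross-checking (e.g. `"ARG"`).
#' @return A list usable as a selection in [sidechain_distance_trace()].
#' @export
atom_label <- function(chain, resno, atom, resid = NULL) {
  list(chain = as.character(chain), resno = as.integer(resno),
       atom = as.character(atom), resid = resid)
}

.find_atom <- function(frame, sel, frame_index) {
  hit <- frame$chain == sel$chain & frame$resno == sel$resno &
    frame$elety == sel$atom
  if (!is.null(sel$resid)) hit <- hit & frame$resid == sel$resid
  idx <- which(hit)
  if (length(idx) == 0)
    stop_invalid("atom %s:%d:%s not found in frame %d",
                 sel$chain, sel$resno, sel$atom, frame_index)
  if (length(idx) > 1)
    stop_invalid("atom %s:%d:%s matches %d atoms in frame %d",
                 sel$chain, sel$resno, sel$atom, length(idx), frame_index)
  c(frame$x[idx], frame$y[idx], frame$z[idx])
}

#' Construct a distance trace
#'
#' @param times Frame times in ns, strictly increasing.
#' @param distances Distances in Angstrom, > 0 (0 tolerated with a warning
#'   from [sidechain_distance_trace()]).
#' @param .allow_zero Internal.
#' @return Data frame of class `distance_trace` with columns `time_ns`,
#'   `distance_A`.
#' @export
distance_trace <- function(times, distances, .allow_zero = FALSE) {
  if (length(times) != length(distances))
    stop_invalid("distance_trace: times and distances must have equal length")
  if (length(times) == 0) stop_invalid("distance_trace: empty trace")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop_invalid("distance_trace: times must be finite and strictly increasing")
  lo <- if (.allow_zero) 0 else .Machine$double.eps
  if (any(!is.finite(distances)) || any(distances < lo))
    stop_invalid("distance_trace: distances must be positive and finite")
  structure(data.frame(time_ns = times, distance_A = distances),
            class = c("distance_trace", "data.frame"))
}

#' Classify an ion-pair trace into open and closed states
#'
#' Frames with distance strictly above `threshold` are labelled `"open"`,
#' all others `"closed"` (a frame exactly at the threshold counts as closed;
#' the split is a hard 5 Angstrom rule with no hysteresis).
#'
#' @param trace A [distance_trace()].
#' @param threshold Distance cutoff in Angstrom, default 5.
#' @return A `state_trace`: data frame with `time_ns` and `state`
#'   (factor closed/open), with attributes `threshold` and `occupancy`
#'   (named fractions).
#' @export
classify_ionpair <- function(trace, threshold = 5.0) {
  stopifnot(inherits(trace, "distance_trace"))
  if (nrow(trace) == 0) stop_invalid("classify_ionpair: empty trace")
  state <- factor(ifelse(trace$distance_A > threshold, "open", "closed"),
                  levels = c("closed", "open"))
  occ <- c(closed = mean(state == "closed"), open = mean(state == "open"))
  structure(data.frame(time_ns = trace$time_ns, state = state),
            class = c("state_trace", "data.frame"),
            threshold = threshold, occupancy = occ)
}

#' Dwell times of a state trace
#'
#' Converts contiguous runs of one state into dwell durations using the
#' (uniform) frame spacing. The first and last runs are censored: the entry
#' into the first and the exit from the last state were not observed, so they
#' are reported separately and excluded from the dwell means.
#'
#' @param states A `state_trace` from [classify_ionpair()].
#' @param frame_durations Optional explicit per-frame durations (ns) when the
#'   time grid is not uniform.
#' @return List with per-state dwell vectors (`open`, `closed`, ns), per-state
#'   `means` over uncensored dwells, and `censored` (the first/last run
#'   durations and their states).
#' @export
dwell_times <- function(states, frame_durations = NULL) {
  stopifnot(inherits(states, "state_trace"))
  n <- nrow(states)
  if (n < 1) stop_invalid("dwell_times: empty state trace")
  if (is.null(frame_durations)) {
    if (n == 1) {
      dt <- 1
    } else {
      dts <- diff(states$time_ns)
      if (diff(range(dts)) > 1e-9 * max(dts))
        stop_invalid("dwell_times: non-uniform frame spacing; supply frame_durations")
      dt <- dts[1]
    }
    frame_durations <- rep(dt, n)
  }
  if (length(frame_durations) != n)
    stop_invalid("dwell_times: frame_durations length mismatch")
  r <- rle(as.character(states$state))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dur <- vapply(seq_along(r$lengths),
                function(i) sum(frame_durations[starts[i]:ends[i]]),
                numeric(1))
  k <- length(dur)
  censored_idx <- unique(c(1L, k))
  interior <- setdiff(seq_len(k), censored_idx)
  out <- list(
    open = dur[interior][r$values[interior] == "open"],
    closed = dur[interior][r$values[interior] == "closed"],
    censored = data.frame(state = r$values[censored_idx],
                          duration_ns = dur[censored_idx]))
  out$means <- c(open = if (length(out$open)) mean(out$open) else NA_real_,
                 closed = if (length(out$closed)) mean(out$closed) else NA_real_)
  out
}

# charged heavy atoms considered for salt bridges
.charged_atoms <- list(
  positive = list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                  HIS = c("ND1", "NE2")),
  negative = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")))

.residue_charge_atoms <- function(frame, chain, resno) {
  sel <- frame$chain == chain & frame$resno == resno
  if (!any(sel)) return(NULL)
  resid <- frame$resid[sel][1]
  pos <- .charged_atoms$positive[[resid]]
  neg <- .charged_atoms$negative[[resid]]
  atoms <- frame$elety[sel]
  # C-terminal carboxylate counts as negative
  if ("OXT" %in% atoms) neg <- c(neg, "O", "OXT")
  use_pos <- sel & frame$elety %in% pos
  use_neg <- sel & frame$elety %in% neg
  if (!any(use_pos) && !any(use_neg)) return(NULL)
  list(resid = resid,
       sign = if (any(use_pos)) +1 else -1,
       xyz = cbind(frame$x, frame$y, frame$z)[if (any(use_pos)) use_pos else use_neg, ,
                                              drop = FALSE])
}

#' Count salt bridges between two residue groups in one frame
#'
#' A residue pair (one residue from each group, opposite formal charge)
#' counts once if any pair of their charged heavy atoms (Arg NH1/NH2/NE,
#' Lys NZ, His ND1/NE2, Asp OD1/OD2, Glu OE1/OE2, C-terminal carboxylate)
#' lies within `cutoff`.
#'
#' @param frame A single frame (data frame with `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z`), e.g. one element of `traj_frames$frames`.
#' @param groupA,groupB Data frames with columns `chain` and `resno` naming
#'   the residues of each group; groups must be disjoint.
#' @param cutoff Heavy-atom distance cutoff, Angstrom (default 4).
#' @return List with `count` and `pairs` (data frame of contacting residue
#'   pairs with their minimum atom distance).
#' @export
count_ion_pairs <- function(frame, groupA, groupB, cutoff = 4.0) {
  keyA <- paste(groupA$chain, groupA$resno)
  keyB <- paste(groupB$chain, groupB$resno)
  if (length(intersect(keyA, keyB)) > 0)
    stop_invalid("count_ion_pairs: groups must be disjoint")
  getg <- function(g) {
    out <- list()
    for (i in seq_len(nrow(g))) {
      ca <- .residue_charge_atoms(frame, g$chain[i], g$resno[i])
      if (is.null(ca)) {
        warning(sprintf("count_ion_pairs: residue %s:%d has no charged atoms; skipped",
                        g$chain[i], g$resno[i]), call. = FALSE)
      } else {
        ca$chain <- g$chain[i]; ca$resno <- g$resno[i]
        out[[length(out) + 1]] <- ca
      }
    }
    out
  }
  ga <- getg(groupA); gb <- getg(groupB)
  pairs <- data.frame(chainA = character(), resnoA = integer(),
                      chainB = character(), resnoB = integer(),
                      min_dist_A = numeric())
  for (a in ga) for (b in gb) {
    if (a$sign * b$sign >= 0) next  # only opposite charges
    dmat <- sqrt(pmax(outer(rowSums(a$xyz^2), rowSums(b$xyz^2), "+") -
                        2 * a$xyz %*% t(b$xyz), 0))
    dmin <- min(dmat)
    if (dmin <= cutoff)
      pairs <- rbind(pairs, data.frame(
        chainA = a$chain, resnoA = a$resno,
        chainB = b$chain, resnoB = b$resno, min_dist_A = dmin))
  }
  list(count = nrow(pairs), pairs = pairs)
}

#' Fit a coulombic 1/distance model to barrier-vs-distance data
#'
#' Linear least squares of the catalytic barrier against the inverse ion-pair
#' distance, \eqn{\Delta G^\ddagger(d) = a + b/d}: `a` is the fully screened
#' (infinite-separation) barrier and `b` the effective coulombic coupling
#' strength (kcal mol^-1 Angstrom).
#'
#' @param d Ion-pair distances, Angstrom (>= 3 distinct values).
#' @param barrier Barrier heights, kcal mol^-1.
#' @return A `biophys_fit` with estimates `a`, `b`, their standard errors,
#'   residuals and `r_squared`.
#' @export
fit_inverse_distance <- function(d, barrier) {
  if (length(d) != length(barrier) || length(d) < 3)
    stop_invalid("fit_inverse_distance: need >= 3 (d, barrier) points")
  if (length(unique(d)) < 2)
    stop_invalid("fit_inverse_distance: all distances identical (rank deficient)")
  inv <- 1 / d
  fit <- stats::lm(barrier ~ inv)
  cf <- summary(fit)$coefficients
  new_biophys_fit(
    model = "inverse_distance",
    estimate = c(a = unname(cf[1, 1]), b = unname(cf[2, 1])),
    se = c(a = unname(cf[1, 2]), b = unname(cf[2, 2])),
    residuals = unname(stats::residuals(fit)),
    converged = TRUE,
    extra = list(r_squared = summary(fit)$r.squared))
}

#' Coulombic pKa shift of an acidic residue from a nearby charge
#'
#' Point-charge estimate of how much a neighbouring charge (e.g. an arginine
#' guanidinium at distance d from a glutamate carboxylate) shifts the
#' glutamate's pKa, screening the interaction with a uniform dielectric:
#' \deqn{\Delta pK_a = \frac{C\,|q_1 q_2|}{\varepsilon\, d\, \ln 10\, RT},}
#' with C = 332.06 kcal Angstrom mol^-1 e^-2. With the protein-interior
#' dielectric 4 and d = 5.5 Angstrom this gives roughly 10 pKa units,
#' i.e. ion-pair opening converts the glutamate from a strong acid into an
#' effective proton acceptor.
#'
#' @param d Charge separation, Angstrom.
#' @param epsilon Dielectric constant (> 0), default 4.
#' @param q1,q2 Formal charges in elementary units (defaults +1, -1).
#' @param temperature Temperature in K, default 310.
#' @return pKa shift (dimensionless, positive).
#' @export
coulomb_pka_shift <- function(d, epsilon = 4, q1 = 1, q2 = -1,
                              temperature = 310) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop_invalid("coulomb_pka_shift: d must be > 0")
  if (!is.finite(epsilon) || epsilon <= 0)
    stop_invalid("coulomb_pka_shift: epsilon must be > 0")
  phys_constants$coulomb_kcal * abs(q1 * q2) /
    (epsilon * d * log(10) * phys_constants$R_kcal * temperature)
}
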