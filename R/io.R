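# File readers/writers and the command-line surface.
#
# All tabular schemas are plain text with headers; units are part of the
# column names (time_ns, distance_A) or of the window-file header so that
# minutes-vs-seconds and Angstrom conventions are always explicit.

#' Read a distance trace CSV
#'
#' Expects a CSV with header columns `time_ns` and `distance_A`; extra
#' columns are ignored with a warning. Times must be strictly increasing.
#'
#' @param path Path to the CSV file.
#' @return A [distance_trace()].
#' @export
read_distance_trace <- function(path) {
  if (!file.exists(path)) stop_invalid("read_distance_trace: no such file: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop_invalid("read_distance_trace: %s: %s", path,
                                conditionMessage(e)))
  if (nrow(df) == 0) stop_invalid("read_distance_trace: %s is empty", path)
  req <- c("time_ns", "distance_A")
  if (!all(req %in% names(df)))
    stop_invalid("read_distance_trace: %s must have columns time_ns, distance_A", path)
  extra <- setdiff(names(df), req)
  if (length(extra) > 0)
    warning(sprintf("read_distance_trace: ignoring extra columns: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(df$time_ns) | !is.finite(df$distance_A))
  if (length(bad) > 0)
    stop_invalid("read_distance_trace: malformed row at line %d of %s",
                 bad[1] + 1L, path)
  distance_trace(df$time_ns, df$distance_A)
}

#' Write a distance trace CSV
#'
#' @param trace A [distance_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_trace <- function(trace, path) {
  stopifnot(inherits(trace, "distance_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an umbrella-window file
#'
#' Delimited text with `# key value` header lines declaring `center`,
#' `force_constant`, `temperature` and `bias_convention`, followed by one
#' sampled reaction-coordinate value per line.
#'
#' @param path Path to the window file.
#' @return An [umbrella_window()].
#' @export
read_umbrella_window <- function(path) {
  if (!file.exists(path)) stop_invalid("read_umbrella_window: no such file: %s", path)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  keys <- list()
  for (l in lines[hdr]) {
    parts <- strsplit(sub("^#\\s*", "", l), "\\s+")[[1]]
    if (length(parts) >= 2) keys[[parts[1]]] <- parts[2]
  }
  for (k in c("center", "force_constant"))
    if (is.null(keys[[k]]))
      stop_invalid("read_umbrella_window: %s missing header key '%s'", path, k)
  vals <- suppressWarnings(as.numeric(lines[!hdr & nzchar(trimws(lines))]))
  if (length(vals) == 0 || any(is.na(vals)))
    stop_invalid("read_umbrella_window: %s has missing or malformed samples", path)
  umbrella_window(
    center = as.numeric(keys$center),
    force_constant = as.numeric(keys$force_constant),
    samples = vals,
    temperature = as.numeric(keys$temperature %||% 310),
    bias_convention = keys$bias_convention %||% "half_k")
}

#' Write an umbrella-window file
#'
#' @param window An [umbrella_window()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_umbrella_window <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# center %.10g", window$center),
    sprintf("# force_constant %.10g", window$force_constant),
    sprintf("# temperature %.10g", window$temperature),
    sprintf("# bias_convention %s", window$bias_convention),
    format(window$samples, digits = 12, trim = TRUE, scientific = FALSE)),
    con)
  invisible(path)
}

#' Write a free-energy profile as TSV
#'
#' Columns: `bin_center`, `g`, `stderr`, `count`.
#'
#' @param profile A `fep_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fep_profile"))
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a trajectory-frames object
#'
#' @param frames List of per-frame data frames with columns `chain`,
#'   `resno`, `resid`, `elety`, `x`, `y`, `z`.
#' @param times Frame times, ns (default 0, 1, 2, ...).
#' @return An object of class `traj_frames`.
#' @export
traj_frames <- function(frames, times = seq_along(frames) - 1) {
  if (length(frames) != length(times))
    stop_invalid("traj_frames: times length must match frame count")
  structure(list(frames = frames, times = as.numeric(times)),
            class = "traj_frames")
}

#' @export
print.traj_frames <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms in frame 1\n",
              length(x$frames), nrow(x$frames[[1]])))
  invisible(x)
}

#' Read a (multi-model) PDB file into labelled frames
#'
#' Parses ATOM/HETATM records with bio3d; each MODEL becomes one frame (a
#' single implicit model if the file has none). Alternate locations are
#' resolved to the highest-occupancy conformer, ties going to altloc "A".
#' Duplicate atom labels (chain, residue, atom name) within a model are an
#' error.
#'
#' @param path Path to the PDB file.
#' @param times Optional frame times in ns (default 0, 1, 2, ...).
#' @return A [traj_frames()] object.
#' @export
read_pdb_models <- function(path, times = NULL) {
  if (!file.exists(path)) stop_invalid("read_pdb_models: no such file: %s", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at$row <- seq_len(nrow(at))   # position in the xyz triplets
  if (nrow(at) == 0) stop_invalid("read_pdb_models: %s has no atoms", path)
  if (any(is.na(at$x) | is.na(at$y) | is.na(at$z)))
    stop_invalid("read_pdb_models: %s has missing coordinates", path)
  at$chain[is.na(at$chain)] <- " "
  # altloc resolution: highest occupancy, tie -> "A"
  alt <- !is.na(at$alt) & nzchar(at$alt) & at$alt != " "
  if (any(alt)) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[alt])) {
      idx <- which(key == k)
      if (length(idx) > 1) {
        occ <- at$o[idx]; occ[is.na(occ)] <- 1
        best <- idx[order(-occ, at$alt[idx])][1]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    at <- at[keep, ]
  }
  n_models <- max(1L, nrow(pdb$xyz))
  xyz <- pdb$xyz
  frames <- vector("list", n_models)
  base <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                     elety = at$elety, stringsAsFactors = FALSE)
  key <- paste(base$chain, base$resno, base$elety)
  if (anyDuplicated(key))
    stop_invalid("read_pdb_models: duplicate atom label '%s' within a model",
                 key[duplicated(key)][1])
  # indices of the retained atoms in the xyz triplets
  sel_idx <- at$row
  for (m in seq_len(n_models)) {
    row <- xyz[m, ]
    fr <- base
    fr$x <- row[3 * (sel_idx - 1) + 1]
    fr$y <- row[3 * (sel_idx - 1) + 2]
    fr$z <- row[3 * (sel_idx - 1) + 3]
    frames[[m]] <- fr
  }
  traj_frames(frames, times %||% (seq_len(n_models) - 1))
}

# ---------------------------------------------------------------------------
# Command-line surface
# ---------------------------------------------------------------------------

.cli_usage <- paste(
  "usage: hsp90cycle <subcommand> [options]",
  "subcommands:",
  "  rates    --barrier G | --rate K  [--temp 310] [--kappa 1]",
  "  wham     --windows f1,f2,...  [--out profile.tsv] [--bin-width 0.1]",
  "           [--bootstrap N --seed S]",
  "  ionpair  --trace trace.csv [--threshold 5] [--out states.csv]",
  "  cycle    --mode steady|simulate|scan [--f-cat F] [--f-close F]",
  "           [--k-decoupled K] [--t-end 500] [--n-enzymes 200] [--seed 1]",
  "  fit      --type monoexp|mm --in data.csv",
  "  synth    --generator fret|adp|telegraph|guinier --seed 1 --out file.csv",
  "  pr       --pdb file.pdb [--bin-width 1]",
  sep = "\n")

.cli_parse <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(argv) && !startsWith(argv[i + 1L], "--")) {
        opts[[key]] <- argv[i + 1L]; i <- i + 2L
      } else {
        opts[[key]] <- TRUE; i <- i + 1L
      }
    } else {
      opts$positional <- c(opts$positional, a); i <- i + 1L
    }
  }
  opts
}

.cli_json <- function(x) {
  cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE), "\n")
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions, suitable for wrapping in an
#' Rscript executable (see `inst/cli/hsp90cycle`). Results are printed as
#' JSON; file outputs use the package's text schemas.
#'
#' @param argv Character vector of arguments (subcommand first).
#' @return Integer exit status, invisibly: 0 success, 1 computation error,
#'   2 usage error.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    message(.cli_usage); return(invisible(2L))
  }
  if (argv[1] %in% c("--help", "-h", "help")) {
    cat(.cli_usage, "\n"); return(invisible(0L))
  }
  sub <- argv[1]
  opts <- .cli_parse(argv[-1])
  handler <- switch(sub,
                    rates = .cli_rates, wham = .cli_wham,
                    ionpair = .cli_ionpair, cycle = .cli_cycle,
                    fit = .cli_fit, synth = .cli_synth, pr = .cli_pr,
                    NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", sub, "\n", .cli_usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    handler(opts)
    0L
  },
  usage_error = function(e) { message(conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

.usage_stop <- function(msg) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.opt_num <- function(opts, key, default = NULL) {
  v <- opts[[key]] %||% default
  if (is.null(v)) return(NULL)
  as.numeric(v)
}

.cli_rates <- function(opts) {
  temp <- .opt_num(opts, "temp", 310)
  kappa <- .opt_num(opts, "kappa", 1)
  if (!is.null(opts$barrier)) {
    g <- .opt_num(opts, "barrier")
    k <- rate_from_barrier(g, temp, kappa)
    .cli_json(list(barrier_kcal_mol = g, temperature_K = temp,
                   rate_per_s = k, timescale = timescale_label(k)))
  } else if (!is.null(opts$rate)) {
    k <- .opt_num(opts, "rate")
    .cli_json(list(rate_per_s = k, temperature_K = temp,
                   barrier_kcal_mol = barrier_from_rate(k, temp, kappa),
                   timescale = timescale_label(k)))
  } else .usage_stop("rates: need --barrier or --rate")
}

.cli_wham <- function(opts) {
  if (is.null(opts$windows)) .usage_stop("wham: need --windows f1,f2,...")
  paths <- strsplit(opts$windows, ",")[[1]]
  windows <- lapply(paths, read_umbrella_window)
  bw <- .opt_num(opts, "bin-width", 0.1)
  nboot <- .opt_num(opts, "bootstrap", 0)
  prof <- if (nboot > 0)
    bootstrap_profile(windows, n_trials = nboot,
                      seed = .opt_num(opts, "seed", 1), bin_width = bw)
  else wham_solve(windows, bin_width = bw)
  if (!is.null(opts$out)) write_profile(prof, opts$out)
  pop <- !is.na(prof$g)
  .cli_json(list(n_windows = length(windows), n_bins = sum(pop),
                 g_max = max(prof$g, na.rm = TRUE),
                 iterations = prof$iterations,
                 out = opts$out %||% NA))
}

.cli_ionpair <- function(opts) {
  if (is.null(opts$trace)) .usage_stop("ionpair: need --trace file.csv")
  tr <- read_distance_trace(opts$trace)
  st <- classify_ionpair(tr, .opt_num(opts, "threshold", 5))
  if (!is.null(opts$out))
    utils::write.csv(data.frame(time_ns = st$time_ns, state = st$state),
                     opts$out, row.names = FALSE, quote = FALSE)
  occ <- attr(st, "occupancy")
  .cli_json(list(n_frames = nrow(st), threshold_A = attr(st, "threshold"),
                 occupancy_closed = occ[["closed"]],
                 occupancy_open = occ[["open"]]))
}

.cli_cycle <- function(opts) {
  mode <- opts$mode %||% "steady"
  model <- build_variant(build_default_model(),
                         f_cat = .opt_num(opts, "f-cat", 1),
                         f_close = .opt_num(opts, "f-close", 1),
                         k_decoupled = .opt_num(opts, "k-decoupled", 0))
  if (mode == "steady") {
    ss <- steady_state(model)
    .cli_json(list(turnover_per_min = ss$turnover,
                   decoupled_flux_per_min = ss$decoupled_flux,
                   occupancy = as.list(ss$occupancy)))
  } else if (mode == "simulate") {
    res <- simulate_ssa(model, t_end = .opt_num(opts, "t-end", 500),
                        n_enzymes = .opt_num(opts, "n-enzymes", 200),
                        seed = .opt_num(opts, "seed", 1))
    if (!is.null(opts$out))
      utils::write.csv(res$events, opts$out, row.names = FALSE, quote = FALSE)
    .cli_json(list(turnover_per_min = res$turnover,
                   turnover_sem = res$turnover_sem,
                   n_events = nrow(res$events),
                   occupancy = as.list(res$occupancy)))
  } else if (mode == "scan") {
    f_cat <- .opt_num(opts, "f-cat", 100)
    f <- required_closing_reduction(build_default_model(), f_cat)
    .cli_json(list(f_cat = f_cat, required_f_close = f))
  } else .usage_stop("cycle: --mode must be steady, simulate or scan")
}

.cli_fit <- function(opts) {
  if (is.null(opts$type) || is.null(opts$`in`))
    .usage_stop("fit: need --type and --in")
  df <- utils::read.csv(opts$`in`)
  if (opts$type == "monoexp") {
    res <- fit_monoexponential(df[[1]], df[[2]])
  } else if (opts$type == "mm") {
    res <- fit_michaelis_menten(df[[1]], df[[2]])
  } else .usage_stop("fit: --type must be monoexp or mm")
  .cli_json(list(model = res$model, converged = res$converged,
                 estimate = as.list(res$estimate), se = as.list(res$se)))
}

.cli_synth <- function(opts) {
  gen <- opts$generator %||% .usage_stop("synth: need --generator")
  seed <- .opt_num(opts, "seed", 1)
  out <- opts$out %||% .usage_stop("synth: need --out")
  obj <- switch(gen,
                fret = gen_fret_trace(seed = seed),
                adp = gen_adp_trace(seed = seed),
                telegraph = {
                  tr <- gen_two_state_trace(seed = seed)
                  data.frame(time_ns = tr$time_ns, distance_A = tr$distance_A)
                },
                guinier = gen_guinier_curve(seed = seed, sigma_rel = 0.01),
                .usage_stop(paste("synth: unknown generator", gen)))
  utils::write.csv(as.data.frame(obj), out, row.names = FALSE, quote = FALSE)
  truth <- attr(obj, "truth")
  if (!is.null(truth)) {
    truth$states <- NULL
    jsonlite::write_json(truth, paste0(out, ".truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  .cli_json(list(generator = gen, seed = seed, out = out))
}

.cli_pr <- function(opts) {
  if (is.null(opts$pdb)) .usage_stop("pr: need --pdb file")
  frames <- read_pdb_models(opts$pdb)
  fr <- frames$frames[[1]]
  pr <- pr_from_coordinates(cbind(fr$x, fr$y, fr$z),
                            bin_width = .opt_num(opts, "bin-width", 1))
  .cli_json(list(n_atoms = nrow(fr), d_max_A = pr$d_max, rg_A = pr$rg))
}
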