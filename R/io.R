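config_schema <- list(
  seed = "integer",
  scenario = c("N_S", "N_R", "regime", "shared_theta", "x", "y", "ranges"),
  solver = c("t_end", "n_out", "rtol", "atol", "method", "project_every"),
  drift = c("mode", "positivity", "tau_infinite_threshold", "zero_tol"),
  protocol = c("D", "cycle_hours", "n_cycles", "fresh_c", "carryover", "T_growth"),
  output = c("dir")
)

config_defaults <- list(
  seed = 1L,
  scenario = list(N_S = 10L, N_R = 3L, regime = "slow_lowgamma",
                  shared_theta = TRUE, x = 1, y = 1, ranges = NULL),
  solver = list(t_end = 1000, n_out = 201, rtol = 1e-8, atol = 1e-10,
                method = "lsoda", project_every = 1L),
  drift = list(mode = "adaptive", positivity = TRUE,
               tau_infinite_threshold = 1e6, zero_tol = 1e-12),
  protocol = NULL,
  output = list(dir = ".")
)

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration describing a reproducible run: the
#' random scenario, solver settings, allocation-drift options, an optional
#' serial-dilution protocol, the output directory and the seed. Unknown
#' keys are rejected by name; missing keys receive documented defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config` list with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- config_defaults
  for (section in names(raw)) {
    val <- raw[[section]]
    if (section == "seed") { cfg$seed <- as.integer(val); next }
    allowed <- config_schema[[section]]
    bad <- setdiff(names(val), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in `%s`: %s", section,
                   paste(bad, collapse = ", ")))
    merged <- cfg[[section]]
    if (is.null(merged)) merged <- list()
    merged[names(val)] <- val
    cfg[[section]] <- merged
  }
  cfg$source <- normalizePath(path)
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param config A `run_config` (or plain list with the same sections).
#' @param path Destination `.yaml` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  config$source <- NULL
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a trajectory as a tidy delimited table
#'
#' Long format with columns `time`, `kind` (biomass / resource / phi /
#' residual), `species`, `resource`, `value`; values are printed with 17
#' significant digits so that re-reading reproduces them to full double
#' precision. Metadata lines are '#'-prefixed.
#'
#' @param traj A `cpr_trajectory`.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  ns <- traj$params$n_species; nr <- traj$params$n_resources
  t <- traj$times; nt <- length(t)
  rows <- rbind(
    data.frame(time = rep(t, ns), kind = "biomass",
               species = rep(seq_len(ns), each = nt), resource = NA_integer_,
               value = as.vector(traj$m)),
    data.frame(time = rep(t, nr), kind = "resource", species = NA_integer_,
               resource = rep(seq_len(nr), each = nt),
               value = as.vector(traj$c)),
    data.frame(time = rep(t, ns * nr), kind = "phi",
               species = rep(rep(seq_len(ns), each = nt), nr),
               resource = rep(seq_len(nr), each = nt * ns),
               value = as.vector(traj$phi)),
    data.frame(time = t, kind = "residual", species = NA_integer_,
               resource = NA_integer_, value = traj$diagnostics$max_residual))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cprmodel trajectory: %d species, %d resources, %d times",
                     ns, nr, nt), con)
  writeLines("time\tkind\tspecies\tresource\tvalue", con)
  writeLines(sprintf("%.17g\t%s\t%s\t%s\t%.17g", rows$time, rows$kind,
                     ifelse(is.na(rows$species), "NA", rows$species),
                     ifelse(is.na(rows$resource), "NA", rows$resource),
                     rows$value), con)
  invisible(path)
}

#' Read a trajectory table written by [write_trajectory()]
#'
#' @param path TSV path.
#' @return List with `times`, `m`, `c`, `phi` and `max_residual`, matching
#'   the in-memory trajectory fields at full precision.
#' @export
read_trajectory <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         na.strings = "NA",
                         colClasses = c(time = "numeric", kind = "character",
                                        species = "integer",
                                        resource = "integer",
                                        value = "numeric"))
  times <- sort(unique(d$time))
  nt <- length(times)
  ns <- max(d$species, na.rm = TRUE)
  nr <- max(d$resource, na.rm = TRUE)
  m <- matrix(d$value[d$kind == "biomass"], nt, ns)
  cc <- matrix(d$value[d$kind == "resource"], nt, nr)
  phi <- array(d$value[d$kind == "phi"], dim = c(nt, ns, nr))
  list(times = times, m = m, c = cc, phi = phi,
       max_residual = d$value[d$kind == "residual"])
}

write_provenance <- function(config, seed, path) {
  prov <- list(
    config_md5 = if (!is.null(config$source)) unname(tools::md5sum(config$source))
                 else NA_character_,
    seed = seed,
    package_version = as.character(utils::packageVersion("cprmodel")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

cli_build <- function(cfg) {
  spec <- scenario_spec(N_S = cfg$scenario$N_S, N_R = cfg$scenario$N_R,
                        seed = cfg$seed, regime = cfg$scenario$regime,
                        shared_theta = cfg$scenario$shared_theta,
                        x = cfg$scenario$x, y = cfg$scenario$y,
                        ranges = cfg$scenario$ranges)
  random_community(spec)
}

cli_options <- function(cfg) {
  drift_options(mode = cfg$drift$mode, positivity = cfg$drift$positivity,
                tau_infinite_threshold = cfg$drift$tau_infinite_threshold,
                zero_tol = cfg$drift$zero_tol)
}

#' Command-line interface entry point
#'
#' Thin dispatcher used by the installed `exec/cpr` script. Subcommands:
#' `simulate` and `dilution` write a trajectory table, event log and
#' provenance record; `coexistence` writes the simplex summary (rescaled
#' supply, initial and stationary allocations, hull verdicts, survivor
#' mask) and an optional ternary plot; `competition` estimates selection
#' coefficients from a frequency table; `induction` computes normalized
#' production rates from a fluorescence table; `synth` writes synthetic
#' fixture datasets.
#'
#' @param args Character vector of command-line arguments (first element:
#'   the subcommand).
#' @return Integer exit status: 0 on success, 1 on usage/config error, 2 on
#'   numerical failure. Called for its file side effects.
#' @export
cpr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: cpr <simulate|dilution|coexistence|competition|induction|synth> [options]"
  if (length(args) < 1) { message(usage); return(1L) }
  sub <- args[1]
  if (!sub %in% c("simulate", "dilution", "coexistence", "competition",
                  "induction", "synth")) {
    message(usage); return(1L)
  }
  opts <- tryCatch(parse_cli_options(sub, args[-1]),
                   error = function(e) { message("error: ", conditionMessage(e)); NULL })
  if (is.null(opts)) return(1L)
  status <- tryCatch({
    do.call(paste0("cli_", sub), list(opts))
    0L
  },
  config_error = function(e) { message("error: ", conditionMessage(e)); 1L },
  error = function(e) { message("error: ", conditionMessage(e)); 2L })
  status
}

parse_cli_options <- function(sub, rest) {
  olist <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--data", type = "character", default = NULL),
    optparse::make_option("--g1", type = "double", default = NULL),
    optparse::make_option("--inorm", type = "double", default = 1),
    optparse::make_option("--plot", action = "store_true", default = FALSE))
  parser <- optparse::OptionParser(option_list = olist)
  optparse::parse_args(parser, args = rest)
}

cli_load <- function(opts) {
  if (is.null(opts$config))
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = "--config is required", call = NULL)))
  cfg <- tryCatch(load_config(opts$config), error = function(e)
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = conditionMessage(e), call = NULL))))
  if (!is.null(opts$seed)) cfg$seed <- opts$seed
  if (!is.null(opts$out)) cfg$output$dir <- opts$out
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  cfg
}

cli_simulate <- function(opts) {
  cfg <- cli_load(opts)
  com <- cli_build(cfg)
  traj <- simulate_cpr(com$params, com$init, cfg$solver$t_end,
                       options = cli_options(cfg), n_out = cfg$solver$n_out,
                       rtol = cfg$solver$rtol, atol = cfg$solver$atol,
                       project_every = cfg$solver$project_every,
                       method = cfg$solver$method)
  out <- cfg$output$dir
  write_trajectory(traj, file.path(out, "trajectory.tsv"))
  writeLines(vapply(traj$events, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), character(1)),
    file.path(out, "events.jsonl"))
  write_provenance(cfg, cfg$seed, file.path(out, "provenance.json"))
  invisible(traj)
}

cli_dilution <- function(opts) {
  cfg <- cli_load(opts)
  if (is.null(cfg$protocol))
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = "`protocol` section is required for dilution runs",
                        call = NULL)))
  com <- cli_build(cfg)
  pr <- cfg$protocol
  protocol <- dilution_protocol(pr$D, pr$cycle_hours, pr$n_cycles,
                                rep_len(pr$fresh_c, com$params$n_resources),
                                carryover = isTRUE(pr$carryover),
                                T_growth = pr$T_growth)
  traj <- simulate_serial_dilution(com$params, com$init, protocol,
                                   options = cli_options(cfg))
  out <- cfg$output$dir
  write_trajectory(traj, file.path(out, "trajectory.tsv"))
  writeLines(vapply(traj$events, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), character(1)),
    file.path(out, "events.jsonl"))
  write_provenance(cfg, cfg$seed, file.path(out, "provenance.json"))
  invisible(traj)
}

cli_coexistence <- function(opts) {
  cfg <- cli_load(opts)
  com <- cli_build(cfg)
  traj <- simulate_cpr(com$params, com$init, cfg$solver$t_end,
                       options = cli_options(cfg), n_out = cfg$solver$n_out,
                       rtol = cfg$solver$rtol, atol = cfg$solver$atol,
                       project_every = cfg$solver$project_every)
  st <- state_at(traj)
  survivors <- classify_survivors(st, com$init)
  coords0 <- rescale_to_simplex(com$params, com$init$phi)
  coords1 <- rescale_to_simplex(com$params, st$phi)
  hull0 <- hull_condition(coords0$s_hat, coords0$phi_hat, tol = 1e-6)
  hull1 <- hull_condition(coords1$s_hat,
                          coords1$phi_hat[survivors, , drop = FALSE],
                          tol = 1e-6)
  summary <- list(
    s_hat = coords0$s_hat,
    phi_hat_initial = coords0$phi_hat,
    phi_hat_stationary = coords1$phi_hat,
    hull_initial_inside = hull0$inside,
    hull_stationary_inside = hull1$inside,
    survivors = survivors,
    stationary = detect_stationarity(traj)$stationary)
  out <- cfg$output$dir
  jsonlite::write_json(summary, file.path(out, "coexistence.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(opts$plot) && com$params$n_resources == 3)
    plot_simplex(coords0, coords1, file = file.path(out, "simplex.svg"))
  write_provenance(cfg, cfg$seed, file.path(out, "provenance.json"))
  invisible(summary)
}

cli_competition <- function(opts) {
  if (is.null(opts$data))
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = "--data is required", call = NULL)))
  d <- utils::read.table(opts$data, header = TRUE, sep = "\t",
                         comment.char = "#")
  series <- structure(data.frame(replicate = d$replicate, time = d$time,
                                 f = d$f, ln_odds = log(d$f / (1 - d$f))),
                      class = c("competition_series", "data.frame"))
  est <- estimate_selection(series)
  res <- data.frame(S = est$S, se = est$se)
  if (!is.null(opts$g1)) res$phi_ratio <- phi_ratio(est$S, opts$g1)
  outdir <- if (is.null(opts$out)) "." else opts$out
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res, file.path(outdir, "selection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(res)
}

cli_induction <- function(opts) {
  if (is.null(opts$data))
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = "--data is required", call = NULL)))
  d <- utils::read.table(opts$data, header = TRUE, sep = "\t",
                         comment.char = "#")
  rates <- mapply(function(I1, I2, dt, g)
    infer_production_rate(I1, I2, dt, g, I_norm = opts$inorm)$k,
    d$I_first, d$I_second, d$delta_t, d$g)
  res <- data.frame(inducer_conc = d$inducer_conc, k_normalized = rates)
  outdir <- if (is.null(opts$out)) "." else opts$out
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res, file.path(outdir, "production_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}

cli_synth <- function(opts) {
  cfg <- cli_load(opts)
  eg <- capacity_ratios(1.2, 3.0, 0.76)
  s1 <- strain_physiology(0.45, 0.01, eta = eg$eta, gamma = eg$gamma)
  s2 <- strain_physiology(0.44, 0, eta = eg$eta, gamma = eg$gamma)
  comp <- synthetic_competition_data(s1, s2, T_growth = 15.4, n_cycles = 5,
                                     noise_sd = 0.05, n_replicates = 6,
                                     seed = cfg$seed)
  out <- cfg$output$dir
  utils::write.table(comp, file.path(out, "competition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  models <- lapply(c(0.5, 1, 2, 4), function(k)
    induction_model(k = k, g = 0.3, I0 = 10))
  fl <- synthetic_fluorescence_data(models, inducer_conc = c(0, 15, 30, 45),
                                    noise_cv = 0.05, seed = cfg$seed)
  utils::write.table(fl, file.path(out, "fluorescence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_provenance(cfg, cfg$seed, file.path(out, "provenance.json"))
  invisible(NULL)
}
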