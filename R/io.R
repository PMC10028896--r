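## Serialisation: fixtures as a documented JSON schema, run records as a
## JSON manifest plus flat binary arrays, run configuration as YAML.

FIXTURE_SCHEMA_VERSION <- 1L
RECORD_SCHEMA_VERSION <- 1L

system_to_list <- function(sys) {
  out <- list(
    n_particles = sys$n_particles,
    positions = sys$positions,
    charges = sys$charges, lj_sigma = sys$lj_sigma,
    lj_epsilon = sys$lj_epsilon, masses = sys$masses, tags = sys$tags
  )
  for (nm in c("bonds", "angles", "torsions", "restraints", "doublewells")) {
    if (!is.null(sys[[nm]])) out[[nm]] <- sys[[nm]]
  }
  out
}

list_to_system <- function(l) {
  particle_system(
    positions = matrix(unlist(l$positions), ncol = 3,
                       byrow = is.list(l$positions)),
    charges = l$charges, lj_sigma = l$lj_sigma, lj_epsilon = l$lj_epsilon,
    masses = l$masses,
    bonds = l$bonds, angles = l$angles, torsions = l$torsions,
    restraints = l$restraints, doublewells = l$doublewells,
    tags = l$tags
  )
}

#' Write a mutation fixture to JSON
#'
#' Serialises a [mutation_pair()] (both systems, atom map, tags, analytic
#' reference, registered observables) to a self-describing JSON file at
#' full floating-point precision, so fixtures round-trip exactly.
#'
#' @param pair A [mutation_pair()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(pair, path) {
  stopifnot(inherits(pair, "mutation_pair"))
  doc <- list(
    schema = "alchrex-fixture", version = FIXTURE_SCHEMA_VERSION,
    kind = pair$kind, temperature = pair$temperature,
    old_system = system_to_list(pair$old_system),
    new_system = system_to_list(pair$new_system),
    atom_map = pair$atom_map,
    net_charge_change = pair$net_charge_change,
    analytic_delta_g = if (pair$analytic_valid) pair$analytic_delta_g else NULL,
    observables = pair$observables
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor", null = "null", na = "null")
  invisible(path)
}

#' Read a mutation fixture from JSON
#'
#' @param path Path written by [write_fixture()].
#' @return A [mutation_pair()].
#' @export
read_fixture <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "alchrex-fixture")) {
    stop("not an alchrex fixture file")
  }
  if (doc$version > FIXTURE_SCHEMA_VERSION) {
    stop(sprintf("fixture schema version %s is newer than supported (%d)",
                 doc$version, FIXTURE_SCHEMA_VERSION))
  }
  obs <- doc$observables
  if (!is.null(obs)) obs <- as.data.frame(obs)
  mutation_pair(
    old_system = list_to_system(doc$old_system),
    new_system = list_to_system(doc$new_system),
    atom_map = matrix(as.integer(doc$atom_map), ncol = 2),
    analytic_delta_g = doc$analytic_delta_g %||% NA_real_,
    kind = doc$kind, temperature = doc$temperature,
    observables = obs
  )
}

## ---- run records: JSON manifest + flat binary arrays ----

#' Write a run record to disk
#'
#' Persists a `run_record` as a directory containing `manifest.json`
#' (metadata, dimensions, array index) and one flat little-endian binary
#' file per array, giving lossless (bitwise) round trips.
#'
#' @param record A `run_record`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_record <- function(record, dir) {
  stopifnot(inherits(record, "run_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arrays <- list(
    u = list(data = as.numeric(record$u), dim = dim(record$u), type = "double"),
    state_history = list(data = as.integer(record$state_history),
                         dim = dim(record$state_history), type = "integer"),
    dudl = list(data = as.numeric(record$dudl), dim = dim(record$dudl),
                type = "double")
  )
  for (nm in names(record$observables)) {
    arrays[[paste0("obs_", nm)]] <- list(
      data = as.numeric(record$observables[[nm]]),
      dim = dim(record$observables[[nm]]), type = "double")
  }
  if (!is.null(record$configurations)) {
    arrays$configurations <- list(data = as.numeric(record$configurations),
                                  dim = dim(record$configurations),
                                  type = "double")
  }
  index <- list()
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    f <- paste0(nm, ".bin")
    con <- file(file.path(dir, f), "wb")
    writeBin(a$data, con, size = if (a$type == "double") 8L else 4L,
             endian = "little")
    close(con)
    index[[nm]] <- list(file = f, dim = a$dim, type = a$type)
  }
  rest <- record$rest
  manifest <- list(
    schema = "alchrex-run-record", version = RECORD_SCHEMA_VERSION,
    method = record$method, K = record$K, lambdas = record$lambdas,
    temperature = record$temperature,
    rest = if (is.null(rest)) NULL else
      list(T0 = rest$T0, Tmax = rest$Tmax,
           inter_exponent = rest$inter_exponent),
    params = record$params[c("w_lifting", "screening_alpha",
                             "coulomb_constant")],
    seed = record$seed, n_iterations = record$n_iterations,
    steps_per_iteration = record$steps_per_iteration,
    dt = record$dt, friction = record$friction,
    sampling_interval_ns = record$sampling_interval_ns,
    swap_acceptance = record$swap_acceptance,
    observable_names = names(record$observables),
    observable_spec = record$hybrid$observables,
    arrays = index
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Read a run record from disk
#'
#' @param dir Directory written by [write_run_record()]. The hybrid system
#'   is not persisted; supply it if diagnostics that need it will be run.
#' @param hybrid Optional `hybrid_system` to re-attach.
#' @return A `run_record`.
#' @export
read_run_record <- function(dir, hybrid = NULL) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("manifest.json not found in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(mf$schema, "alchrex-run-record")) {
    stop("not an alchrex run-record directory")
  }
  if (mf$version > RECORD_SCHEMA_VERSION) {
    stop(sprintf(
      "run-record schema version %s is newer than supported (%d); migrate first",
      mf$version, RECORD_SCHEMA_VERSION))
  }
  read_arr <- function(nm) {
    info <- mf$arrays[[nm]]
    if (is.null(info)) stop(sprintf("array '%s' missing from manifest", nm))
    f <- file.path(dir, info$file)
    if (!file.exists(f)) stop(sprintf("array file missing: %s", info$file))
    n_expect <- prod(info$dim)
    sz <- if (info$type == "double") 8L else 4L
    what <- if (info$type == "double") numeric() else integer()
    con <- file(f, "rb")
    on.exit(close(con))
    v <- readBin(con, what, n = n_expect + 1, size = sz, endian = "little")
    if (length(v) != n_expect) {
      stop(sprintf("array '%s' truncated or padded: expected %d values, got %d",
                   nm, n_expect, length(v)))
    }
    array(v, dim = info$dim)
  }
  obs <- list()
  for (nm in mf$observable_names %||% character(0)) {
    obs[[nm]] <- read_arr(paste0("obs_", nm))
  }
  configs <- if ("configurations" %in% names(mf$arrays)) {
    read_arr("configurations")
  } else NULL
  rest <- if (is.null(mf$rest)) NULL else {
    rest_params(mf$rest$T0, mf$rest$Tmax, mf$rest$inter_exponent)
  }
  if (!is.null(hybrid) && is.null(hybrid$observables) &&
      !is.null(mf$observable_spec)) {
    hybrid$observables <- as.data.frame(mf$observable_spec)
  }
  structure(list(
    u = read_arr("u"),
    state_history = matrix(read_arr("state_history"),
                           nrow = mf$n_iterations),
    dudl = read_arr("dudl"),
    observables = obs, configurations = configs,
    lambdas = mf$lambdas, K = mf$K, temperature = mf$temperature,
    rest = rest,
    params = alchemical_params(mf$params$w_lifting, mf$params$screening_alpha,
                               mf$params$coulomb_constant),
    seed = mf$seed, n_iterations = mf$n_iterations,
    steps_per_iteration = mf$steps_per_iteration, dt = mf$dt,
    friction = mf$friction, sampling_interval_ns = mf$sampling_interval_ns,
    swap_acceptance = mf$swap_acceptance,
    hybrid = hybrid, method = mf$method
  ), class = "run_record")
}

## ---- YAML run configuration ----

config_defaults <- function() {
  list(
    fixture = list(kind = "harmonic_ladder", n_particles = 1, k_old = 100,
                   k_new = 100 * exp(2), seed = 1, barrier = 3,
                   well_offset_coupling = 1, cluster_size = 2,
                   delta_sigma = 0, delta_epsilon = 0, delta_charge = 0,
                   path = NULL),
    method = "arex",
    protocol = list(K = NULL),
    params = list(w_lifting = 0.4, screening_alpha = 0),
    rest = list(T0 = 300, Tmax = 600, radius = 0.5, inter_exponent = 0.5),
    sampler = list(dt = NULL, friction = 5, temperature = 300,
                   n_iterations = 500, steps_per_iteration = 40),
    estimation = list(burn_in = 0.1, n_bootstrap = 200),
    diagnostics = list(threshold = 0.1, window = NULL, n_points = 10,
                       series_bootstrap = 50),
    seed = 1,
    output_dir = "alchrex_out"
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys take the documented defaults
#' (T0 = 300 K, Tmax = 600 K, REST radius 0.5 nm, 200 bootstrap resamples,
#' convergence threshold 0.1 kcal/mol/ns).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list overriding file values.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path) %||% list()
  user <- modifyList(user, overrides)
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(bad, collapse = ", ")))
    }
  }
  check_keys(user, names(cfg), "top level")
  for (sec in names(user)) {
    if (is.list(cfg[[sec]]) && is.list(user[[sec]])) {
      check_keys(user[[sec]], names(cfg[[sec]]), sec)
      cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  if (!cfg$method %in% c("arex", "arest")) {
    stop("method must be 'arex' or 'arest'")
  }
  structure(cfg, class = "run_config")
}

fixture_from_config <- function(fx) {
  if (!is.null(fx$path)) return(read_fixture(fx$path))
  switch(fx$kind,
    harmonic_ladder = make_harmonic_ladder(
      fx$n_particles, fx$k_old, fx$k_new, seed = fx$seed),
    lj_cluster = make_lj_mutation(
      fx$cluster_size, fx$delta_sigma, fx$delta_epsilon, fx$delta_charge,
      seed = fx$seed),
    double_well = make_double_well_mutation(
      fx$barrier, fx$well_offset_coupling, seed = fx$seed),
    stop(sprintf("unknown fixture kind '%s'", fx$kind)))
}

#' Run the full pipeline from a configuration
#'
#' fixture -> hybrid -> AREX/AREST -> decorrelate -> MBAR + bootstrap ->
#' diagnostics -> report. Artifacts (fixture JSON, run record, results JSON
#' and CSV) are written under `config$output_dir`.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param write_artifacts Write outputs to disk (default `TRUE`).
#' @return List with `pair`, `hybrid`, `record`, `fe`, `series`,
#'   `convergence`, `mixing` and the output `dir`, invisibly printable.
#' @export
run_pipeline <- function(config = read_run_config(), write_artifacts = TRUE) {
  stopifnot(inherits(config, "run_config"))
  pair <- fixture_from_config(config$fixture)
  hybrid <- build_hybrid(pair)
  params <- alchemical_params(w_lifting = config$params$w_lifting,
                              screening_alpha = config$params$screening_alpha)
  protocol <- lambda_protocol(K = config$protocol$K,
                              charge_changing = pair$net_charge_change != 0)
  rest <- NULL
  if (config$method == "arest") {
    hybrid <- assign_rest_region(hybrid, radius = config$rest$radius)
    rest <- rest_params(config$rest$T0, config$rest$Tmax,
                        config$rest$inter_exponent)
  }
  sm <- config$sampler
  record <- run_arex(hybrid, protocol, params,
                     n_iterations = sm$n_iterations,
                     steps_per_iteration = sm$steps_per_iteration,
                     temperature = sm$temperature, seed = config$seed,
                     dt = sm$dt, friction = sm$friction, rest = rest)
  m <- decorrelate(record, burn_in = config$estimation$burn_in)
  fe <- bootstrap_delta_g(m, n_bootstrap = config$estimation$n_bootstrap,
                          seed = config$seed)
  series <- dg_time_series(record, n_points = config$diagnostics$n_points,
                           burn_in = config$estimation$burn_in,
                           n_bootstrap = config$diagnostics$series_bootstrap,
                           seed = config$seed)
  conv <- convergence_slope_test(series,
                                 window = config$diagnostics$window,
                                 threshold = config$diagnostics$threshold)
  mixing <- replica_mixing_report(record)
  out <- list(pair = pair, hybrid = hybrid, record = record, fe = fe,
              series = series, convergence = conv, mixing = mixing,
              dir = config$output_dir)
  if (write_artifacts) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_fixture(pair, file.path(config$output_dir, "fixture.json"))
    write_run_record(record, file.path(config$output_dir, "record"))
    report_run(out, config$output_dir)
  }
  invisible(out)
}

#' Write the human-readable run report
#'
#' One JSON and one CSV summary per run: free energy with 2 SD error bars
#' and 95% CI, convergence verdict, and replica-mixing summary.
#'
#' @param result Output of [run_pipeline()] (or a compatible list).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
report_run <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fe <- result$fe; conv <- result$convergence; mix <- result$mixing
  row <- tibble::tibble(
    kind = result$pair$kind,
    delta_g = fe$delta_g, sigma = fe$sigma,
    error_bar_2sd = 2 * fe$sigma,
    ci_lo = fe$ci95[1], ci_hi = fe$ci95[2],
    analytic_delta_g = if (result$pair$analytic_valid)
      result$pair$analytic_delta_g else NA_real_,
    converged = conv$converged, slope = conv$slope,
    slope_2sd = conv$slope_2sd,
    bottleneck = mix$bottleneck,
    mean_round_trips = mix$mean_round_trips,
    swap_acceptance = result$record$swap_acceptance
  )
  write.csv(row, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(row), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
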