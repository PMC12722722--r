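#' Tabular input/output
#'
#' All trajectory-derived inputs are tab-separated tables with
#' unit-suffixed column names; every reader validates the required
#' columns and names any that are missing. Writers and readers round-trip
#' exactly (numbers are written at full precision).
#'
#' @name poregate-io
NULL

required_cols <- list(
  umbrella = c("window_center_A", "spring_k_kJ_mol_nm2", "monomer",
               "replicate", "time_ns", "z_A"),
  trace = c("time_ns", "monomer", "replicate", "z_A"),
  lambda = c("residue", "pH", "monomer", "replicate", "time_ns",
             "protonated"),
  work = c("residue", "state_pair", "direction", "work_kJ_mol", "monomer",
           "replicate"),
  distance = c("pair", "pH", "monomer", "replicate", "time_ns", "dist_A"),
  positions = c("time_ns", "x_A", "y_A", "z_A"),
  profile = c("z_A", "G_kJ_mol")
)

read_tsv_checked <- function(path, kind) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- required_cols[[kind]]
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("%s table %s lacks required column(s): %s", kind, path,
                 paste(missing, collapse = ", ")))
  }
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read umbrella-window samples from TSV
#'
#' Expects columns `window_center_A`, `spring_k_kJ_mol_nm2`, `monomer`,
#' `replicate`, `time_ns`, `z_A`; one row per sample.
#'
#' @param path TSV file path.
#' @return list of [umbrella_window()] objects (one per unique
#'   center/monomer/replicate combination).
#' @export
read_umbrella_tsv <- function(path) {
  df <- read_tsv_checked(path, "umbrella")
  key <- paste(df$window_center_A, df$spring_k_kJ_mol_nm2, df$monomer,
               df$replicate)
  unname(lapply(split(df, key), function(g) {
    umbrella_window(center = g$window_center_A[1],
                    spring_k = g$spring_k_kJ_mol_nm2[1],
                    samples = g$z_A, monomer = g$monomer[1],
                    replicate = g$replicate[1])
  }))
}

#' Write umbrella windows to TSV
#' @param windows list of [umbrella_window()] objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_umbrella_tsv <- function(windows, path) {
  rows <- lapply(windows, function(w) {
    data.frame(window_center_A = w$center,
               spring_k_kJ_mol_nm2 = w$spring_k, monomer = w$monomer,
               replicate = w$replicate,
               time_ns = seq_along(w$samples), z_A = w$samples)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read solute traces from TSV
#'
#' Expects `time_ns`, `monomer`, `replicate`, `z_A` (and optionally
#' `particle_id`); returns one `trace` per (monomer, replicate,
#' particle_id).
#'
#' @param path TSV file path.
#' @return list of `trace` objects.
#' @export
read_trace_tsv <- function(path) {
  df <- read_tsv_checked(path, "trace")
  pid <- if (!is.null(df$particle_id)) df$particle_id else 1
  key <- paste(df$monomer, df$replicate, pid)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_ns), ]
    new_trace(time = g$time_ns, z = g$z_A, monomer = g$monomer[1],
              replicate = g$replicate[1])
  })
}

#' Write traces to TSV
#' @param traces list of `trace` objects (or a single one).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trace_tsv <- function(traces, path) {
  if (inherits(traces, "trace")) traces <- list(traces)
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(time_ns = tr$time, monomer = tr$monomer,
               replicate = tr$replicate, particle_id = i, z_A = tr$z)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read protonation (lambda-state) traces from TSV
#'
#' Expects `residue`, `pH`, `monomer`, `replicate`, `time_ns`,
#' `protonated` (0/1).
#'
#' @param path TSV file path.
#' @return a `lambda_trace_set`.
#' @export
read_lambda_tsv <- function(path) {
  df <- read_tsv_checked(path, "lambda")
  if (!all(df$protonated %in% c(0, 1))) {
    stop("protonated column must be binary 0/1")
  }
  key <- paste(df$residue, df$pH, df$monomer, df$replicate)
  entries <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_ns), ]
    list(residue = g$residue[1], pH = g$pH[1], monomer = g$monomer[1],
         replicate = g$replicate[1], time = g$time_ns,
         state = as.integer(g$protonated))
  })
  structure(unname(entries), class = "lambda_trace_set",
            warnings = character())
}

#' Write a lambda trace set to TSV
#' @param traces a `lambda_trace_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_lambda_tsv <- function(traces, path) {
  rows <- lapply(traces, function(e) {
    data.frame(residue = e$residue, pH = e$pH, monomer = e$monomer,
               replicate = e$replicate, time_ns = e$time,
               protonated = e$state)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read forward/backward work values from TSV
#'
#' Expects `residue`, `state_pair`, `direction` (F/R), `work_kJ_mol`,
#' `monomer`, `replicate`; returns one [work_set()] per (residue,
#' state_pair).
#'
#' @param path TSV file path.
#' @param kT thermal energy attached to each set (kJ/mol).
#' @return named list of `work_set` objects.
#' @export
read_work_tsv <- function(path, kT = kT_at(300)) {
  df <- read_tsv_checked(path, "work")
  if (!all(df$direction %in% c("F", "R"))) {
    stop("direction column must contain only F or R")
  }
  key <- paste(df$residue, df$state_pair)
  sets <- lapply(split(df, key), function(g) {
    work_set(forward = g$work_kJ_mol[g$direction == "F"],
             reverse = g$work_kJ_mol[g$direction == "R"], kT = kT,
             residue = g$residue[1])
  })
  sets
}

#' Write a work set to TSV
#' @param works a [work_set()].
#' @param path output path.
#' @param state_pair label for the state pair column.
#' @return the path, invisibly.
#' @export
write_work_tsv <- function(works, path, state_pair = "open-closed") {
  df <- rbind(
    data.frame(residue = works$residue, state_pair = state_pair,
               direction = "F", work_kJ_mol = works$forward,
               monomer = works$monomer, replicate = works$replicate),
    data.frame(residue = works$residue, state_pair = state_pair,
               direction = "R", work_kJ_mol = works$reverse,
               monomer = works$monomer, replicate = works$replicate)
  )
  write_tsv(df, path)
}

#' Read a distance (contact) trajectory from TSV
#'
#' Expects `pair`, `pH`, `monomer`, `replicate`, `time_ns`, `dist_A`;
#' optional `angle_deg`, `cond_state`, `dist_second`.
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_distance_tsv <- function(path) {
  read_tsv_checked(path, "distance")
}

#' Read solute positions from TSV
#'
#' Expects `time_ns`, `x_A`, `y_A`, `z_A`.
#'
#' @param path TSV file path.
#' @return data frame.
#' @export
read_positions_tsv <- function(path) {
  read_tsv_checked(path, "positions")
}

#' Write a free-energy profile to TSV
#' @param profile a `pmf_profile`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(z_A = profile$z, G_kJ_mol = profile$G,
                   sem_kJ_mol = if (is.null(profile$sem)) NA else profile$sem)
  write_tsv(df, path)
}

#' Read a free-energy profile from TSV
#' @param path TSV with columns `z_A`, `G_kJ_mol` (optional
#'   `sem_kJ_mol`).
#' @param kT thermal energy (kJ/mol).
#' @param reference referencing convention to (re-)apply.
#' @return a `pmf_profile`.
#' @export
read_profile_tsv <- function(path, kT = kT_at(300),
                             reference = "bulk_zero") {
  df <- read_tsv_checked(path, "profile")
  sem <- if (!is.null(df$sem_kJ_mol) && !all(is.na(df$sem_kJ_mol))) {
    df$sem_kJ_mol
  } else {
    NULL
  }
  pmf_profile(z = df$z_A, G = df$G_kJ_mol, sem = sem, kT = kT,
              reference = reference)
}

#' Analysis run configuration
#'
#' Collects the protocol constants shared across modules: temperature
#' (kT is derived, never set independently), equilibration cuts (fraction
#' of each umbrella window; ns of each constant-pH trace), and bootstrap
#' controls. Every JSON summary embeds the resolved configuration and a
#' hash of it for provenance.
#'
#' @param temperature_K simulation temperature (default 300).
#' @param umbrella_equilibration fraction of each umbrella window
#'   discarded (default 0.1).
#' @param cphmd_equilibration_ns constant-pH equilibration cut (default
#'   100 ns).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed default RNG seed.
#' @return a `run_config` list with `kT` filled in.
#' @export
run_config <- function(temperature_K = 300, umbrella_equilibration = 0.1,
                       cphmd_equilibration_ns = 100, n_boot = 1000L,
                       seed = 1L) {
  stopifnot(temperature_K > 0, umbrella_equilibration >= 0,
            umbrella_equilibration < 1, cphmd_equilibration_ns >= 0)
  structure(list(temperature_K = temperature_K,
                 kT = kT_at(temperature_K),
                 umbrella_equilibration = umbrella_equilibration,
                 cphmd_equilibration_ns = cphmd_equilibration_ns,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x) {
    paste(format(x, digits = 15), collapse = ",")
  }, character(1)), sep = "=", collapse = ";")
  # small stable polynomial hash; provenance only, not cryptographic
  h <- 17
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Write a JSON analysis summary with provenance
#'
#' @param results named list of results (numbers, vectors, tables).
#' @param path output path.
#' @param config a [run_config()] echoed into the summary along with its
#'   hash.
#' @return the path, invisibly.
#' @export
write_json_summary <- function(results, path, config = run_config()) {
  payload <- list(results = results,
                  config = unclass(config),
                  config_hash = config_hash(config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
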