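#' Experiment configuration
#'
#' A nested list mirroring the package's modules: `graph` (constructor kind
#' and its arguments), `band` (AR(2) peak, sampling rate, root magnitude),
#' `mixing` (`K`, `decay`, and either `noise_sd` or `snr`), `spectral`
#' (kernel, `half_width`, `band_hz`, `transform`), `persistence` (`max_dim`,
#' `rel_threshold`), `experiment` (`n_time`, `N`, `B`, `snr_grid`,
#' `n_replicates`) and `seed`.  [resolve_config()] fills every omitted field
#' with its default and rejects unknown keys, so the resolved config written
#' next to each command's outputs is a complete, re-runnable record.
#'
#' @return `default_config()` returns the full default configuration list.
#' @export
default_config <- function() {
  list(
    graph = list(kind = "circular_ladder", n_rungs = 15,
                 n_rungs_per_lobe = 8, n_bridges = 1,
                 rows = 9, cols = 17, n_points = 200,
                 mode = "regular", wrap_rows = TRUE, wrap_cols = TRUE,
                 reverse_rows = FALSE, reverse_cols = FALSE),
    band = list(preset = "alpha", peak_freq_hz = NULL,
                sampling_rate_hz = 100, root_magnitude = 1.05),
    mixing = list(K = 2, decay = "inv_linear", noise_sd = 1, snr = NULL),
    spectral = list(kernel = "daniell", half_width = NULL,
                    band_hz = c(8, 12), transform = "one_minus"),
    persistence = list(max_dim = 2, rel_threshold = 0.5),
    experiment = list(n_time = 2000, N = 20, B = 200,
                      snr_grid = c(0.25, 0.5, 1, 2, 4, 8, 16),
                      n_replicates = 50),
    seed = 1
  )
}

#' @rdname default_config
#' @param config partial configuration (nested list, e.g. parsed from YAML).
#' @export
resolve_config <- function(config = list()) {
  defaults <- default_config()
  if (!is.list(config)) stop_invalid("config must be a list")
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop_invalid("unknown config key(s): %s", paste(bad, collapse = ", "))
  for (section in names(config)) {
    if (is.list(defaults[[section]])) {
      bad <- setdiff(names(config[[section]]), names(defaults[[section]]))
      if (length(bad))
        stop_invalid("unknown key(s) in `%s`: %s", section,
                     paste(bad, collapse = ", "))
    }
  }
  utils::modifyList(defaults, config)
}

#' Canonical experiment presets
#'
#' The four canonical configurations: `one_cycle` (circular ladder, P = 30),
#' `two_cycle` (double circular ladder, P = 32), `torus` (9 x 17 periodic
#' grid, P = 153, K = 3) and `sphere` (dodecahedron, P = 20).
#'
#' @param name preset name.
#' @return a resolved configuration list.
#' @export
config_preset <- function(name = c("one_cycle", "two_cycle", "torus",
                                   "sphere")) {
  name <- match.arg(name)
  overrides <- switch(name,
    one_cycle = list(graph = list(kind = "circular_ladder", n_rungs = 15)),
    two_cycle = list(graph = list(kind = "double_circular_ladder",
                                  n_rungs_per_lobe = 8)),
    torus = list(graph = list(kind = "torus_grid", rows = 9, cols = 17),
                 mixing = list(K = 3)),
    sphere = list(graph = list(kind = "dodecahedron")))
  resolve_config(overrides)
}

#' Read / write configuration files
#'
#' Configurations are stored as YAML.  The reader resolves the parsed file
#' against the defaults (so partial configs are valid input).
#'
#' @param path file path.
#' @param config a configuration list.
#' @return the reader returns a resolved config; the writer returns `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file '%s' not found", path)
  resolve_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_graph <- function(cfg) {
  gs <- cfg$graph
  switch(gs$kind,
         circular_ladder = circular_ladder(gs$n_rungs),
         double_circular_ladder =
           double_circular_ladder(gs$n_rungs_per_lobe, gs$n_bridges),
         torus_grid = torus_grid(gs$rows, gs$cols),
         dodecahedron = dodecahedron(),
         quotient = sample_quotient_graph(
           polygon_quotient_spec(gs$rows, gs$cols, gs$wrap_rows,
                                 gs$wrap_cols, gs$reverse_rows,
                                 gs$reverse_cols),
           n_points = gs$n_points, seed = cfg$seed, mode = gs$mode),
         stop_invalid("unknown graph kind '%s'", gs$kind))
}

config_band <- function(cfg) {
  bs <- cfg$band
  if (!is.null(bs$peak_freq_hz))
    ar2_from_peak(bs$peak_freq_hz, bs$sampling_rate_hz, bs$root_magnitude)
  else band_preset(bs$preset, SR = bs$sampling_rate_hz,
                   M = bs$root_magnitude)
}

config_noise_sd <- function(cfg, W) {
  if (!is.null(cfg$mixing$snr)) noise_sd_for_snr(W, cfg$mixing$snr)
  else cfg$mixing$noise_sd
}

# command implementations (thin orchestration used by the CLI) -----------

#' Run the `simulate` command
#'
#' Builds the configured graph and band, simulates the series, and writes
#' `series.tsv`, `graph_edges.txt`, `weights.tsv`, a `derived.yaml` log of
#' derived quantities (phi1, phi2, noise sd) and the resolved
#' `config_resolved.yaml` into `out_dir`.
#'
#' @param config a (partial) configuration list or a YAML path.
#' @param out_dir output directory (created if needed).
#' @return the resolved config, invisibly.
#' @export
cmd_simulate <- function(config = list(), out_dir = ".") {
  cfg <- if (is.character(config)) read_config(config)
         else resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- config_graph(cfg)
  band <- config_band(cfg)
  W <- mixing_weights(shortest_path_distances(g), K = cfg$mixing$K,
                      decay = cfg$mixing$decay)
  noise_sd <- config_noise_sd(cfg, W)
  y <- simulate_network_series(g, band, K = cfg$mixing$K,
                               decay = cfg$mixing$decay,
                               n_time = cfg$experiment$n_time,
                               noise_sd = noise_sd, seed = cfg$seed)
  write_series(y, file.path(out_dir, "series.tsv"))
  write_edge_list(g, file.path(out_dir, "graph_edges.txt"))
  utils::write.table(W, file.path(out_dir, "weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(P = g$n_nodes, phi1 = band$phi1, phi2 = band$phi2,
                        noise_sd = noise_sd),
                   file.path(out_dir, "derived.yaml"))
  write_config(cfg, file.path(out_dir, "config_resolved.yaml"))
  invisible(cfg)
}

#' Run the `persist` command
#'
#' Accepts either a series file (runs the spectral stage first) or a
#' precomputed distance matrix, computes the Vietoris-Rips persistence
#' diagram, and writes `diagram.tsv`, a `summary.tsv` table of per-dimension
#' total persistence and prominent-feature counts, and the resolved config.
#'
#' @param input path to a `series.tsv` (from [cmd_simulate()] /
#'   [write_series()]) or a distance matrix (`.dist.tsv` or
#'   `distance` in the name, or pass `is_distance = TRUE`).
#' @param config a (partial) configuration list or a YAML path.
#' @param out_dir output directory.
#' @param is_distance treat `input` as a distance matrix.
#' @return the persistence diagram, invisibly.
#' @export
cmd_persist <- function(input, config = list(), out_dir = ".",
                        is_distance = grepl("dist", basename(input))) {
  cfg <- if (is.character(config)) read_config(config)
         else resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is_distance) {
    D <- read_distance_matrix(input)
    pd <- vr_persistence(D, max_dim = cfg$persistence$max_dim)
  } else {
    y <- read_series(input)
    pd <- coherence_persistence(y, band_hz = cfg$spectral$band_hz,
                                half_width = cfg$spectral$half_width,
                                transform = cfg$spectral$transform,
                                max_dim = cfg$persistence$max_dim)
  }
  write_persistence_diagram(pd, file.path(out_dir, "diagram.tsv"))
  dims <- 0:cfg$persistence$max_dim
  summary <- data.frame(
    dim = dims,
    total_persistence = vapply(dims, function(k)
      total_persistence(pd, k), 0),
    prominent = vapply(dims, function(k)
      prominent_features(pd, k, cfg$persistence$rel_threshold), 0L))
  utils::write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_config(cfg, file.path(out_dir, "config_resolved.yaml"))
  invisible(pd)
}

#' Run the `snr-study` command
#'
#' Orchestrates [snr_study()] from a configuration and writes the per-SNR
#' mean total persistence table `snr_means.tsv`, the per-replicate table
#' `snr_values.tsv` and the resolved config.
#'
#' @inheritParams cmd_simulate
#' @return the `snr_study_result`, invisibly.
#' @export
cmd_snr_study <- function(config = list(), out_dir = ".") {
  cfg <- if (is.character(config)) read_config(config)
         else resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- snr_study(config_graph(cfg), config_band(cfg), K = cfg$mixing$K,
                   snr_grid = cfg$experiment$snr_grid,
                   n_replicates = cfg$experiment$n_replicates,
                   n_time = cfg$experiment$n_time, seed = cfg$seed,
                   max_dim = cfg$persistence$max_dim,
                   band_hz = cfg$spectral$band_hz,
                   half_width = cfg$spectral$half_width,
                   transform = cfg$spectral$transform)
  means <- data.frame(snr = res$snr_grid, res$mean_total_persistence)
  utils::write.table(means, file.path(out_dir, "snr_means.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$values, file.path(out_dir, "snr_values.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(cfg, file.path(out_dir, "config_resolved.yaml"))
  invisible(res)
}

#' Run the `infer` command
#'
#' Orchestrates [two_group_experiment()] from a configuration and writes the
#' bootstrap table `bootstrap_means.tsv` (group, dim, replicate, mean), a
#' `report.txt` with the group means and difference intervals, and the
#' resolved config.
#'
#' @inheritParams cmd_simulate
#' @return the `two_group_result`, invisibly.
#' @export
cmd_infer <- function(config = list(), out_dir = ".") {
  cfg <- if (is.character(config)) read_config(config)
         else resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- two_group_experiment(N = cfg$experiment$N, B = cfg$experiment$B,
                              n_time = cfg$experiment$n_time,
                              band = config_band(cfg), K = cfg$mixing$K,
                              noise_sd = cfg$mixing$noise_sd,
                              max_dim = max(1, cfg$persistence$max_dim - 1),
                              seed = cfg$seed,
                              band_hz = cfg$spectral$band_hz,
                              half_width = cfg$spectral$half_width,
                              transform = cfg$spectral$transform)
  tab <- do.call(rbind, lapply(res$per_dim, function(pd) {
    rbind(data.frame(group = "one_cycle", dim = pd$dim,
                     replicate = seq_len(res$B),
                     bootstrap_mean = pd$one_cycle$boot_means),
          data.frame(group = "two_cycle", dim = pd$dim,
                     replicate = seq_len(res$B),
                     bootstrap_mean = pd$two_cycle$boot_means))
  }))
  utils::write.table(tab, file.path(out_dir, "bootstrap_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- utils::capture.output(print(res))
  writeLines(report, file.path(out_dir, "report.txt"))
  write_config(cfg, file.path(out_dir, "config_resolved.yaml"))
  invisible(res)
}
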