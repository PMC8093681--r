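#' Read a pipeline configuration
#'
#' Configurations are plain lists; on disk they may be YAML (`.yaml`/`.yml`)
#' or JSON (`.json`). A list passed in is returned unchanged, so every
#' pipeline entry point accepts either a path or an in-memory config.
#'
#' YAML 1.1 parses a bare `n` key as the boolean `FALSE`; the reader maps
#' such a key back to `n` (quote it as `'n':` to avoid relying on this), and
#' `n_species` is accepted as an alias for `n` everywhere.
#'
#' @param config Path to a YAML/JSON file, or a list.
#' @return A named list.
#' @export
read_config <- function(config) {
  cfg <- if (is.list(config)) {
    config
  } else if (!file.exists(config)) {
    rlang::abort(paste0("Config file not found: ", config), class = "radlabel_usage_error")
  } else if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
  normalize_config_keys(cfg)
}

normalize_config_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    nm[nm %in% c("FALSE", "no")] <- "n"   # YAML 1.1 boolean-key casualties
    nm[nm == "n_species"] <- "n"
    names(x) <- nm
  }
  lapply(x, normalize_config_keys)
}

config_trade_off <- function(cfg) {
  tocfg <- cfg[["trade_off"]]
  if (is.null(tocfg)) {
    rlang::abort("Config is missing the `trade_off` block.", class = "radlabel_usage_error")
  }
  x_hat <- tocfg[["x_hat"]] %||% cfg[["x_hat"]] %||% 2.5
  if (!is.null(tocfg[["shape"]])) {
    reference_trade_off(tocfg[["shape"]], x_hat = x_hat)
  } else {
    trade_off(tocfg[["family"]], unlist(tocfg[["params"]]), x_hat = x_hat)
  }
}

#' Equilibrium pipeline: model config to equilibrium, RAD, and summaries
#'
#' Builds the community from a config (`trade_off` block with `family` +
#' `params` or a reference `shape`; `n`; `m`; `q`; optional `relative_shift`,
#' `perturbation` block with `mode`/`seed`, and RAD `threshold`), solves the
#' equilibrium by forward recursion, labels peaks, and computes the RAD,
#' Simpson's index, both SAD histograms, the deviation index against the
#' continuous solution, and the neighbour-survival fraction. When `out_dir`
#' is set, writes `equilibrium.csv`, `rad.csv`, and `summary.json` there.
#'
#' @param config Path or list (see [read_config()]).
#' @param out_dir Output directory (created if missing); `NULL` writes
#'   nothing.
#' @return A list: `spec`, `equilibrium` (tibble), `rad`, `sad`, `summary`
#'   (one-row tibble).
#' @export
run_equilibrium_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  for (field in c("n", "m", "q")) {
    if (is.null(cfg[[field]])) {
      rlang::abort(paste0("Config is missing `", field, "`."), class = "radlabel_usage_error")
    }
  }
  to <- config_trade_off(cfg)
  pert <- cfg[["perturbation"]] %||% list(mode = "none")
  pos <- make_positions(cfg[["n"]], to$x_hat,
                        relative_shift = cfg[["relative_shift"]] %||% 0,
                        perturbation = pert[["mode"]] %||% "none",
                        seed = pert[["seed"]])
  spec <- community_spec(pos, m = cfg[["m"]], q = cfg[["q"]], trade_off = to)
  if (spec$m == 0) {
    rlang::warn("m = 0: no empty sites are regenerated, so only the top competitor persists.")
  }
  eq <- solve_equilibrium(spec)
  message("extinction threshold m/q = ", signif(spec$m / spec$q, 6),
          "; survivors: ", sum(eq$survivors), " of ", spec$n)

  eq_tb <- tidy.equilibrium_community(eq)
  rad <- adjacency_groups(build_rad(eq, threshold = cfg[["threshold"]] %||% 1e-7))
  sad <- if (nrow(rad) >= 2 && max(rad$frequency) > min(rad$frequency)) sad_histograms(rad) else NULL
  dev_idx <- tryCatch(deviation_index(spec), error = function(e) NA_real_)
  nf <- neighbor_survival_fraction(eq)
  summary <- tibble::tibble(
    n = spec$n,
    m_over_q = spec$m / spec$q,
    n_survivors = sum(eq$survivors),
    n_with_surviving_neighbor = nf[["numerator"]],
    empty_fraction = eq$empty_fraction,
    simpson = simpson_index(rad),
    deviation_index = dev_idx
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(eq_tb, file.path(out_dir, "equilibrium.csv"), progress = FALSE)
    readr::write_csv(tibble::as_tibble(rad), file.path(out_dir, "rad.csv"), progress = FALSE)
    payload <- as.list(summary)
    if (!is.null(sad)) {
      payload$sad_linear_counts <- sad$linear$count
      payload$sad_log2_counts <- sad$log2$count
    }
    jsonlite::write_json(payload, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(spec = spec, equilibrium = eq_tb, rad = rad, sad = sad, summary = summary)
}

#' Rank-test pipeline: community table to randomization report
#'
#' Loads a community table (config field `input`, a CSV/TSV path) or
#' generates one (`synth` block passed to [generate_null_table()], or a
#' `model` block solved and converted by [generate_structured_table()]),
#' ranks it with genus-by-guild groups, runs the randomization test, and
#' writes a JSON report plus the RAD table when `out_dir` is set.
#'
#' Config fields: `input` or `synth`/`model`, `exclude` (species names
#' dropped before ranking), `n_trials` (default 100,000), `seed`,
#' `mode` (`all_pairs`/`adjacent_only`), `rank_scale`
#' (`absolute`/`relative`).
#'
#' @inheritParams run_equilibrium_pipeline
#' @return A list: `table`, `rad`, `result` (a `rank_test_result`), and the
#'   paths written (if any).
#' @export
run_rank_test_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  tb <- if (!is.null(cfg[["input"]])) {
    read_community_table(cfg[["input"]], dialect = cfg[["dialect"]] %||% "auto",
                         col_names = unlist(cfg[["col_names"]]))
  } else if (!is.null(cfg[["synth"]])) {
    do.call(generate_null_table, cfg[["synth"]])
  } else if (!is.null(cfg[["model"]])) {
    spec <- community_spec(
      make_positions(cfg[["model"]]$n, cfg[["model"]]$trade_off$x_hat %||% 2.5,
                     relative_shift = cfg[["model"]]$relative_shift %||% 0),
      m = cfg[["model"]]$m, q = cfg[["model"]]$q,
      trade_off = config_trade_off(cfg[["model"]])
    )
    generate_structured_table(spec, scale = cfg[["model"]]$scale %||% 1000)
  } else {
    rlang::abort("Config needs one of `input`, `synth`, or `model`.",
                 class = "radlabel_usage_error")
  }
  rad <- rank_with_ties(tb, exclude = cfg[["exclude"]])
  result <- randomization_test(
    rad,
    n_trials = cfg[["n_trials"]] %||% 1e5,
    seed = cfg[["seed"]] %||% 20210316,
    rank_scale = cfg[["rank_scale"]] %||% "absolute",
    mode = cfg[["mode"]] %||% "all_pairs"
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_report(result, rad, file.path(out_dir, "rank_test_report.json"))
  }
  list(table = tb, rad = rad, result = result, paths = paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
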