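#' Read an empirical community abundance table
#'
#' Reads a delimited text table (CSV or TSV, UTF-8, header row) of species
#' records: species name, genus, foraging-guild code, abundance, and an
#' optional precomputed rank column (preserved verbatim when present, as
#' published tables sometimes carry tied ranks). Zero-abundance rows are
#' retained but flagged.
#'
#' @param path File path.
#' @param dialect `"auto"` (by file extension), `"csv"`, or `"tsv"`.
#' @param col_names Named character vector mapping the canonical roles
#'   `species`, `genus`, `guild`, `abundance`, `rank` to the file's column
#'   names; defaults to those names themselves.
#' @return A `community_table`: a tibble with columns `species`, `genus`,
#'   `guild`, `abundance`, optionally `rank`, plus `zero_abundance`.
#' @export
read_community_table <- function(path, dialect = c("auto", "csv", "tsv"),
                                 col_names = NULL) {
  dialect <- rlang::arg_match(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)

  defaults <- c(species = "species", genus = "genus", guild = "guild",
                abundance = "abundance", rank = "rank")
  cn <- defaults
  if (!is.null(col_names)) cn[names(col_names)] <- col_names

  for (role in c("species", "genus", "guild", "abundance")) {
    if (!cn[[role]] %in% names(raw)) {
      rlang::abort(paste0("Missing required column '", cn[[role]], "' (role: ", role, ")."),
                   class = "radlabel_schema_error")
    }
  }
  ab <- suppressWarnings(as.numeric(raw[[cn[["abundance"]]]]))
  bad <- which(is.na(ab) & !is.na(raw[[cn[["abundance"]]]]))
  if (length(bad) > 0 || anyNA(raw[[cn[["abundance"]]]])) {
    row <- if (length(bad) > 0) bad[1] else which(is.na(raw[[cn[["abundance"]]]]))[1]
    rlang::abort(paste0("Non-numeric or missing abundance at data row ", row, "."),
                 class = "radlabel_parse_error")
  }
  if (any(ab < 0)) {
    rlang::abort("Abundances must be >= 0.", class = "radlabel_parse_error")
  }
  sp <- raw[[cn[["species"]]]]
  if (anyDuplicated(sp)) {
    rlang::abort(paste0("Duplicate species name: ",
                        sp[duplicated(sp)][1]),
                 class = "radlabel_schema_error")
  }

  tb <- tibble::tibble(
    species = sp,
    genus = raw[[cn[["genus"]]]],
    guild = raw[[cn[["guild"]]]],
    abundance = ab
  )
  if (cn[["rank"]] %in% names(raw)) {
    rk <- suppressWarnings(as.integer(raw[[cn[["rank"]]]]))
    pos <- tb$abundance > 0
    expected <- rank_min_desc(tb$abundance[pos])
    if (anyNA(rk[pos]) || any(rk[pos] != expected)) {
      rlang::abort("Precomputed rank column is inconsistent with abundance ordering.",
                   class = "radlabel_schema_error")
    }
    tb$rank <- rk
  }
  tb$zero_abundance <- tb$abundance == 0
  structure(tb, class = c("community_table", class(tb)))
}

#' Write a community table to delimited text
#'
#' @param table A `community_table` (or compatible data frame).
#' @param path Output path; extension `.tsv` selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path) {
  out <- tibble::as_tibble(table)
  out$zero_abundance <- NULL
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Rank a community table and attach genus-by-guild groups
#'
#' Ranks species by descending abundance with competition ("min") ties —
#' tied abundances share the smallest applicable rank and the next distinct
#' abundance skips accordingly — unless the table carries a precomputed rank
#' column, which is preserved verbatim. The similarity grouping is
#' `genus x guild`: species sharing both genus and guild code form a group;
#' species alone in their genus-guild combination are singletons.
#' Zero-abundance species are excluded from ranking (they mirror the model's
#' extinct species). An optional exclusion list removes named species before
#' ranking, re-ranking the remainder contiguously.
#'
#' @param table A `community_table` (from [read_community_table()] or a
#'   generator).
#' @param exclude Character vector of species names to drop before ranking.
#' @return A `rad_community` with `group_key = genus x guild` (singletons'
#'   keys are kept but marked by the `singleton` column), carrying `genus`,
#'   `guild`, and `abundance` columns.
#' @examples
#' tb <- tibble::tibble(species = letters[1:4], genus = c("G1","G1","G2","G3"),
#'                      guild = "F", abundance = c(10, 5, 5, 1))
#' rank_with_ties(tb)$rank  # 1 2 2 4
#' @export
rank_with_ties <- function(table, exclude = NULL) {
  tb <- tibble::as_tibble(table)
  if (!all(c("species", "genus", "guild", "abundance") %in% names(tb))) {
    rlang::abort("Table must have columns species, genus, guild, abundance.",
                 class = "radlabel_schema_error")
  }
  if (!is.null(exclude)) tb <- tb[!tb$species %in% exclude, , drop = FALSE]
  tb <- tb[tb$abundance > 0, , drop = FALSE]
  if (nrow(tb) == 0L) {
    rlang::abort("No species with positive abundance: empty community.",
                 class = "radlabel_empty_community")
  }
  ranks <- if ("rank" %in% names(tb) && is.null(exclude)) {
    as.integer(tb$rank)
  } else {
    rank_min_desc(tb$abundance)
  }
  key <- paste(tb$genus, tb$guild, sep = ":")
  multi <- names(which(table(key) >= 2L))
  rad <- new_rad(
    species_id = tb$species,
    frequency = tb$abundance / sum(tb$abundance),
    rank = ranks,
    peak = NA,
    group_key = key,
    grid_index = NA_integer_,
    resolution = nrow(tb),
    threshold = 0,
    extra = tibble::tibble(genus = tb$genus, guild = tb$guild,
                           abundance = tb$abundance,
                           singleton = !key %in% multi)
  )
  rad
}

#' Write a rank-test report and its RAD table
#'
#' Serializes a [randomization_test()] result to JSON (observed indices,
#' null summaries, probabilities with significance marks, seed, trial count,
#' software version) and writes the ranked community alongside as delimited
#' text. Identical inputs give byte-identical files.
#'
#' @param result A `rank_test_result`.
#' @param rad The `rad_community` the test was run on.
#' @param path Path for the JSON report; the RAD table goes to the same path
#'   with a `_rad.csv` suffix.
#' @return Invisibly, a list of the two paths written.
#' @export
write_report <- function(result, rad, path) {
  g <- glance.rank_test_result(result)
  payload <- c(
    as.list(g),
    list(
      seed = result$seed,
      rank_scale = result$rank_scale,
      mode = result$mode,
      p_rank_denominator = result$p_rank_denominator,
      group_sizes = I(result$group_sizes),
      software = "radlabel",
      version = as.character(utils::packageVersion("radlabel"))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rad_path <- sub("\\.json$", "", path)
  rad_path <- paste0(rad_path, "_rad.csv")
  readr::write_csv(tibble::as_tibble(rad), rad_path, progress = FALSE)
  invisible(list(report = path, rad = rad_path))
}

#' Read back a rank-test report
#'
#' @param path Path written by [write_report()].
#' @return A list of report fields.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
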