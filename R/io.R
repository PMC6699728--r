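# Scenario files (YAML/JSON) and trajectory serialization.

scenario_schema_version <- "1"

scenario_keys <- c("schema_version", "eps_A", "eps_B", "eps_AM", "eps_BM",
                   "eps_Rev", "m", "generations", "releases",
                   "record_genotypes", "stop_wild", "stop_stationary")

#' Load a scenario configuration file
#'
#' Reads a YAML or JSON scenario file into a [scenario_config()]. Unknown
#' keys are rejected. Missing keys take the package defaults (intact
#' constructs at 5% fitness cost, mutated at 4%, `m = 1e-6`, a 1:1
#' release of intact double homozygotes at generation 0, horizon 10000).
#' Releases are given as a list of mappings with fields `generation`,
#' `genotype` and `alpha`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `ud_scenario` object.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop("scenario file must parse to a mapping: ", path)
  unknown <- setdiff(names(raw), scenario_keys)
  if (length(unknown))
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$schema_version) &&
      as.character(raw$schema_version) != scenario_schema_version)
    stop("unsupported scenario schema version: ", raw$schema_version)
  num <- function(key, default) {
    v <- raw[[key]]
    if (is.null(v)) return(default)
    v <- suppressWarnings(as.numeric(v))
    if (length(v) != 1 || !is.finite(v))
      stop("scenario field '", key, "' must be a single finite number")
    v
  }
  params <- fitness_params(eps_A = num("eps_A", 0.95),
                           eps_B = num("eps_B", 0.95),
                           eps_AM = num("eps_AM", 0.96),
                           eps_BM = num("eps_BM", 0.96),
                           eps_Rev = num("eps_Rev", 0.96))
  releases <- if (is.null(raw$releases)) {
    list(release_event(0L, "AABB", 1))
  } else {
    lapply(raw$releases, function(r) {
      extra <- setdiff(names(r), c("generation", "genotype", "alpha"))
      if (length(extra))
        stop("unknown release fields: ", paste(extra, collapse = ", "))
      if (is.null(r$generation) || is.null(r$genotype) || is.null(r$alpha))
        stop("each release needs fields generation, genotype and alpha")
      release_event(as.integer(r$generation), r$genotype, as.numeric(r$alpha))
    })
  }
  scenario_config(
    params = params, m = num("m", 1e-6), releases = releases,
    generations = as.integer(num("generations", 10000)),
    record_genotypes = isTRUE(raw$record_genotypes),
    stop_wild = if (is.null(raw$stop_wild)) NULL else num("stop_wild", NULL),
    stop_stationary = if (is.null(raw$stop_stationary)) NULL
                      else num("stop_stationary", NULL))
}

scenario_header <- function(config) {
  rel <- vapply(config$releases, function(r)
    sprintf("{generation: %d, genotype: \"%s\", alpha: %.17g}",
            r$generation, paste(r$genotype, collapse = " "), r$alpha),
    character(1))
  c(sprintf("# underdrive_version: %s",
            as.character(utils::packageVersion("underdrive"))),
    sprintf("# schema_version: %s", scenario_schema_version),
    sprintf("# eps_A: %.17g", config$params$eps_A),
    sprintf("# eps_B: %.17g", config$params$eps_B),
    sprintf("# eps_AM: %.17g", config$params$eps_AM),
    sprintf("# eps_BM: %.17g", config$params$eps_BM),
    sprintf("# eps_Rev: %.17g", config$params$eps_Rev),
    sprintf("# m: %.17g", config$m),
    sprintf("# generations: %d", config$generations),
    sprintf("# releases: [%s]", paste(rel, collapse = ", ")))
}

#' Write a trajectory to CSV
#'
#' Writes the trajectory as CSV at full double precision (17 significant
#' digits, so values round-trip bit-exactly through [read_trajectory()]),
#' preceded by `#`-prefixed header lines embedding the resolved scenario
#' configuration and the package version.
#'
#' @param tr A trajectory from [run_scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  config <- attr(tr, "config")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write trajectory to '",
                                           path, "': ", conditionMessage(e)))
  on.exit(close(con))
  if (!is.null(config)) writeLines(scenario_header(config), con)
  df <- as.data.frame(tr)
  cells <- vapply(df, function(col) {
    if (is.integer(col) || all(col == round(col))) sprintf("%d", as.integer(col))
    else sprintf("%.17g", col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0L)
    writeLines(apply(cells, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path File path.
#' @return A data frame with the allele-frequency columns; header
#'   metadata is attached as the `header` attribute (named character
#'   vector).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        check.names = FALSE)
  meta <- sub("^# *", "", hdr)
  keys <- sub(":.*$", "", meta)
  vals <- sub("^[^:]*: *", "", meta)
  attr(df, "header") <- stats::setNames(vals, keys)
  df
}
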