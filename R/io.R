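#' Read catch records from CSV
#'
#' Expects a header with at least `length_cm`, optionally `id`, `sex` and
#' `age`; column order is irrelevant. Rows failing validation (non-positive
#' or non-numeric length, negative age) are collected in the
#' `"rejected"` attribute with a reason, never silently dropped.
#'
#' @param path CSV file path.
#' @return Data frame of valid records (`id`, `sex`, `length_cm`, and
#'   `age` when present) with attribute `rejected` (data frame of bad rows
#'   and reasons).
#' @export
read_catch_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!"length_cm" %in% names(raw))
    stop("catch CSV must have a 'length_cm' column")
  if (!"id" %in% names(raw)) raw$id <- seq_len(nrow(raw))
  if (!"sex" %in% names(raw)) raw$sex <- "unknown"
  raw$sex[!raw$sex %in% c("F", "M")] <- "unknown"
  len <- suppressWarnings(as.numeric(raw$length_cm))
  bad <- !is.finite(len) | len <= 0
  reason <- ifelse(bad, "invalid length", "")
  if (!is.null(raw$age)) {
    age <- suppressWarnings(as.numeric(raw$age))
    bad_age <- !is.na(raw$age) & (!is.finite(age) | age < 0)
    reason[bad_age] <- paste0(reason[bad_age], " invalid age")
    bad <- bad | bad_age
    raw$age <- age
  }
  raw$length_cm <- len
  keep_cols <- intersect(c("id", "sex", "length_cm", "age"), names(raw))
  out <- raw[!bad, keep_cols, drop = FALSE]
  rownames(out) <- NULL
  rejected <- raw[bad, keep_cols, drop = FALSE]
  if (nrow(rejected)) rejected$reason <- trimws(reason[bad])
  attr(out, "rejected") <- rejected
  out
}

#' Write catch records to CSV
#'
#' @param records Catch records data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catch_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write result tables as CSV and JSON
#'
#' Every named element of `results` is written to `<dir>/<name>.csv` (data
#' frames) and `<dir>/<name>.json`.
#'
#' @param results Named list of data frames / lists.
#' @param dir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_tables <- function(results, dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      write.csv(x, f, row.names = FALSE)
      written <- c(written, f)
    }
    j <- file.path(dir, paste0(nm, ".json"))
    jsonlite::write_json(x, j, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    written <- c(written, j)
  }
  invisible(written)
}

run_config_schema <- list(
  life_history = c("L_inf", "k", "t0", "L_mat", "t_mat", "t_max",
                   "t_max_mortality", "m_bar", "m_sd", "cycle_years",
                   "temp_C", "length_weight_a", "length_weight_b"),
  mortality = c("aggregation"),
  total_mortality = c("Z_values", "catch_file"),
  scenarios = c("name", "recruit_age"),
  monte_carlo = c("n", "seed", "ci_level"),
  output = c("dir")
)

#' Read and validate a pipeline configuration
#'
#' Configurations are JSON with the blocks `life_history`, `mortality`,
#' `total_mortality`, `scenarios`, `monte_carlo` and `output`. Unknown
#' blocks or keys are rejected with an error naming the offenders, so
#' typos never pass silently.
#'
#' @param path JSON file path.
#' @return The validated configuration list.
#' @seealso [porosus_run_config()] for the bundled default,
#'   [run_pipeline()] to execute one.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_run_config(cfg)
  cfg
}

#' Validate a pipeline configuration list
#'
#' @param cfg Configuration list (see [porosus_run_config()] for the
#'   expected shape).
#' @return `TRUE` invisibly; errors describe any unknown blocks or keys.
#' @export
validate_run_config <- function(cfg) {
  bad_blocks <- setdiff(names(cfg), names(run_config_schema))
  if (length(bad_blocks))
    stop("unknown config blocks: ", paste(bad_blocks, collapse = ", "))
  for (blk in intersect(names(cfg), names(run_config_schema))) {
    if (blk == "scenarios") {
      keys <- if (is.data.frame(cfg[[blk]])) names(cfg[[blk]])
      else unique(unlist(lapply(cfg[[blk]], names)))
    } else keys <- names(cfg[[blk]])
    bad <- setdiff(keys, run_config_schema[[blk]])
    if (length(bad))
      stop("unknown keys in config block '", blk, "': ",
           paste(bad, collapse = ", "))
  }
  if (is.null(cfg$life_history)) stop("config needs a life_history block")
  invisible(TRUE)
}

#' Default pipeline configuration for the smalltail shark analysis
#'
#' @return Configuration list mirroring [porosus_profile()],
#'   [porosus_Z_values()] and [porosus_scenarios()], with 1000 Monte Carlo
#'   draws.
#' @export
porosus_run_config <- function() {
  list(
    life_history = list(L_inf = 136.4, k = 0.077, t0 = -3.27, L_mat = 71,
                        t_max = 12, t_max_mortality = 14, m_bar = 1.48,
                        m_sd = 0.57, cycle_years = 2, temp_C = 28,
                        length_weight_a = 5e-6, length_weight_b = 3.0),
    mortality = list(aggregation = "age-mean"),
    total_mortality = list(Z_values = unname(porosus_Z_values())),
    scenarios = list(list(name = "1: no fishing"),
                     list(name = "2: fishing from recruitment age",
                          recruit_age = 2),
                     list(name = "3: fishing from maturity",
                          recruit_age = 6)),
    monte_carlo = list(n = 1000, seed = 1, ci_level = 0.95),
    output = list(dir = NULL)
  )
}
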