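# File-format adapters. CSV dialect is fixed: UTF-8, comma separator, dot
# decimal, mandatory header row. FASTQ is strict 4-line records.

check_columns <- function(d, required, what, path) {
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop(sprintf("%s '%s': missing column(s) %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(d)
}

read_checked_csv <- function(path, required, what, numeric_cols = required) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  # grouping mark set to NBSP so "1,5" is never silently read as 15 or 1005
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       locale = readr::locale(decimal_mark = ".",
                                              grouping_mark = " "))
  check_columns(d, required, what, path)
  for (col in intersect(numeric_cols, names(d))) {
    if (!is.numeric(d[[col]])) {
      stop(sprintf(paste0("%s '%s': column '%s' is not numeric ",
                          "(check decimal separator: dot required)"),
                   what, path, col), call. = FALSE)
    }
  }
  d
}

#' Read a 96-well plate-reader endpoint table
#'
#' Expected header: `well, day, od, yfp, cfp`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_plate_csv <- function(path) {
  read_checked_csv(path, c("well", "day", "od", "yfp", "cfp"), "plate CSV",
                   numeric_cols = c("day", "od", "yfp", "cfp"))
}

#' Read a flow-cytometry-like event table
#'
#' Expected header: `event, yfp, cfp`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_event_csv <- function(path) {
  read_checked_csv(path, c("event", "yfp", "cfp"), "event CSV")
}

#' Read a qPCR Cq table
#'
#' Expected header: `sample, channel, replicate, cq, dilution`; dilution-series
#' rows have `sample == "dilution"` and a non-missing `dilution`.
#'
#' @param path CSV file path.
#' @return A `qpcr_run` list with elements `cq` and `dilution_series`.
#' @export
read_cq_csv <- function(path) {
  d <- read_checked_csv(path, c("sample", "channel", "replicate", "cq",
                                "dilution"),
                        "Cq CSV", numeric_cols = c("cq", "dilution"))
  run <- list(
    cq = d[d$sample != "dilution", c("sample", "channel", "replicate", "cq")],
    dilution_series = d[d$sample == "dilution",
                        c("channel", "dilution", "cq")]
  )
  class(run) <- "qpcr_run"
  run
}

#' Write a qPCR run to a single Cq CSV
#'
#' @param run A `qpcr_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cq_csv <- function(run, path) {
  d <- dplyr::bind_rows(
    dplyr::mutate(run$cq, dilution = NA_real_),
    dplyr::mutate(run$dilution_series, sample = "dilution",
                  replicate = NA_integer_)
  )
  readr::write_csv(d[c("sample", "channel", "replicate", "cq", "dilution")],
                   path, progress = FALSE)
  invisible(path)
}

#' Write a tidy table as CSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read amplicon reads from a FASTQ file
#'
#' Strict 4-line records (Sanger-encoded qualities; qualities are carried but
#' ignored by the assays).
#'
#' @param path FASTQ file path.
#' @return A tibble (`id`, `seq`, `qual`) of class `fastq_reads`.
#' @export
read_fastq_reads <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop(sprintf("truncated FASTQ '%s': record %d is incomplete", path,
                 length(lines) %/% 4 + 1), call. = FALSE)
  }
  n <- length(lines) %/% 4
  hd <- lines[seq(1, by = 4, length.out = n)]
  sq <- lines[seq(2, by = 4, length.out = n)]
  pl <- lines[seq(3, by = 4, length.out = n)]
  ql <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") |
                 nchar(sq) != nchar(ql))
  if (length(bad) > 0) {
    stop(sprintf("malformed FASTQ '%s': record %d", path, bad[1]),
         call. = FALSE)
  }
  out <- tibble::tibble(id = sub("^@", "", hd), seq = toupper(sq), qual = ql)
  class(out) <- c("fastq_reads", class(out))
  out
}

#' Write amplicon reads to a FASTQ file
#'
#' @param reads A tibble (`id`, `seq`, `qual`), e.g. from
#'   [gen_amplicon_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq_reads <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated experiment as tidy trajectory CSV plus manifest
#'
#' @param experiment A `dupdiv_experiment`.
#' @param dir Output directory (created if needed).
#' @param name File stem (default `"trajectories"`).
#' @return Paths of the CSV and JSON manifest, invisibly.
#' @export
write_experiment <- function(experiment, dir, name = "trajectories") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  readr::write_csv(tibble::as_tibble(experiment), csv, progress = FALSE)
  manifest <- file.path(dir, paste0(name, "_manifest.json"))
  write_manifest(manifest,
                 config = attr(experiment, "config"),
                 base_seed = attr(experiment, "base_seed"),
                 n_replicates = attr(experiment, "n_replicates"),
                 outputs = basename(csv))
  invisible(c(csv = csv, manifest = manifest))
}

config_as_list <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_as_list(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a reproducibility manifest
#'
#' Records package version, the full configuration and its MD5 hash, seeds and
#' any extra fields — enough to reproduce the artifact bit-for-bit.
#'
#' @param path Output JSON path.
#' @param config A [sim_config()] (or `NULL`).
#' @param ... Extra fields to record (seeds, input checksums, output names).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = NULL, ...) {
  m <- list(
    package = "dupdiv",
    version = as.character(utils::packageVersion("dupdiv")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    ...
  )
  if (!is.null(config)) {
    m$config <- config_as_list(config)
    m$config_hash <- config_hash(config)
  }
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# --- run configuration files ------------------------------------------------

# minimal TOML-style key/value reader: [section] headers, key = value lines,
# '#' comments; values are numbers, quoted strings, or bare words
parse_kv_value <- function(v) {
  v <- trimws(v)
  if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  if (v %in% c("true", "false")) return(v == "true")
  v
}

#' Read a run configuration file
#'
#' TOML-style sections `[alleles]`, `[env]`, `[rates]`, `[protocol]`,
#' `[model]` with `key = value` lines; every key must be an argument of the
#' corresponding constructor ([allele_params()], [env_params()],
#' [mutation_rates()], [serial_protocol()]; `[model]` takes `kmax`). Unknown
#' keys or sections are rejected.
#'
#' @param path Configuration file path.
#' @return A [sim_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  vals <- list(alleles = list(), env = list(), rates = list(),
               protocol = list(), model = list())
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(vals)) {
        stop("unknown config section [", section, "]", call. = FALSE)
      }
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.na(section)) stop("config line outside any section: ", ln,
                               call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      vals[[section]][[key]] <- parse_kv_value(sub("^[^=]*=", "", ln))
    } else {
      stop("unparseable config line: ", ln, call. = FALSE)
    }
  }
  check_keys <- function(got, allowed, section) {
    bad <- setdiff(names(got), allowed)
    if (length(bad) > 0) {
      stop("unknown key(s) in [", section, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  check_keys(vals$alleles, names(formals(allele_params)), "alleles")
  check_keys(vals$env, names(formals(env_params)), "env")
  check_keys(vals$rates, names(formals(mutation_rates)), "rates")
  check_keys(vals$protocol, names(formals(serial_protocol)), "protocol")
  check_keys(vals$model, "kmax", "model")
  sim_config(
    alleles = do.call(allele_params, vals$alleles),
    env = do.call(env_params, vals$env),
    rates = do.call(mutation_rates, vals$rates),
    protocol = do.call(serial_protocol, vals$protocol),
    kmax = vals$model$kmax %||% 20
  )
}

#' Write a run configuration file
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  fmt <- function(section, x) {
    c(sprintf("[%s]", section),
      vapply(names(x), function(k) sprintf("%s = %s", k, format(x[[k]])),
             character(1)),
      "")
  }
  writeLines(c(
    fmt("alleles", unclass(config$alleles)),
    fmt("env", unclass(config$env)),
    fmt("rates", unclass(config$rates)),
    fmt("protocol", unclass(config$protocol)),
    fmt("model", list(kmax = config$kmax))
  ), path)
  invisible(path)
}
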