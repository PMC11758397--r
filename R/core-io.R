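#' Write a sweep set to a directory
#'
#' The on-disk dialect is one CSV per sweep (columns `time_ms`,
#' `voltage_mV`, `current_pA`) plus a `protocol.json` sidecar. Converters
#' to other unit systems belong at this boundary; everything inside the
#' package is mV / pA / ms.
#'
#' @param sweepset A [sweep_set()].
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_sweepset <- function(sweepset, path) {
  stopifnot(inherits(sweepset, "sweep_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  proto <- sweepset$protocol
  meta <- list(
    step_amplitudes_pa = proto$step_amplitudes_pa,
    step_onset_ms = proto$step_onset_ms,
    step_duration_ms = proto$step_duration_ms,
    inter_sweep_interval_s = proto$inter_sweep_interval_s,
    neuron_id = sweepset$sweeps[[1]]$neuron_id,
    sweep_files = sprintf("sweep_%03d.csv", seq_along(sweepset$sweeps))
  )
  jsonlite::write_json(meta, file.path(path, "protocol.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(sweepset$sweeps)) {
    sw <- sweepset$sweeps[[i]]
    cur <- if (length(sw$current_pa) == 1L) {
      rep(sw$current_pa, length(sw$time_ms))
    } else sw$current_pa
    df <- data.frame(time_ms = sw$time_ms, voltage_mV = sw$voltage_mv,
                     current_pA = cur)
    utils::write.csv(df, file.path(path, meta$sweep_files[i]),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a sweep set from a directory
#'
#' Inverse of [write_sweepset()]. Validates the sweep-set invariants:
#' uniform time grids, equal sample counts, one sweep per protocol
#' amplitude. Each violation raises a distinct error naming the culprit.
#'
#' @param path Directory written by [write_sweepset()] (or hand-assembled
#'   in the same dialect).
#' @return A [sweep_set()].
#' @export
read_sweepset <- function(path) {
  pj <- file.path(path, "protocol.json")
  if (!file.exists(pj)) stop("no protocol.json in ", path, call. = FALSE)
  meta <- jsonlite::read_json(pj, simplifyVector = TRUE)
  proto <- step_protocol(meta$step_amplitudes_pa, meta$step_onset_ms,
                         meta$step_duration_ms, meta$inter_sweep_interval_s)
  files <- meta$sweep_files
  sweeps <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- file.path(path, files[i])
    if (!file.exists(f)) stop("missing sweep file ", files[i], call. = FALSE)
    df <- utils::read.csv(f)
    need <- c("time_ms", "voltage_mV", "current_pA")
    if (!all(need %in% names(df))) {
      stop(sprintf("sweep file '%s' lacks columns: %s", files[i],
                   paste(setdiff(need, names(df)), collapse = ", ")),
           call. = FALSE)
    }
    sweeps[[i]] <- sweep_recording(df$time_ms, df$voltage_mV, df$current_pA,
                                   sweep_id = i,
                                   neuron_id = meta$neuron_id %||% "n1")
  }
  sweep_set(proto, sweeps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-neuron feature records as TSV
#'
#' @param records Data frame of homogeneous feature records (one row per
#'   neuron), or a list of identically named lists.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- records_to_df(records)
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read per-neuron feature records from TSV
#' @param path TSV written by [write_records()].
#' @return Data frame.
#' @export
read_records <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

records_to_df <- function(records) {
  if (is.data.frame(records)) return(records)
  if (length(records) == 0L) return(data.frame())
  schemas <- lapply(records, names)
  if (length(unique(vapply(schemas, paste, character(1), collapse = "|"))) > 1L) {
    stop("heterogeneous record schemas", call. = FALSE)
  }
  do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write a group-summary feature table
#'
#' Mirrors the layout of published cell-type tables: rows are parameters,
#' columns are groups, cells hold `mean +/- SD`. Group sizes appear in the
#' column headers; an `(n=1)` group is flagged there and its SD reported
#' as 0.
#'
#' @param records Data frame with one row per neuron, a grouping column,
#'   and numeric feature columns.
#' @param path Output TSV path.
#' @param group_col Name of the grouping column.
#' @param digits Significant digits for formatting.
#' @return The summary data frame (features x groups), invisibly.
#' @export
write_feature_table <- function(records, path, group_col = "group",
                                digits = 4) {
  records <- records_to_df(records)
  if (nrow(records) == 0L) {
    utils::write.table(data.frame(parameter = character(0)), path,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(data.frame(parameter = character(0))))
  }
  if (!group_col %in% names(records)) {
    stop("no grouping column '", group_col, "' in records", call. = FALSE)
  }
  feats <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                   group_col)
  groups <- unique(as.character(records[[group_col]]))
  out <- data.frame(parameter = feats, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- records[records[[group_col]] == g, , drop = FALSE]
    cells <- vapply(feats, function(f) {
      v <- sub[[f]][!is.na(sub[[f]])]
      if (length(v) == 0L) return("NA")
      ms <- group_mean_sd(v)
      sprintf("%s ± %s", signif(ms$mean, digits), signif(ms$sd, digits))
    }, character(1))
    hdr <- sprintf("%s (n=%d)", g, nrow(sub))
    out[[hdr]] <- cells
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Derive a per-stage, per-unit RNG seed from a master seed
#'
#' Counter-based fan-out so pipeline stages can be rerun independently and
#' reproducibly: each (stage, index) pair maps to a distinct 31-bit seed.
#'
#' @param master Master seed (integer).
#' @param stage Stage name (character) or integer stage code.
#' @param index Unit index within the stage.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 1L) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + as.numeric(stage) * 16807) %% m
  x <- (x * 48271 + as.numeric(index)) %% m
  as.integer(x %% (m - 1) + 1)
}
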