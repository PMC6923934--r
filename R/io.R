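# File formats. CSV dialect is pinned: comma separator, '.' decimal, LF,
# UTF-8, mandatory header. Units are fixed by the schema (mV, ms, nA, nC,
# mmol/L); no autodetection.

.trace_csv_cols <- c("sweep_id", "step_mV", "time_ms", "current_nA")
.ct_csv_cols <- c("gene", "stage", "replicate", "round", "ct")

.write_csv <- function(df, path) {
  # render doubles with 17 significant digits so the round trip is exact
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
}

# md5 fingerprint of an R object via its canonical JSON rendering
config_fingerprint <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write / read a trace set (CSV + JSON sidecar)
#'
#' The sweep samples go to `<name>.csv` with columns `sweep_id`,
#' `step_mV`, `time_ms`, `current_nA`; the protocol and condition metadata
#' (plus package version and a content fingerprint) go to `<name>.json`.
#' The round trip is lossless for the numeric payload.
#'
#' @param ts A `trace_set`.
#' @param dir Output directory (created if missing).
#' @param name File stem.
#' @return `write_trace_set()` returns the CSV path invisibly;
#'   `read_trace_set()` returns a `trace_set`.
#' @export
write_trace_set <- function(ts, dir, name = "traces") {
  stopifnot(inherits(ts, "trace_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(ts$current)
  df <- data.frame(
    sweep_id = rep(seq_len(ncol(ts$current)), each = n),
    step_mV = rep(ts$protocol$steps, each = n),
    time_ms = rep(ts$time_ms, times = ncol(ts$current)),
    current_nA = as.vector(ts$current))
  csv <- file.path(dir, paste0(name, ".csv"))
  .write_csv(df, csv)
  sidecar <- list(
    schema = "tevckit/trace_set/1",
    tool_version = as.character(utils::packageVersion("tevckit")),
    protocol = ts$protocol[c("v_hold", "steps", "pre_ms", "pulse_ms",
                             "post_ms", "sample_rate")],
    metadata = ts$metadata)
  sidecar$fingerprint <- config_fingerprint(sidecar[c("protocol", "metadata")])
  jsonlite::write_json(sidecar, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv)
}

#' @param path Path to the `.csv` file (the `.json` sidecar is looked up
#'   next to it).
#' @rdname write_trace_set
#' @export
read_trace_set <- function(path) {
  json_path <- sub("\\.csv$", ".json", path)
  if (!file.exists(path)) stop("trace CSV not found: ", path, call. = FALSE)
  if (!file.exists(json_path)) {
    stop("missing JSON sidecar: ", json_path, call. = FALSE)
  }
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.trace_csv_cols, names(df))
  if (length(missing_cols)) {
    stop("trace CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  prot <- side$protocol
  protocol <- build_protocol(
    v_hold = prot$v_hold,
    start = prot$steps[1], stop = prot$steps[length(prot$steps)],
    increment = if (length(prot$steps) > 1) prot$steps[2] - prot$steps[1]
                else 1,
    pulse_ms = prot$pulse_ms, sample_rate = prot$sample_rate,
    pre_ms = prot$pre_ms, post_ms = prot$post_ms)
  counts <- table(df$sweep_id)
  if (length(unique(counts)) != 1) {
    stop("sweeps have inconsistent sample counts", call. = FALSE)
  }
  if (length(counts) != length(protocol$steps)) {
    stop("number of sweeps does not match the protocol step list",
         call. = FALSE)
  }
  sweeps <- split(df, df$sweep_id)
  for (sw in sweeps) {
    if (is.unsorted(sw$time_ms, strictly = TRUE)) {
      stop("non-monotone time base in sweep ", sw$sweep_id[1], call. = FALSE)
    }
  }
  current <- do.call(cbind, lapply(sweeps, `[[`, "current_nA"))
  colnames(current) <- paste0("step_", seq_len(ncol(current)))
  structure(list(protocol = protocol, time_ms = sweeps[[1]]$time_ms,
                 current = current, metadata = side$metadata),
            class = "trace_set")
}

#' Write / read a threshold-cycle table
#'
#' Plain CSV with columns `gene`, `stage`, `replicate`, `round`, `ct`.
#'
#' @param table A CT table data frame.
#' @param path CSV path.
#' @return `read_ct_table()` returns the validated data frame.
#' @export
write_ct_table <- function(table, path) {
  .check_ct_table(table)
  .write_csv(table[, .ct_csv_cols], path)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.ct_csv_cols, names(df))
  if (length(missing_cols)) {
    stop("CT table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  .check_ct_table(df)
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Protein length implied by a coding sequence
#'
#' `cds_bp / 3 - 1` amino acids: one codon per residue, terminal stop
#' codon untranslated (a 2154 bp CDS encodes 717 residues).
#'
#' @param cds_bp Coding-sequence length in base pairs; a multiple of 3,
#'   at least 6 (one codon plus the stop).
#' @return Protein length in amino acids.
#' @export
cds_protein_length <- function(cds_bp) {
  .check_finite(cds_bp, "cds_bp")
  if (any(cds_bp %% 3 != 0)) {
    stop("`cds_bp` must be a multiple of 3 (reading-frame violation)",
         call. = FALSE)
  }
  if (any(cds_bp < 6)) stop("`cds_bp` must be at least 6", call. = FALSE)
  cds_bp / 3 - 1
}
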