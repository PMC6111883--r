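# Plain-text readers/writers.  All numeric payloads are written with
# "%.17g" so a write/read round trip reproduces doubles exactly; MSP
# cycle data has no community standard format, so delimited text with a
# small manifest keeps fixtures human-readable.

write_matrix_txt <- function(m, path) {
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                         collapse = "\t"))
  writeLines(lines, path)
}

read_matrix_txt <- function(path, expected_cols = NULL) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (!is.null(expected_cols) && ncol(m) != expected_cols) {
    stop("format error: ", path, " has ", ncol(m), " columns, expected ",
         expected_cols, call. = FALSE)
  }
  m
}

#' Read a continuous ECG signal from delimited text
#'
#' Accepts the two-column `time_s amplitude` layout (sampling rate
#' inferred from the time stamps) or a single amplitude column with the
#' rate given as `fs`.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz; required for single-column files.
#' @return List with `signal` and `fs`.
#' @export
read_ecg_signal <- function(path, fs = NULL) {
  tb <- utils::read.table(path, header = TRUE)
  if (ncol(tb) >= 2) {
    dt <- diff(tb[[1]])
    if (length(dt) < 1 || any(dt <= 0)) {
      stop("format error: ", path, " time column is not increasing",
           call. = FALSE)
    }
    list(signal = as.numeric(tb[[2]]), fs = 1 / stats::median(dt))
  } else {
    if (is.null(fs)) stop("single-column signal needs fs", call. = FALSE)
    list(signal = as.numeric(tb[[1]]), fs = fs)
  }
}

#' Write a continuous ECG signal as two-column text
#'
#' @param signal Numeric vector.
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @export
write_ecg_signal <- function(signal, path, fs = 250) {
  tt <- (seq_along(signal) - 1) / fs
  writeLines(c("time_s\tamplitude",
               sprintf("%.17g\t%.17g", tt, signal)), path)
}

#' Write cohort record sets to a directory
#'
#' One delimited matrix per subject and modality (18 rows, one feature
#' vector each) plus a `manifest.tsv` naming subject, modality, file
#' and the record/pulse grouping.
#'
#' @param records A cohort [wa_record_set()] tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_records <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- records |>
    dplyr::distinct(.data$subject, .data$modality) |>
    dplyr::mutate(file = paste0(.data$subject, "_", .data$modality, ".tsv"),
                  n_records = N_RECORDS,
                  pulses_per_record = PULSES_PER_RECORD)
  for (i in seq_len(nrow(man))) {
    sub <- records[records$subject == man$subject[i] &
                     records$modality == man$modality[i], ]
    sub <- sub[order(sub$record), ]
    write_matrix_txt(do.call(rbind, sub$features),
                     file.path(dir, man$file[i]))
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read cohort record sets written by [write_records()]
#'
#' @param dir Directory containing `manifest.tsv` and the per-subject
#'   matrices.
#' @return A cohort [wa_record_set()] tibble.
#' @export
read_records <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) {
    stop("format error: no manifest.tsv in ", dir, call. = FALSE)
  }
  man <- utils::read.table(man_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(man)), function(i) {
    m <- read_matrix_txt(file.path(dir, man$file[i]))
    if (nrow(m) != N_RECORDS * PULSES_PER_RECORD) {
      stop("format error: ", man$file[i], " has ", nrow(m),
           " rows, expected ", N_RECORDS * PULSES_PER_RECORD,
           call. = FALSE)
    }
    wa_record_set(man$subject[i], man$modality[i],
                  lapply(seq_len(N_RECORDS), function(r) {
                    m[(PULSES_PER_RECORD * (r - 1) + 1):
                        (PULSES_PER_RECORD * r), , drop = FALSE]
                  }))
  }))
}

#' Write raw MSP cycles for one mode to a directory
#'
#' One 16 x 32 matrix per cycle plus a manifest with the mode and
#' per-source type labels.
#'
#' @param cycles List of [msp_cycle()] objects (one acquisition mode).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_msp_cycles <- function(cycles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("cycle_%02d.tsv", seq_along(cycles))
  for (i in seq_along(cycles)) {
    write_matrix_txt(cycles[[i]]$readings, file.path(dir, files[i]))
  }
  man <- tibble::tibble(
    file = files,
    mode = vapply(cycles, function(cy) cy$mode, character(1)),
    source_type = vapply(cycles, function(cy)
      paste(cy$source_type, collapse = ","), character(1))
  )
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read raw MSP cycles written by [write_msp_cycles()]
#'
#' @param dir Directory containing `manifest.tsv` and the cycle files.
#' @return List of [msp_cycle()] objects.
#' @export
read_msp_cycles <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) {
    stop("format error: no manifest.tsv in ", dir, call. = FALSE)
  }
  man <- utils::read.table(man_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    m <- read_matrix_txt(file.path(dir, man$file[i]), N_DETECTORS)
    if (nrow(m) != N_SOURCES) {
      stop("format error: ", man$file[i], " has ", nrow(m),
           " rows, expected ", N_SOURCES, call. = FALSE)
    }
    msp_cycle(m, man$mode[i],
              strsplit(man$source_type[i], ",", fixed = TRUE)[[1]])
  })
}

#' Write an evaluation report
#'
#' Delimited table of the per-condition metrics (rows = fusion x
#' guided-filter condition, columns EER / PD.1 / FRR0 in percent)
#' preceded by provenance comment lines (package version, seed,
#' conditions).
#'
#' @param eval_tbl A `wa_eval` from [evaluate_cohort()].
#' @param path Output file.
#' @param seed Seed recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_report <- function(eval_tbl, path, seed = NA_integer_) {
  hdr <- c(
    paste0("# wristauth ",
           as.character(utils::packageVersion("wristauth"))),
    paste0("# seed: ", seed),
    paste0("# n_subjects: ", attr(eval_tbl, "n_subjects")),
    paste0("# conditions: ",
           paste(unique(paste(eval_tbl$gf, eval_tbl$mode, sep = "/")),
                 collapse = " "))
  )
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(tidy(eval_tbl), path, sep = "\t",
                       row.names = FALSE, quote = FALSE, append = TRUE)
  )
  invisible(path)
}
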