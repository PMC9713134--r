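# cohort writer/reader: per-trial CSV + manifest CSV + ground-truth JSON

fmt17 <- function(x) sprintf("%.17g", x)

write_numeric_csv <- function(df, path, header_comment = NULL) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt17(col) else as.character(col)
  })
  lines <- c(
    header_comment,
    paste(names(df), collapse = ","),
    do.call(paste, c(cols, sep = ","))
  )
  writeLines(lines, path)
}

trial_file_name <- function(participant_id, task_id, trial_index) {
  sprintf("%s_%s_%d.csv", participant_id, task_id, trial_index)
}

#' Write a simulated cohort to a directory
#'
#' One CSV per trial (columns `time_s`, then `<placement>_<acc|gyr>_<x|y|z>`),
#' a cohort `manifest.csv` (participant, task, trial, label, fs, file) and a
#' `ground_truth.json`. Doubles are written with 17 significant digits, so a
#' read-back round-trips bit-exactly.
#'
#' @param cohort A `gait_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort$trials))
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    n <- nrow(tr$placements[[1]]$acc)
    df <- list(time_s = (seq_len(n) - 1) / tr$fs)
    for (p in names(tr$placements)) {
      for (sig in c("acc", "gyr")) {
        m <- tr$placements[[p]][[sig]]
        for (j in 1:3) {
          df[[sprintf("%s_%s_%s", p, sig, c("x", "y", "z")[j])]] <- m[, j]
        }
      }
    }
    files[i] <- trial_file_name(tr$participant_id, tr$task_id, tr$trial_index)
    write_numeric_csv(as_tibble(df), file.path(dir, files[i]))
  }
  manifest <- cohort$manifest |>
    mutate(fs = cohort$config$fs,
           static_lead_in = cohort$config$static_lead_in,
           file = files[.data$index])
  write_numeric_csv(manifest, file.path(dir, "manifest.csv"))
  truths <- lapply(cohort$truths, function(tt) {
    tt$mounting <- lapply(tt$mounting, function(R) lapply(seq_len(nrow(R)), function(r) R[r, ]))
    tt$feet <- lapply(tt$feet, function(ft) {
      ft$stationary_intervals <- lapply(seq_len(nrow(ft$stationary_intervals)),
                                        function(r) ft$stationary_intervals[r, ])
      ft$velocity <- NULL  # bulky series; reconstructible by re-simulation
      ft
    })
    unclass(tt)
  })
  write_json(truths, file.path(dir, "ground_truth.json"),
             digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv`, per-trial CSVs and
#'   `ground_truth.json`.
#' @return A `gait_cohort` (without the noise-free velocity ground-truth
#'   series, which are not serialized).
#' @export
read_cohort <- function(dir) {
  manifest <- as_tibble(fread(file.path(dir, "manifest.csv")))
  trials <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    dat <- fread(file.path(dir, row$file))
    placements <- unique(sub("_(acc|gyr)_[xyz]$", "",
                             grep("_(acc|gyr)_[xyz]$", names(dat), value = TRUE)))
    pl <- list()
    for (p in placements) {
      pl[[p]] <- list(
        acc = as.matrix(dat[, paste0(p, "_acc_", c("x", "y", "z")), with = FALSE]),
        gyr = as.matrix(dat[, paste0(p, "_gyr_", c("x", "y", "z")), with = FALSE])
      )
      colnames(pl[[p]]$acc) <- c("x", "y", "z")
      colnames(pl[[p]]$gyr) <- c("x", "y", "z")
    }
    trials[[i]] <- structure(list(
      participant_id = row$participant_id, task_id = row$task_id,
      trial_index = as.integer(row$trial_index), label = as.integer(row$label),
      fs = row$fs, static_lead_in = row$static_lead_in, placements = pl
    ), class = "trial_recording")
  }
  truths <- read_json(file.path(dir, "ground_truth.json"))
  truths <- lapply(truths, function(tt) {
    tt$mounting <- lapply(tt$mounting, function(rows) {
      do.call(rbind, lapply(rows, unlist))
    })
    tt$feet <- lapply(tt$feet, function(ft) {
      ft$footfall_times <- unlist(ft$footfall_times)
      ft$stride_lengths <- unlist(ft$stride_lengths)
      ft$stride_times <- unlist(ft$stride_times)
      ft$stationary_intervals <- do.call(rbind, lapply(ft$stationary_intervals, unlist))
      ft
    })
    structure(tt, class = "trial_truth")
  })
  structure(list(trials = trials, truths = truths,
                 manifest = manifest |> select(-"file", -"fs", -"static_lead_in"),
                 config = NULL),
            class = "gait_cohort")
}
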