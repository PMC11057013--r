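#' Default severity scale for pod rot grading
#'
#' Five ordinal levels assigned from the rotten pod rate: Level 1 for no
#' rotten pods (rate exactly 0), Level 3 for rates in (0, 10%], Level 5 in
#' (10%, 25%], Level 7 in (25%, 50%], Level 9 above 50%. Interval knots are
#' right-closed so "larger than 50%" is exact.
#'
#' @return list with `boundaries` (0, 0.10, 0.25, 0.50) and `levels`
#'   (1, 3, 5, 7, 9).
#' @export
gradeScale <- function() {
  list(boundaries = c(0, 0.10, 0.25, 0.50), levels = c(1L, 3L, 5L, 7L, 9L))
}

#' Rotten pod rate
#'
#' Fraction of detected pods that are rotten:
#' `n_rotten / (n_nonrotted + n_rotten)`.
#'
#' @param nNonrotted,nRotten per-image pod counts.
#' @return rate in `[0, 1]`.
#' @export
rottenPodRate <- function(nNonrotted, nRotten) {
  if (any(nNonrotted + nRotten <= 0))
    stop("empty image: rate undefined when no pods were counted")
  nRotten / (nNonrotted + nRotten)
}

#' Disease grade from the rotten pod rate
#'
#' Maps a rate in `[0, 1]` to the ordinal level of the grading scale with
#' left-open/right-closed intervals (a rate of exactly 0.10 is still
#' Level 3, exactly 0.50 still Level 7).
#'
#' @param rate rotten pod rate(s) in `[0, 1]`.
#' @param scale scale from [gradeScale()].
#' @return integer grade level(s) in `{1, 3, 5, 7, 9}`.
#' @examples
#' podRotGrade(c(0, 0.05, 0.2, 0.3, 0.6))  # 1 3 5 7 9
#' @export
podRotGrade <- function(rate, scale = gradeScale()) {
  if (any(rate < 0 | rate > 1)) stop("rate must lie in [0, 1]")
  idx <- findInterval(rate, scale$boundaries, left.open = TRUE) + 1L
  # findInterval(left.open): rate = 0 -> 0 intervals passed -> level 1;
  # rate in (0, .1] -> 1; (.1, .25] -> 2; (.25, .5] -> 3; > .5 -> 4
  scale$levels[idx]
}

#' Build a grade record from per-image detections
#'
#' Counts detections per class and derives the rotten pod rate and grade.
#' An image with no detections yields counts 0, a rate defined as 0 and
#' Level 1, flagged via the `empty` column.
#'
#' @param imageId image identifier.
#' @param detections detection box table (columns `cls`, optionally `conf`).
#' @param scale grading scale, see [gradeScale()].
#' @return one-row data.frame: `image_id, n_nonrotted, n_rotten, total,
#'   rate, grade, empty`.
#' @export
recordFromDetections <- function(imageId, detections, scale = gradeScale()) {
  nG <- sum(detections$cls == "G"); nR <- sum(detections$cls == "R")
  tot <- nG + nR
  empty <- tot == 0L
  if (empty) warning(sprintf("image '%s': no detections; grade 1 flagged", imageId))
  rate <- if (empty) 0 else rottenPodRate(nG, nR)
  data.frame(image_id = imageId, n_nonrotted = nG, n_rotten = nR,
             total = tot, rate = rate,
             grade = podRotGrade(rate, scale), empty = empty,
             stringsAsFactors = FALSE)
}

#' Write per-image count files and the aggregate grading report
#'
#' For every record one `<image_id>.txt` file with the counts is written to
#' `out_dir/graduation/`, plus an aggregate table (`grading.csv` and a
#' mirror `grading.xlsx`) whose columns follow the workflow layout:
#' column 1 image id, column 2 non-rotted count, column 3 rotten count,
#' column 4 overall total, column 5 rotten pod rate, column 6 grade. The
#' total in column 4 is inferred (the layout leaves it unstated).
#'
#' @param records data.frame of grade records (rows from
#'   [recordFromDetections()]).
#' @param outDir output directory (created if missing).
#' @return invisible named list of written paths.
#' @export
writeGradeReports <- function(records, outDir) {
  dir.create(file.path(outDir, "graduation"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    writeLines(c(sprintf("image: %s", r$image_id),
                 sprintf("non_rotted: %d", r$n_nonrotted),
                 sprintf("rotten: %d", r$n_rotten),
                 sprintf("total: %d", r$total),
                 sprintf("rotten_pod_rate: %.6f", r$rate),
                 sprintf("grade: %d", r$grade)),
               file.path(outDir, "graduation", paste0(r$image_id, ".txt")))
  }
  tab <- records[, c("image_id", "n_nonrotted", "n_rotten", "total",
                     "rate", "grade"), drop = FALSE]
  csv <- file.path(outDir, "grading.csv")
  write.csv(tab, csv, row.names = FALSE)
  xlsx <- file.path(outDir, "grading.xlsx")
  writeMinimalXlsx(tab, xlsx)
  invisible(list(csv = csv, xlsx = xlsx,
                 txt_dir = file.path(outDir, "graduation")))
}

#' Re-read an aggregate grading report
#' @param path path to `grading.csv`.
#' @export
readGradeReport <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
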