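#' Five-level blood pressure stage code
#'
#' Classifies systolic/diastolic readings (mmHg) into the five conventional
#' blood pressure groups and codes them 1--5: normal (systolic < 120 and
#' diastolic < 80), elevated (systolic 120--129 and diastolic < 80), high
#' stage 1 (systolic 130--139 and diastolic 80--89), high stage 2 (systolic
#' 140--180 or diastolic 90--120) and hypertensive (systolic > 180 or
#' diastolic > 120).
#'
#' The printed band definitions neither cover nor partition the plane (a
#' reading of 125/85 satisfies no band verbatim; 150/125 satisfies two), so
#' the implementation uses the standard clinical convention: the systolic and
#' diastolic values are classified independently into their bands and the
#' reading receives the more severe of the two categories. This rule is total
#' and monotone in both components, and agrees with the printed definitions
#' wherever they apply unambiguously.
#'
#' @param systolic,diastolic Numeric vectors of pressures in mmHg. Recycled to
#'   a common length. Both must be positive and `systolic >= diastolic`.
#' @return Integer vector of codes in 1--5.
#' @examples
#' bp_code5(c(118, 125, 185), c(76, 85, 70))
#' @export
bp_code5 <- function(systolic, diastolic) {
  n <- max(length(systolic), length(diastolic))
  systolic <- rep_len(as.numeric(systolic), n)
  diastolic <- rep_len(as.numeric(diastolic), n)
  ok <- !is.na(systolic) & !is.na(diastolic)
  if (any(systolic[ok] <= 0 | diastolic[ok] <= 0)) {
    stop("blood pressure readings must be positive", call. = FALSE)
  }
  if (any(systolic[ok] < diastolic[ok])) {
    stop("systolic pressure must be >= diastolic pressure", call. = FALSE)
  }
  sys_code <- 1L + (systolic >= 120) + (systolic >= 130) + (systolic >= 140) +
    (systolic > 180)
  # diastolic has no "elevated" band: < 80 normal, 80-89 high stage 1,
  # 90-120 high stage 2, > 120 hypertensive
  dia_code <- 1L + 2L * (diastolic >= 80) + (diastolic >= 90) + (diastolic > 120)
  out <- pmax(sys_code, dia_code)
  out[!ok] <- NA_integer_
  out
}

#' Collapse the 5-level code to the 4-stage display code
#'
#' Display stages: 1 normal, 2 prehypertension (elevated + high stage 1),
#' 3 hypertension (high stage 2), 4 crisis (hypertensive). The mapping is
#' configurable for sensitivity analyses.
#'
#' @param code5 Integer vector of 5-level codes.
#' @param map Integer vector of length 5 giving the 4-level stage for each
#'   5-level code; must be non-decreasing.
#' @return Integer vector of codes in 1--4.
#' @export
bp_code4 <- function(code5, map = c(1L, 2L, 2L, 3L, 4L)) {
  stopifnot(length(map) == 5L, !is.unsorted(map))
  map[as.integer(code5)]
}

#' Dichotomize the 4-stage code into normal vs high
#'
#' @param code4 Integer vector of 4-level codes.
#' @param high_from Lowest 4-level stage counted as "high" (default 2).
#' @return Factor with levels `normal`, `high`.
#' @export
bp_binary <- function(code4, high_from = 2L) {
  factor(ifelse(code4 >= high_from, "high", "normal"),
         levels = c("normal", "high"))
}

#' Stage a clinical table
#'
#' Adds the columns `bp_code5`, `bp_code4` and `bp_binary` derived from the
#' `systolic` and `diastolic` columns.
#'
#' @param clinical A data frame with numeric `systolic` and `diastolic`
#'   columns (mmHg).
#' @inheritParams bp_code4
#' @inheritParams bp_binary
#' @return The input as a tibble with the three staging columns appended.
#' @examples
#' stage_bp(tibble::tibble(systolic = c(118, 145), diastolic = c(76, 95)))
#' @export
stage_bp <- function(clinical, map = c(1L, 2L, 2L, 3L, 4L), high_from = 2L) {
  for (col in c("systolic", "diastolic")) {
    if (!col %in% names(clinical)) {
      stop("clinical table lacks required column '", col, "'", call. = FALSE)
    }
  }
  clinical <- tibble::as_tibble(clinical)
  clinical$bp_code5 <- bp_code5(clinical$systolic, clinical$diastolic)
  clinical$bp_code4 <- bp_code4(clinical$bp_code5, map = map)
  clinical$bp_binary <- bp_binary(clinical$bp_code4, high_from = high_from)
  clinical
}

#' Count samples per 5-level blood pressure code
#'
#' @param clinical A staged clinical table (see [stage_bp()]), or any data
#'   frame with a `bp_code5` column.
#' @return A tibble with columns `bp_code5` (1--5) and `n`; counts sum to the
#'   number of rows of `clinical`, with zero rows represented explicitly.
#' @export
code_counts <- function(clinical) {
  if (!"bp_code5" %in% names(clinical)) {
    stop("clinical table is not staged; run stage_bp() first", call. = FALSE)
  }
  counts <- table(factor(clinical$bp_code5, levels = 1:5))
  tibble::tibble(bp_code5 = 1:5, n = as.integer(counts))
}
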