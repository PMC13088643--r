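#' Configure the synthetic multiplex-imaging cell generator
#'
#' Emulates segmented-cell marker-intensity tables from cyclic multiplex
#' immunofluorescence of graded tumor regions. Intensities are log-normal;
#' declared markers carry multiplicative, grade-monotone median shifts.
#' A stromal contaminant fraction (high collagen, low cancer marker) is
#' included so the default cancer gate has something to remove.
#'
#' @param markers marker names; must include the gating markers `MUC1` and
#'   `CollagenI` when the default gates are to be used.
#' @param n_cells named counts per grade group (`G1-2`, `G2`, `G2-3`),
#'   defaults scaled down ~10x from a realistic graded-region census.
#' @param base_median baseline median intensity per marker (named, recycled).
#' @param sdlog log-scale SD of intensities.
#' @param grade_shifts named list: marker -> numeric vector of multiplicative
#'   median shifts per grade (names = grade groups). Unlisted markers have no
#'   planted shift.
#' @param stroma_fraction fraction of stromal (non-cancer) cells per grade.
#' @param n_patients patients the cells are spread over.
#' @param seed integer seed.
#' @return a `multiplex_config` list.
#' @export
multiplex_config <- function(markers = c("MUC1", "CollagenI", "GLUT1", "LDHA", "MLPH"),
                             n_cells = c(`G1-2` = 400L, `G2` = 1600L, `G2-3` = 300L),
                             base_median = c(MUC1 = 150, CollagenI = 120,
                                             GLUT1 = 80, LDHA = 80, MLPH = 60),
                             sdlog = 0.5,
                             grade_shifts = list(
                               GLUT1 = c(`G1-2` = 1, `G2` = 1.5, `G2-3` = 2),
                               LDHA  = c(`G1-2` = 1, `G2` = 1.3, `G2-3` = 1.7)),
                             stroma_fraction = 0.25,
                             n_patients = 3L,
                             seed = 0L) {
  grades <- c("G1-2", "G2", "G2-3")
  if (!all(names(n_cells) %in% grades)) stopf("grade groups must be %s", paste(grades, collapse = ", "))
  bm <- rep_len(unname(base_median), length(markers))
  if (!is.null(names(base_median))) {
    bm <- base_median[markers]
    if (anyNA(bm)) stopf("base_median missing for markers: %s",
                         paste(markers[is.na(bm)], collapse = ", "))
  }
  if (any(bm <= 0)) stopf("intensity scales must be positive")
  if (sdlog <= 0) stopf("intensity scales must be positive")
  for (m in names(grade_shifts)) {
    if (!m %in% markers) stopf("grade_shifts names a marker not in `markers`: %s", m)
    if (any(grade_shifts[[m]] <= 0)) stopf("grade shifts must be positive")
  }
  structure(list(markers = markers, n_cells = n_cells,
                 base_median = setNames(as.numeric(bm), markers),
                 sdlog = check_positive(sdlog, "sdlog"),
                 grade_shifts = grade_shifts,
                 stroma_fraction = check_fraction(stroma_fraction, "stroma_fraction"),
                 n_patients = check_count(n_patients, "n_patients"),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "multiplex_config")
}

#' Generate synthetic segmented-cell marker intensities with graded shifts
#'
#' @param config a [multiplex_config()].
#' @return list with `cells` (a `cell_table` data.frame: cell_id, one column
#'   per marker, region_grade, patient_id, is_cancer) and `truth` (planted
#'   shift map and expected medians per marker and grade).
#' @export
generate_multiplex_cells <- function(config) {
  stopifnot(inherits(config, "multiplex_config"))
  set.seed(derive_seed(config$seed, 41L))
  rows <- list()
  expected_median <- list()
  for (g in names(config$n_cells)) {
    n <- config$n_cells[[g]]
    n_str <- round(n * config$stroma_fraction)
    n_can <- n - n_str
    intens <- matrix(0, nrow = n, ncol = length(config$markers),
                     dimnames = list(NULL, config$markers))
    for (m in config$markers) {
      shift <- 1
      if (m %in% names(config$grade_shifts)) {
        sh <- config$grade_shifts[[m]]
        if (g %in% names(sh)) shift <- sh[[g]]
      }
      med <- config$base_median[[m]] * shift
      # cancer cells
      intens[seq_len(n_can), m] <- rlnorm(n_can, meanlog = log(med), sdlog = config$sdlog)
      # stromal cells: collagen-high, cancer-marker-low
      med_str <- switch(m, CollagenI = 1500, MUC1 = 15, config$base_median[[m]])
      if (n_str > 0)
        intens[n_can + seq_len(n_str), m] <-
          rlnorm(n_str, meanlog = log(med_str), sdlog = config$sdlog)
      expected_median[[paste(m, g, sep = "|")]] <- med
    }
    rows[[g]] <- data.frame(
      region_grade = g, is_cancer = rep(c(TRUE, FALSE), c(n_can, n_str)),
      intens, check.names = FALSE, stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, rows)
  cells$cell_id <- sprintf("c%06d", seq_len(nrow(cells)))
  cells$patient_id <- sprintf("P%02d", 1 + (seq_len(nrow(cells)) %% config$n_patients))
  rownames(cells) <- NULL
  cells <- cells[, c("cell_id", config$markers, "region_grade", "patient_id", "is_cancer")]
  class(cells) <- c("cell_table", "data.frame")
  truth <- list(grade_shifts = config$grade_shifts,
                expected_median = unlist(expected_median))
  list(cells = cells, truth = truth)
}
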