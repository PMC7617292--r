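#' Write a trial dataset as a wide CSV
#'
#' Documented wide schema: `id`, `arm`, `bdi_m0` ... `bdi_m24`,
#' `ffmq_pre`, `ffmq_post`, `delta_ffmq`, the indicator columns,
#' `suicide_attempt`, `qol`, `practice_level`, `adm_discontinued`,
#' `true_class` (simulation only). Missing cells are written empty.
#'
#' @param dataset a `trial_dataset` data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a wide trial CSV
#'
#' Maps blank, `NA` and `NaN` cells to a single missing sentinel (`NA`),
#' checks the documented ranges (BDI-II in 0-63 where observed, arm in
#' {0, 1}), recomputes `delta_ffmq` when both FFMQ scores are observed,
#' and attaches an ingest report (missing counts per column).
#'
#' @param path CSV file with the wide schema of [write_trial_csv()].
#' @param manifest optional list with `continuous` / `binary` character
#'   vectors naming the profile indicator columns; stored as an attribute
#'   for downstream stages.
#' @return a `trial_dataset` data.frame with attributes `ingest_report`
#'   and (optionally) `manifest`.
#' @export
read_trial_csv <- function(path, manifest = NULL) {
  dat <- utils::read.csv(path, na.strings = c("", "NA", "NaN", "nan"),
                         stringsAsFactors = FALSE)
  mandatory <- c("id", "arm", bdi_columns())
  missing_cols <- setdiff(mandatory, names(dat))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_arm <- which(!(dat$arm %in% c(0, 1)))
  if (length(bad_arm) > 0L) {
    stop("`arm` must be 0/1; offending rows: ",
         paste(utils::head(bad_arm, 10L), collapse = ", "), call. = FALSE)
  }
  for (cl in bdi_columns()) {
    bad <- which(!is.na(dat[[cl]]) & (dat[[cl]] < 0 | dat[[cl]] > 63))
    if (length(bad) > 0L) {
      stop("column ", cl, " outside the BDI-II range 0-63; rows: ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
  }
  if (all(c("ffmq_pre", "ffmq_post") %in% names(dat))) {
    dat$delta_ffmq <- dat$ffmq_post - dat$ffmq_pre
  }
  report <- data.frame(column = names(dat),
                       n_missing = vapply(dat, function(v) sum(is.na(v)),
                                          integer(1L)),
                       row.names = NULL)
  class(dat) <- c("trial_dataset", "data.frame")
  attr(dat, "ingest_report") <- report
  if (!is.null(manifest)) attr(dat, "manifest") <- manifest
  dat
}

#' Write / read a simulation configuration as a flat key-value file
#'
#' Scalars and numeric vectors (comma-separated) are written one `key = value`
#' per line; the indicator battery and matrix-valued entries are flattened
#' with documented row-major keys.
#'
#' @param config a [sim_config()].
#' @param path text file path.
#' @return `write_sim_config()` the path invisibly; `read_sim_config()` a
#'   `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  num <- function(x) paste(format(x, digits = 15, trim = TRUE), collapse = ",")
  lines <- c(
    paste0("n = ", config$n),
    paste0("pi2 = ", num(config$pi2)),
    paste0("binary_probs = ", num(config$binary_probs)),
    paste0("alpha0_g = ", num(config$alpha0_g)),
    paste0("alpha1 = ", num(config$alpha1)),
    paste0("alpha2 = ", num(config$alpha2)),
    paste0("psi = ", num(as.vector(config$psi))),
    paste0("a0_g = ", num(config$a0_g)),
    paste0("a_g = ", num(config$a_g)),
    paste0("sigma_m = ", num(config$sigma_m)),
    paste0("b_g = ", num(config$b_g)),
    paste0("cprime_g = ", num(config$cprime_g)),
    paste0("sigma_slope = ", num(config$sigma_slope)),
    paste0("theta_t = ", num(config$theta_t)),
    paste0("rho = ", num(config$rho)),
    paste0("retention_t = ", num(config$retention_t)),
    paste0("retention_ffmq = ", num(config$retention_ffmq)),
    paste0("mar_arm = ", num(config$mar_arm)),
    paste0("mar_bdi = ", num(config$mar_bdi)),
    paste0("ffmq_pre_mean_g = ", num(config$ffmq_pre_mean_g)),
    paste0("ffmq_pre_sd = ", num(config$ffmq_pre_sd)),
    paste0("qol_mean_g = ", num(config$qol_mean_g)),
    paste0("qol_sd = ", num(config$qol_sd)),
    paste0("practice_probs = ", num(as.vector(config$practice_probs))),
    paste0("adm_disc_prob = ", num(config$adm_disc_prob)),
    paste0("seed = ", config$seed),
    paste0("indicator_names = ", paste(config$indicators$name, collapse = ",")),
    paste0("indicator_means1 = ", num(config$indicators$mean1)),
    paste0("indicator_means2 = ", num(config$indicators$mean2)),
    paste0("indicator_sds = ", num(config$indicators$sd)),
    paste0("indicator_lower = ", num(config$indicators$lower)),
    paste0("indicator_upper = ", num(config$indicators$upper)),
    paste0("indicator_integer = ",
           paste(config$indicators$integer, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1L), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                        character(1L)))
  names(vals) <- keys
  numv <- function(k) {
    x <- trimws(strsplit(vals[[k]], ",")[[1L]])
    x[x %in% c("NA", "NaN")] <- NA
    as.numeric(x)
  }
  ind <- data.frame(
    name = strsplit(vals[["indicator_names"]], ",")[[1L]],
    mean1 = numv("indicator_means1"), mean2 = numv("indicator_means2"),
    sd = numv("indicator_sds"), lower = numv("indicator_lower"),
    upper = numv("indicator_upper"),
    integer = as.logical(strsplit(vals[["indicator_integer"]], ",")[[1L]]),
    stringsAsFactors = FALSE)
  sim_config(
    n = numv("n"), pi2 = numv("pi2"), indicators = ind,
    binary_probs = numv("binary_probs"), alpha0_g = numv("alpha0_g"),
    alpha1 = numv("alpha1"), alpha2 = numv("alpha2"),
    psi = matrix(numv("psi"), 3L, 3L), a0_g = numv("a0_g"),
    a_g = numv("a_g"), sigma_m = numv("sigma_m"), b_g = numv("b_g"),
    cprime_g = numv("cprime_g"), sigma_slope = numv("sigma_slope"),
    theta_t = numv("theta_t"), rho = numv("rho"),
    retention_t = numv("retention_t"),
    retention_ffmq = numv("retention_ffmq"), mar_arm = numv("mar_arm"),
    mar_bdi = numv("mar_bdi"), ffmq_pre_mean_g = numv("ffmq_pre_mean_g"),
    ffmq_pre_sd = numv("ffmq_pre_sd"), qol_mean_g = numv("qol_mean_g"),
    qol_sd = numv("qol_sd"),
    practice_probs = matrix(numv("practice_probs"), 2L, 4L),
    adm_disc_prob = numv("adm_disc_prob"), seed = numv("seed"))
}

#' BDI-II severity band
#'
#' Standard interpretive bands of the BDI-II total score: 0-13 minimal,
#' 14-19 mild, 20-28 moderate, 29-63 severe.
#'
#' @param score integer-valued score(s) in 0-63 (`NA` passed through).
#' @return character vector of band labels.
#' @examples
#' classify_bdi(c(13, 14, 29))
#' @export
classify_bdi <- function(score) {
  ok <- is.na(score) | (score >= 0 & score <= 63 & score == round(score))
  if (!all(ok)) {
    stop("scores must be integers in 0-63; offending values: ",
         paste(utils::head(score[!ok], 5L), collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score <= 13] <- "minimal"
  out[!is.na(score) & score >= 14 & score <= 19] <- "mild"
  out[!is.na(score) & score >= 20 & score <= 28] <- "moderate"
  out[!is.na(score) & score >= 29] <- "severe"
  out
}
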