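#' Percentile bootstrap for the moderated-mediation model
#'
#' Nonparametric case resampling of participants, stratified by trial arm
#' (stratum sizes preserved), each draw refitting [fit_medmod()] with the
#' point estimate as warm start and the moderator labels held fixed per
#' resampled case. Records the a-paths, b, c', conditional indirect
#' effects, the index of moderated mediation and the a-path contrast, and
#' forms percentile 2.5/97.5 bounds as order statistics of the draws.
#' Failed draws are dropped and counted; more than 10% failures aborts.
#' Fully reproducible given the seed.
#'
#' @param dataset wide trial dataset.
#' @param labels moderator group labels per row.
#' @param spec a [medmod_spec()]; `spec$B` and `spec$seed` are used unless
#'   overridden.
#' @param B draw count (>= 200 recommended for reporting; a warning is
#'   issued below 1000).
#' @param seed RNG seed.
#' @param fit optional pre-computed full-sample fit (avoids refitting).
#' @return object of class `medmod_boot`: `B`, `seed`, draw matrix, CI
#'   table with significance flags (`0` outside the interval), failed-draw
#'   count, and the point estimates.
#' @export
bootstrap_medmod <- function(dataset, labels, spec = medmod_spec(),
                             B = spec$B, seed = spec$seed, fit = NULL) {
  stopifnot(B >= 1L)
  if (B < 1000L) {
    warning("fewer than 1000 bootstrap draws; intervals may be unstable",
            call. = FALSE)
  }
  if (is.null(fit)) {
    fit <- fit_medmod(dataset, labels, spec, hessian = FALSE)
  }
  G <- fit$G
  stat_names <- c(paste0("a_", seq_len(G)), paste0("b_", seq_len(G)),
                  paste0("cprime_", seq_len(G)), paste0("ie_", seq_len(G)),
                  if (G == 2L) c("a_diff", "index"))
  stat_fun <- function(f) {
    v <- c(f$a, f$b, f$cprime, f$ie)
    if (G == 2L) v <- c(v, f$a[2L] - f$a[1L], f$index)
    setNames(v, stat_names)
  }
  point <- stat_fun(fit)

  n <- nrow(dataset)
  arm <- dataset[[spec$exposure]]
  strata <- if (isTRUE(spec$stratify)) split(seq_len(n), arm) else
    list(seq_len(n))
  draws <- matrix(NA_real_, B, length(stat_names),
                  dimnames = list(NULL, stat_names))
  n_failed <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- unlist(lapply(strata, function(s) {
        s[sample.int(length(s), length(s), replace = TRUE)]
      }), use.names = FALSE)
      res <- tryCatch(
        fit_medmod(dataset[idx, , drop = FALSE], labels[idx], spec,
                   start = fit$packed, hessian = FALSE),
        error = function(e) NULL)
      if (is.null(res)) {
        n_failed <- n_failed + 1L
      } else {
        draws[b, ] <- stat_fun(res)
      }
    }
  })
  if (n_failed > 0.10 * B) {
    stop("more than 10% of bootstrap draws failed (", n_failed, " of ", B,
         ")", call. = FALSE)
  }
  ci <- t(apply(draws, 2L, percentile_ci))
  tab <- data.frame(term = stat_names, estimate = point,
                    lower = ci[, "lower"], upper = ci[, "upper"],
                    row.names = NULL)
  tab$significant <- !(tab$lower <= 0 & tab$upper >= 0)
  structure(list(B = B, seed = seed, draws = draws, ci = tab,
                 n_failed = n_failed, point = point),
            class = "medmod_boot")
}

#' @export
print.medmod_boot <- function(x, ...) {
  cat("Percentile bootstrap, B =", x$B, "(", x$n_failed, "failed draws )\n")
  print(x$ci, digits = 4)
  invisible(x)
}
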