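#' Configuration for the full analysis pipeline
#'
#' Exactly one of `input` (path to a wide trial CSV) or `sim` (a
#' [sim_config()]) must be supplied. The seed governs every stochastic
#' stage (LPA starts, optimiser jitter, bootstrap).
#'
#' @param input path to a wide CSV, or `NULL` to simulate.
#' @param sim a [sim_config()], or `NULL` to read from `input`.
#' @param manifest list with `continuous` / `binary` indicator column
#'   names; defaults to the battery of [default_indicators()].
#' @param k_max largest profile count for model selection.
#' @param K profile count carried into the structural stage.
#' @param boot_draws bootstrap draw count.
#' @param covariates sensitivity-adjustment covariates.
#' @param out_dir output directory (created if absent).
#' @param seed mandatory integer seed.
#' @param verbose logical; log stage progress to the console (a run log
#'   file is always written).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = NULL,
                            manifest = list(
                              continuous = default_indicators()$name,
                              binary = "suicide_attempt"),
                            k_max = 3L, K = 2L, boot_draws = 1000L,
                            covariates = c("practice_level",
                                           "adm_discontinued"),
                            out_dir = "modmedgrowth-run", seed = NULL,
                            verbose = TRUE) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.null(input) == is.null(sim)) {
    stop("supply exactly one of `input` or `sim`", call. = FALSE)
  }
  structure(list(input = input, sim = sim, manifest = manifest,
                 k_max = as.integer(k_max), K = as.integer(K),
                 boot_draws = as.integer(boot_draws),
                 covariates = covariates, out_dir = out_dir,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

pipe_log <- function(state, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [", state$stage, "] ", ...)
  cat(msg, "\n", file = state$logfile, append = TRUE)
  if (state$verbose) message(msg)
  invisible(NULL)
}

write_table <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate or read the dataset; profile enumeration
#' ([select_profiles()]) and the K-profile fit; growth-model comparison
#' over the intercept-only, linear and quadratic shapes (all with
#' heteroscedastic-AR residuals); the moderated-mediation fit with
#' moderation tests, the constrained final model, total effect and
#' percentile bootstrap; and a covariate-adjusted sensitivity rerun.
#' Writes the dataset, selection and parameter tables, a Table-2-shaped
#' mediation summary, a descriptive severity-band report, a z-score
#' profile figure (when ggplot2 is available) and a JSON manifest with
#' seeds, draw counts, convergence codes and timings. Any stage failure
#' aborts with the stage name; partial outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @return result bundle (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(stage = "init",
                logfile = file.path(config$out_dir, "run.log"),
                verbose = config$verbose)
  cat("", file = state$logfile)
  manifest <- list(seed = config$seed, package = "modmedgrowth",
                   version = as.character(utils::packageVersion("modmedgrowth")),
                   stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    state$stage <<- name
    pipe_log(state, "start")
    ts <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - ts, 3))
    pipe_log(state, "done")
    out
  }

  dat <- stage("data", {
    if (!is.null(config$sim)) {
      d <- simulate_trial(config$sim)
      write_sim_config(config$sim, file.path(config$out_dir, "sim_config.txt"))
      write_trial_csv(d, file.path(config$out_dir, "dataset.csv"))
      d
    } else {
      read_trial_csv(config$input, manifest = config$manifest)
    }
  })
  ind_cols <- c(config$manifest$continuous, config$manifest$binary)
  ind_cols <- intersect(ind_cols, names(dat))
  indicators <- dat[ind_cols]

  descr <- stage("descriptives", {
    bands <- classify_bdi(dat$bdi_m0)
    tab <- as.data.frame(table(band = factor(
      bands, levels = c("minimal", "mild", "moderate", "severe")),
      useNA = "no"))
    names(tab) <- c("baseline_band", "n")
    tab$fraction <- tab$n / sum(tab$n)
    write_table(tab, config$out_dir, "descriptives_bdi_bands.csv")
    tab
  })

  lpa <- stage("profiles", {
    sel <- select_profiles(indicators, config$k_max,
                           binary = config$manifest$binary,
                           seed = config$seed)
    write_table(sel, config$out_dir, "profile_selection.csv")
    fit <- attr(sel, "fits")[[config$K]]
    if (is.null(fit)) {
      fit <- fit_lpa(indicators, config$K, binary = config$manifest$binary,
                     seed = config$seed)
    }
    zs <- profile_zscores(fit, indicators)
    write_table(zs, config$out_dir, "profile_zscores.csv")
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      p <- plot_profile_zscores(zs)
      ggplot2::ggsave(file.path(config$out_dir, "profile_zscores.png"), p,
                      width = 9, height = 4.5, dpi = 150)
    }
    labels <- modal_assignment(fit$posteriors)
    distal <- if ("qol" %in% names(dat)) {
      d <- compare_distal(dat, labels, "qol")
      write_table(d, config$out_dir, "profile_distal.csv")
      d
    }
    list(selection = sel, fit = fit, labels = labels, zscores = zs,
         distal = distal)
  })

  growth <- stage("growth", {
    shapes <- c("intercept", "linear", "quadratic")
    fits <- lapply(shapes, function(sh) {
      fit_lgcm(dat, growth_spec(shape = sh), seed = config$seed)
    })
    names(fits) <- shapes
    cmp <- compare_growth_models(fits)
    write_table(cmp, config$out_dir, "growth_comparison.csv")
    best <- fits[[which.min(cmp$bic)]]
    pars <- data.frame(parameter = names(best$estimates),
                       estimate = best$estimates, se = best$se,
                       row.names = NULL)
    write_table(pars, config$out_dir, "growth_parameters.csv")
    list(fits = fits, comparison = cmp, best = best)
  })

  med <- stage("mediation", {
    free_spec <- medmod_spec(b_shared = FALSE, cprime_shared = FALSE,
                             B = config$boot_draws, seed = config$seed)
    free_fit <- fit_medmod(dat, lpa$labels, free_spec, seed = config$seed)
    final_spec <- medmod_spec(B = config$boot_draws, seed = config$seed)
    final_fit <- fit_medmod(dat, lpa$labels, final_spec, seed = config$seed)
    tot <- total_effect(dat, lpa$labels, final_spec, seed = config$seed)
    boot <- suppressWarnings(
      bootstrap_medmod(dat, lpa$labels, final_spec, fit = final_fit))
    tab <- medmod_table(final_fit, free_fit, tot, boot)
    write_table(tab, config$out_dir, "mediation_table.csv")
    list(free_fit = free_fit, fit = final_fit, total = tot, boot = boot,
         table = tab)
  })

  sens <- stage("sensitivity", {
    covs <- intersect(config$covariates, names(dat))
    if (length(covs) == 0L) return(NULL)
    spec <- adjust_covariates(
      medmod_spec(B = config$boot_draws, seed = config$seed + 1L),
      covs, data = dat)
    fit <- fit_medmod(dat, lpa$labels, spec, seed = config$seed)
    boot <- suppressWarnings(
      bootstrap_medmod(dat, lpa$labels, spec, fit = fit))
    tab <- medmod_table(fit, NULL, NULL, boot)
    write_table(tab, config$out_dir, "mediation_sensitivity_table.csv")
    list(fit = fit, boot = boot, table = tab)
  })

  state$stage <- "manifest"
  manifest$boot <- list(B = med$boot$B, seed = med$boot$seed,
                        n_failed = med$boot$n_failed)
  manifest$convergence <- list(
    medmod = med$fit$convergence,
    growth = vapply(growth$fits, function(f) f$convergence, numeric(1L)))
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t0, 3)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log(state, "pipeline complete")

  invisible(list(dataset = dat, descriptives = descr, lpa = lpa,
                 growth = growth, mediation = med, sensitivity = sens,
                 manifest = manifest, out_dir = config$out_dir))
}

# Table-2-shaped summary: paths, moderation contrasts, conditional effects,
# index, total effect, bootstrap bounds and R^2.
medmod_table <- function(fit, free_fit = NULL, total = NULL, boot = NULL) {
  pick <- function(f, term) {
    r <- f$paths[f$paths$term == term, , drop = FALSE]
    if (nrow(r) == 0L) data.frame(estimate = NA_real_, se = NA_real_,
                                  z = NA_real_, p = NA_real_) else
      r[, c("estimate", "se", "z", "p")]
  }
  terms <- c(a_1 = "a_1", a_2 = "a_2", a_diff = "a_diff", b = "b_1",
             cprime = "cprime_1", ie_1 = "ie_1", ie_2 = "ie_2",
             index = "index")
  rows <- lapply(names(terms), function(nm) {
    cbind(data.frame(term = nm), pick(fit, terms[[nm]]))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(free_fit)) {
    extra <- lapply(c(b_moderation = "b_diff",
                      cprime_moderation = "cprime_diff"),
                    function(t) pick(free_fit, t))
    tab <- rbind(tab,
                 cbind(data.frame(term = "b_moderation"), extra[[1L]]),
                 cbind(data.frame(term = "cprime_moderation"), extra[[2L]]))
  }
  if (!is.null(total)) {
    tab <- rbind(tab, data.frame(term = "c_total", estimate = total$c,
                                 se = total$se, z = total$z, p = total$p))
  }
  tab$boot_lower <- tab$boot_upper <- NA_real_
  tab$boot_significant <- NA
  if (!is.null(boot)) {
    map <- c(a_1 = "a_1", a_2 = "a_2", a_diff = "a_diff", b = "b_1",
             cprime = "cprime_1", ie_1 = "ie_1", ie_2 = "ie_2",
             index = "index")
    for (nm in names(map)) {
      r <- boot$ci[boot$ci$term == map[[nm]], , drop = FALSE]
      if (nrow(r) == 1L) {
        tab$boot_lower[tab$term == nm] <- r$lower
        tab$boot_upper[tab$term == nm] <- r$upper
        tab$boot_significant[tab$term == nm] <- r$significant
      }
    }
  }
  r2 <- fit$r2
  for (g in seq_len(nrow(r2))) {
    tab <- rbind(tab, data.frame(
      term = paste0("r2_mediator_", g), estimate = r2$r2_mediator[g],
      se = NA_real_, z = NA_real_, p = NA_real_, boot_lower = NA_real_,
      boot_upper = NA_real_, boot_significant = NA))
    tab <- rbind(tab, data.frame(
      term = paste0("r2_slope_", g), estimate = r2$r2_slope[g],
      se = NA_real_, z = NA_real_, p = NA_real_, boot_lower = NA_real_,
      boot_upper = NA_real_, boot_significant = NA))
  }
  rownames(tab) <- NULL
  tab
}
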