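# Readers/writers, validation, seeding helpers and the staged pipeline.
# Trial data live in a flat CSV: participant_id,group,phase,bout,
# obstacle_index,height_class,fc_observed (meters, decimal point, missing =
# empty field). Posterior draws are persisted as plain CSV plus a JSON
# metadata sidecar for portability.

TRIAL_COLUMNS <- c("participant_id", "group", "phase", "bout",
                   "obstacle_index", "height_class", "fc_observed")

# Internal: validate a trial table; reports offending rows by number.
validate_trials <- function(trials) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss)) stop("trial table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!trials$height_class %in% HEIGHT_CLASSES)
  if (length(bad)) stop("unknown height_class at row(s): ",
                        paste(head(bad, 5), collapse = ", "))
  bad <- which(!trials$phase %in% PHASES)
  if (length(bad)) stop("unknown phase at row(s): ",
                        paste(head(bad, 5), collapse = ", "))
  bad <- which(!trials$group %in% GROUPS)
  if (length(bad)) stop("unknown group at row(s): ",
                        paste(head(bad, 5), collapse = ", "))
  bad <- which(!is.na(trials$fc_observed) & trials$fc_observed < 0)
  if (length(bad)) stop("negative fc_observed at row(s): ",
                        paste(head(bad, 5), collapse = ", "))
  key <- paste(trials$participant_id, trials$phase, trials$obstacle_index)
  bad <- which(duplicated(key))
  if (length(bad)) stop("duplicate (participant, phase, obstacle_index) ",
                        "at row(s): ", paste(head(bad, 5), collapse = ", "))
  invisible(trials)
}

#' Read a trial-record CSV
#'
#' Expects the schema `participant_id,group,phase,bout,obstacle_index,
#' height_class,fc_observed` (clearances in meters; empty field = missing
#' observation). Schema violations are reported with row numbers.
#'
#' @param path CSV file path.
#' @return Validated trial `data.frame`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- read.csv(path, stringsAsFactors = FALSE)
  if ("fc_observed" %in% names(tr))
    tr$fc_observed <- as.numeric(tr$fc_observed)
  validate_trials(tr)
  tr
}

#' Write a trial-record CSV
#'
#' @param trials Trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export posterior draws to CSV (+ JSON metadata sidecar)
#'
#' @param fit A `loco_fit`.
#' @param path Output CSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path) {
  stopifnot(inherits(fit, "loco_fit"))
  m <- posterior_matrix(fit)
  n_keep <- dim(fit$draws)[1]
  out <- data.frame(chain = rep(seq_len(dim(fit$draws)[2]), each = n_keep),
                    draw = rep(seq_len(n_keep), dim(fit$draws)[2]),
                    m, check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  meta <- list(model = fit$model, variant = fit$variant,
               include_no_feedback = fit$include_no_feedback,
               group_levels = fit$group_levels,
               participants = fit$participants, mcmc = fit$mcmc,
               data_hash = fit$data_hash)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read posterior draws written by [write_posterior()]
#'
#' Restores the draws array and metadata (not the fitted data, so
#' WAIC/pointwise recomputation is not available on the restored object).
#'
#' @param path CSV path.
#' @return A `loco_fit`-like list (class `loco_fit_export`).
#' @export
read_posterior <- function(path) {
  m <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  chains <- sort(unique(m$chain))
  pars <- setdiff(names(m), c("chain", "draw"))
  n_keep <- sum(m$chain == chains[1])
  draws <- array(NA_real_, c(n_keep, length(chains), length(pars)),
                 dimnames = list(NULL, paste0("chain", chains), pars))
  for (ch in seq_along(chains))
    draws[, ch, ] <- as.matrix(m[m$chain == chains[ch], pars])
  structure(list(draws = draws, participants = meta$participants,
                 group_levels = meta$group_levels, model = meta$model,
                 variant = meta$variant, mcmc = meta$mcmc,
                 data_hash = meta$data_hash),
            class = c("loco_fit_export", "loco_fit"))
}

# Internal: FNV-1a hash of an R object (via its serialized bytes), as hex.
fnv1a_hash <- function(x) {
  fnv1a_cpp(serialize(x, NULL, version = 2))
}

#' Run the full synthetic-study pipeline
#'
#' Stages: `cohort` (generate synthetic trials + ground truth), `fit`
#' (hierarchical Bayesian estimation), `diagnose` (R-hat table), `test`
#' (group contrasts: probability of direction and ROPE), `metrics`
#' (behavioral summaries and association regressions). Later stages depend
#' on earlier ones; disabling a dependency is an error. All artifacts and a
#' manifest (stage list, seeds, config hash) are written to `out_dir`.
#'
#' @param config List with optional elements `design` ([cohort_design()]
#'   arguments), `populations` (`control` / `pd` [population_params()]
#'   arguments), `model`, `variant`, `mcmc` (chains, iter, burn_in, thin)
#'   and `stages` (character subset of
#'   `c("cohort","fit","diagnose","test","metrics")`).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every stochastic stage derives its seed from it
#'   and records it in the manifest.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  stages <- config$stages %||% c("cohort", "fit", "diagnose", "test",
                                 "metrics")
  deps <- list(fit = "cohort", diagnose = "fit", test = "fit",
               metrics = "fit")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !need %in% stages)
      stop("stage '", s, "' requires stage '", need, "' to be enabled")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 2)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("locolearn")),
                   master_seed = seed, stages = list(),
                   config_hash = fnv1a_hash(config))
  msg <- function(stage, ...) message("[", stage, "] ", ...)

  design <- do.call(cohort_design, config$design %||% list())
  pops <- list(
    control = do.call(population_params,
                      c(list(group = "CONTROL"),
                        config$populations$control %||% list())),
    pd = do.call(population_params,
                 c(list(group = "PD"), config$populations$pd %||% list())))

  cohort <- NULL; fit <- NULL
  if ("cohort" %in% stages) {
    msg("cohort", "generating synthetic cohort (seed ", seeds[1], ")")
    cohort <- generate_cohort(pops$control, pops$pd, design,
                              seed = seeds[1],
                              variant = config$variant %||% "dot")
    write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
    write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
              row.names = FALSE)
    manifest$stages$cohort <- list(seed = seeds[1],
                                   n_participants = nrow(cohort$truth))
  }
  if ("fit" %in% stages) {
    mc <- config$mcmc %||% list()
    msg("fit", "running MCMC (seed ", seeds[2], ")")
    fit <- loco_fit(cohort$trials,
                    model = config$model %||% "full",
                    variant = config$variant %||% "dot",
                    chains = mc$chains %||% 3,
                    iter = mc$iter %||% 20000,
                    burn_in = mc$burn_in %||% 10000,
                    thin = mc$thin %||% 10,
                    seed = seeds[2])
    write_posterior(fit, file.path(out_dir, "posterior.csv"))
    manifest$stages$fit <- list(seed = seeds[2], model = fit$model,
                                n_retained = fit$mcmc$n_retained)
  }
  if ("diagnose" %in% stages) {
    msg("diagnose", "computing R-hat diagnostics")
    dg <- diagnose(fit)
    write.csv(dg, file.path(out_dir, "diagnostics.csv"), row.names = FALSE)
    manifest$stages$diagnose <- list(converged = attr(dg, "converged"),
                                     max_rhat = max(dg$rhat, na.rm = TRUE))
  }
  if ("test" %in% stages) {
    msg("test", "group contrasts (pd, ROPE)")
    report <- lapply(c(learning_rate = "learning_rate",
                       interference = "interference"), function(p) {
      ct <- group_contrast(fit, p)
      ct[c("parameter", "groups", "pd", "direction", "diff_summary",
           "rope")]
    })
    jsonlite::write_json(report, file.path(out_dir, "contrasts.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$test <- list(
      pd_learning_rate = report$learning_rate$pd,
      pd_interference = report$interference$pd)
  }
  if ("metrics" %in% stages) {
    msg("metrics", "behavioral summaries and association models")
    summ <- summarize_cohort(cohort$trials, cohort$specs, fit)
    write.csv(summ, file.path(out_dir, "summaries.csv"), row.names = FALSE)
    assoc <- association_models(summ)
    jsonlite::write_json(assoc, file.path(out_dir, "associations.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$metrics <- list(n = nrow(summ))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
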