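# End-to-end orchestration: simulate -> fit norms -> score -> equivalence ->
# reliability -> diagnostics, with every artifact stamped with the package
# version, the master seed and a hash of the configuration.

.pipeline_meta <- function(config_path, seed) {
  list(tool = jsonlite::unbox("tvfb"),
       version = jsonlite::unbox(as.character(utils::packageVersion("tvfb"))),
       seed = jsonlite::unbox(as.integer(seed)),
       config_md5 = jsonlite::unbox(unname(tools::md5sum(config_path))))
}

#' Run the full standardization pipeline
#'
#' Generates a normative cohort plus its replicate subsamples from the
#' configuration, fits an adjustment equation and derives a norm card for
#' each of the 13 measures, classifies every subject, runs the paired TOST
#' equivalence analysis on the telephone/in-person subsample, computes
#' reliability (inter-rater and test-retest ICC, internal consistency,
#' component structure) and diagnostics (ROC of adjusted scores against a
#' shifted clinical cohort), and writes the artifacts to `out_dir`:
#' `cohort.csv`, `norm_cards.json`, `scored.csv` and `report.json`. All
#' randomness flows from the single master `seed` through fixed per-stage
#' substreams, so the same `(config, seed)` yields byte-identical outputs.
#'
#' @param config_path Path to a simulation-config JSON
#'   (default: the packaged configuration).
#' @param out_dir Output directory (created if absent).
#' @param seed Master integer seed.
#' @param selection_alpha Stepwise entry/stay threshold for norm fitting.
#' @param dz,tost_alpha Paired-TOST equivalence half-width and level.
#' @return Invisibly, the report bundle as a list.
#' @export
run_pipeline <- function(config_path = NULL, out_dir, seed = 1,
                         selection_alpha = 0.05, dz = 0.5,
                         tost_alpha = 0.05) {
  if (is.null(config_path)) {
    config_path <- system.file("extdata", "default_sim_config.json",
                               package = "tvfb")
  }
  config <- default_sim_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- .pipeline_meta(config_path, seed)

  # -- simulate -------------------------------------------------------------
  cohort <- generate_normative(config, seed = .sub_seed(seed, 1L))
  validate_cohort(cohort)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  # -- fit norms and score --------------------------------------------------
  cards <- list()
  scored <- cohort
  for (m in measure_names()) {
    eq <- fit_adjustment(cohort, m, selection_alpha = selection_alpha)
    adj <- adjust_cohort(cohort, eq)
    card <- derive_norm_card(adj, equation = eq)
    cards[[m]] <- card
    scored[[paste0(m, "_adj")]] <- adj
    scored[[paste0(m, "_es")]] <- unname(classify_es(card, adj))
  }
  write_norm_cards(cards, file.path(out_dir, "norm_cards.json"))
  write_cohort(scored, file.path(out_dir, "scored.csv"))

  # -- equivalence (telephone vs in-person subsample, drawn at random) ------
  idx <- .with_seed(.sub_seed(seed, 6L),
                    sample(nrow(cohort), min(config$paired$n, nrow(cohort))))
  paired <- generate_paired_modality(cohort[idx, ],
                                     rho = config$paired$rho,
                                     delta = config$paired$delta,
                                     seed = .sub_seed(seed, 2L))
  equivalence <- lapply(c("pvf", "svf", "avf", "csi"), function(m) {
    res <- tost_paired(paired[[m]] - paired[[paste0(m, "_ip")]],
                       dz = dz, alpha = tost_alpha)
    c(list(measure = jsonlite::unbox(m)),
      lapply(res[c("n", "mean_diff", "sd_diff", "t_nhst", "p_nhst",
                   "p_lower", "p_upper", "p_tost", "equivalent")],
             jsonlite::unbox))
  })

  # -- reliability (random subsamples, as in the study design) --------------
  rt_idx <- .with_seed(.sub_seed(seed, 7L),
                       sample(nrow(cohort), min(config$retest$n, nrow(cohort))))
  retest <- generate_retest(cohort[rt_idx, ], rho = config$retest$rho,
                            seed = .sub_seed(seed, 3L))
  rr_idx <- .with_seed(.sub_seed(seed, 8L),
                       sample(nrow(cohort), min(config$raters$n, nrow(cohort))))
  rated <- generate_ratings(cohort[rr_idx, ],
                            disagreement_rate = config$raters$disagreement_rate,
                            seed = .sub_seed(seed, 4L))
  icc_tbl <- lapply(c("pvf", "svf", "avf"), function(m) {
    list(measure = jsonlite::unbox(m),
         test_retest = jsonlite::unbox(
           icc(retest[c(m, paste0(m, "_rt"))], model = "consistency")$icc),
         inter_rater = jsonlite::unbox(
           icc(rated[c(m, paste0(m, "_r2"))], model = "absolute")$icc))
  })
  adj_trials <- scored[paste0(trial_names(), "_adj")]
  pca <- pca_structure(adj_trials)
  reliability <- list(
    icc = icc_tbl,
    cronbach_alpha = jsonlite::unbox(cronbach_alpha(adj_trials)),
    pca_components = jsonlite::unbox(pca$n_retained),
    pca_explained = jsonlite::unbox(pca$explained_retained))

  # -- diagnostics (clinical vs normative, adjusted scores) -----------------
  clinical <- generate_clinical(config, seed = .sub_seed(seed, 5L))
  diagnostics <- lapply(c("pvf", "svf", "avf"), function(m) {
    roc <- roc_auc(adjust_cohort(clinical, cards[[m]]$equation),
                   scored[[paste0(m, "_adj")]], direction = "lower")
    list(measure = jsonlite::unbox(m), auc = jsonlite::unbox(roc$auc),
         se = jsonlite::unbox(roc$se), ci = roc$ci)
  })

  report <- list(meta = meta, equivalence = equivalence,
                 reliability = reliability, diagnostics = diagnostics)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, cards = cards, scored = scored,
                 paired = paired, report = report))
}
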