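#' Run the channel-reduction study over a case grid
#'
#' For every scenario appearing in `cases`, builds the scenario segment
#' pool, performs the stratified 80/20 train/test split, and runs each
#' case through k-fold cross-validation ([run_cv_case()]). Cases listed
#' in `finalize` are additionally retrained on the full training pool and
#' scored on the held-out test segments ([finalize_case()]).
#'
#' @param segments Preprocessed all-task [segment_set()] (8 channels).
#' @param cases Data frame of cases (default: the full grid from
#'   [enumerate_cases()]).
#' @param tc A [train_config()].
#' @param seed Master seed; scenario splits and case runs derive child
#'   seeds from it, so the whole study is reproducible.
#' @param train_fraction,k Split and fold settings.
#' @param finalize Integer vector of `case_id`s to finalize (empty for
#'   none).
#' @param verbose Print progress per case.
#' @return List with `results` (tidy data frame: one row per case x fold
#'   plus `mean` and `sd` aggregate rows), `cv` (list of `cv_result`),
#'   and `final` (list of finalization results keyed by case id).
#' @export
run_study <- function(segments, cases = enumerate_cases(),
                      tc = train_config(), seed = 1,
                      train_fraction = 0.8, k = 5, finalize = integer(0),
                      verbose = FALSE) {
  scen <- unique(cases$scenario)
  scen_seeds <- derive_seeds(seed, length(scenario_levels))
  names(scen_seeds) <- scenario_levels
  pools <- list()
  for (s in scen) {
    pool <- build_scenario(segments, s)
    pools[[s]] <- split_dataset(pool, train_fraction, scen_seeds[[s]])
  }
  case_seeds <- derive_seeds(seed + 1L, max(cases$case_id))
  rows <- list()
  cvs <- list()
  finals <- list()
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    if (verbose)
      message(sprintf("case %d: variant %s / %s / %s", case$case_id,
                      case$variant, case$scenario, case$regions))
    cv <- run_cv_case(case, pools[[case$scenario]]$train, tc, k,
                      case_seeds[case$case_id])
    cvs[[as.character(case$case_id)]] <- cv
    fold_tab <- do.call(rbind, lapply(cv$per_fold, metrics_vector))
    for (f in seq_len(k))
      rows[[length(rows) + 1L]] <- cbind(
        case[, c("case_id", "variant", "scenario", "regions")],
        fold = as.character(f), as.data.frame(t(fold_tab[f, ])))
    rows[[length(rows) + 1L]] <- cbind(
      case[, c("case_id", "variant", "scenario", "regions")],
      fold = "mean", as.data.frame(t(cv$mean)))
    rows[[length(rows) + 1L]] <- cbind(
      case[, c("case_id", "variant", "scenario", "regions")],
      fold = "sd", as.data.frame(t(cv$sd)))
    if (case$case_id %in% finalize) {
      fin <- finalize_case(case, pools[[case$scenario]]$train,
                           pools[[case$scenario]]$test, tc,
                           case_seeds[case$case_id])
      finals[[as.character(case$case_id)]] <- fin
      rows[[length(rows) + 1L]] <- cbind(
        case[, c("case_id", "variant", "scenario", "regions")],
        fold = "test", as.data.frame(t(metrics_vector(fin$metrics))))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, cv = cvs, final = finals)
}
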