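#' Corpus-level evaluation: reliability, consistency, accuracy
#'
#' Runs the full pipeline on every recording of a corpus and aggregates the
#' three evaluation criteria per (fit family x signal variant x VOT
#' definition): *reliability*, the percentage of recordings for which the
#' VOT is computable; *consistency*, the mean and standard deviation of the
#' VOT over the computable recordings; and *accuracy*, the mean and
#' standard deviation of the fit RMSE over the recordings for which VOT67
#' could be computed for that family and variant. Recording-level failures
#' are counted as non-computable and never abort the corpus.
#'
#' @param recordings List of raw [gaw_signal()] objects (or paths readable
#'   by [read_gaw()]).
#' @param config A [pipeline_config()].
#' @param group Optional group label attached to every row (e.g. a subject
#'   group).
#' @return A tibble with one row per (variant x family x definition):
#'   `group`, `variant`, `family`, `definition`, `n`, `reliability`
#'   (percent), `mean_vot_ms`, `sd_vot_ms`, `mean_rmse`, `sd_rmse`.
#'   Standard deviations use the sample (n-1) denominator.
#' @seealso [format_corpus_table()] for table-style rounding.
#' @export
evaluate_corpus <- function(recordings, config = pipeline_config(),
                            group = NA_character_) {
  if (length(recordings) == 0) {
    abort("need at least one recording.", class = "gawvot_error_input")
  }
  per_rec <- purrr::imap(recordings, function(rec, i) {
    res <- tryCatch(run_pipeline(rec, config), error = function(e) e)
    if (inherits(res, "error")) {
      # recording-level failure: every requested combination non-computable
      tidyr::crossing(
        variant = config$variants, family = config$families,
        definition = config$definitions
      ) |>
        dplyr::filter(!(is_m_family(.data$family) & .data$definition == "VOT90")) |>
        dplyr::mutate(vot_ms = NA_real_, computable = FALSE,
                      rmse = NA_real_, converged = NA,
                      n_peaks = NA_integer_,
                      note = conditionMessage(res), recording = i)
    } else {
      dplyr::mutate(res$summary, recording = i)
    }
  })
  all_rows <- dplyr::bind_rows(per_rec)

  rmse_stats <- all_rows |>
    dplyr::filter(.data$definition == "VOT67", .data$computable) |>
    dplyr::group_by(.data$variant, .data$family) |>
    dplyr::summarise(mean_rmse = mean(.data$rmse),
                     sd_rmse = sd(.data$rmse), .groups = "drop")

  all_rows |>
    dplyr::group_by(.data$variant, .data$family, .data$definition) |>
    dplyr::summarise(
      n = dplyr::n(),
      reliability = 100 * mean(.data$computable),
      mean_vot_ms = mean(.data$vot_ms[.data$computable]),
      sd_vot_ms = sd(.data$vot_ms[.data$computable]),
      .groups = "drop"
    ) |>
    dplyr::left_join(rmse_stats, by = c("variant", "family")) |>
    dplyr::mutate(group = group) |>
    dplyr::relocate(group)
}

#' Round a corpus table for reporting
#'
#' Applies the reporting precision used for corpus summaries: reliability
#' to integer percent, VOT statistics to integer ms, RMSE statistics to two
#' decimals. The unrounded tibble from [evaluate_corpus()] remains the
#' computational record.
#'
#' @param rows Output of [evaluate_corpus()].
#' @return The rows with rounded reporting columns.
#' @export
format_corpus_table <- function(rows) {
  dplyr::mutate(
    rows,
    reliability = round(.data$reliability),
    mean_vot_ms = round(.data$mean_vot_ms),
    sd_vot_ms = round(.data$sd_vot_ms),
    mean_rmse = round(.data$mean_rmse, 2),
    sd_rmse = round(.data$sd_rmse, 2)
  )
}
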