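# Identification-risk arithmetic for a 1-vs-gallery re-identification
# attempt: an individual searches a published gallery of n speakers for their
# own recording with a verifier operating at a given EER. Expected counts are
# closed-form: FA = (n-1)*eer impostors accepted, TA = 1-eer, FR = eer,
# TR = (n-1)*(1-eer); the 1:N identification odds use N = round(FA) (half-up,
# minimum 1).

#' Expected FA/TA/FR/TR breakdown for a gallery of speakers
#'
#' @param n_total gallery size (number of speakers, >= 2).
#' @param eer equal error rate as a fraction in `[0, 1]`.
#' @return object of class `risk_breakdown` with fields `n_total`, `eer`,
#'   `fa`, `ta`, `fr`, `tr`, `odds_denominator`.
#' @export
identification_breakdown <- function(n_total, eer) {
  if (n_total < 2) stop("n_total must be >= 2")
  if (eer < 0 || eer > 1) stop("eer must lie in [0, 1]")
  fa <- (n_total - 1) * eer
  structure(list(n_total = n_total, eer = eer,
                 fa = fa, ta = 1 - eer, fr = eer, tr = (n_total - 1) * (1 - eer),
                 odds_denominator = max(1, round_half_up(fa))),
            class = "risk_breakdown")
}

#' @export
print.risk_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<risk_breakdown n=%d, EER %.2f%%: FA %.3f, TA %.3f, ",
                     "FR %.3f, TR %.3f -> odds 1:%d>\n"),
              x$n_total, 100 * x$eer, x$fa, x$ta, x$fr, x$tr,
              x$odds_denominator))
  invisible(x)
}

#' Identification odds before and after anonymization
#'
#' `fold_change` is the ratio of the rounded odds denominators (the quantity
#' quoted as an N-fold increase in identification difficulty);
#' `fold_change_raw` is the ratio of the un-rounded expected FA counts,
#' reported to one decimal.
#'
#' @param n_total gallery size.
#' @param eer_before,eer_after EER fractions before/after anonymization.
#' @return list with `odds_before`, `odds_after` (the two `risk_breakdown`s),
#'   `fold_change`, `fold_change_raw`.
#' @export
odds_summary <- function(n_total, eer_before, eer_after) {
  b <- identification_breakdown(n_total, eer_before)
  a <- identification_breakdown(n_total, eer_after)
  list(odds_before = b, odds_after = a,
       fold_change = a$odds_denominator / b$odds_denominator,
       fold_change_raw = round_half_up(a$fa / max(b$fa, .Machine$double.eps), 1))
}

#' Percentage increase of a metric
#'
#' `100 * (after - before) / before`, the form in which EER changes under
#' anonymization are reported.
#' @param before,after metric values (same units).
#' @return percentage increase.
#' @export
percent_increase <- function(before, after) {
  if (any(before <= 0)) stop("before must be positive")
  100 * (after - before) / before
}

#' Reference EER summary values from a large restricted clinical corpus
#'
#' Published summary statistics (EER percentages, mean over repeated trials)
#' for a restricted clinical pathological-speech corpus of 2742 German
#' speakers, bundled so the identification-risk arithmetic and percent-change
#' computations can be demonstrated without access to the audio. The audio
#' itself is not redistributable; only these aggregate numbers are used.
#'
#' @return data.frame with columns `subset`, `n_speakers`, `condition`
#'   (`original`, `pitch_shift`, `resynth_only`, `mcadams`, and the
#'   inverse-attack variants `inverse_original`, `inverse_mcadams`) and
#'   `eer_pct`.
#' @export
clinical_eer_reference <- function() {
  rbind(
    data.frame(subset = "dysarthria", n_speakers = 355,
               condition = c("original", "pitch_shift", "resynth_only",
                             "mcadams", "inverse_original", "inverse_mcadams"),
               eer_pct = c(1.80, 30.72, 7.48, 36.59, 1.64, 7.08)),
    data.frame(subset = "dysglossia", n_speakers = 542,
               condition = c("original", "pitch_shift", "resynth_only",
                             "mcadams", "inverse_original", "inverse_mcadams"),
               eer_pct = c(1.78, 31.54, 11.39, 34.26, 1.58, 8.66)),
    data.frame(subset = "dysphonia", n_speakers = 78,
               condition = c("original", "pitch_shift", "resynth_only",
                             "mcadams", "inverse_original", "inverse_mcadams"),
               eer_pct = c(2.19, 41.02, 11.27, 38.86, 1.63, 10.48)),
    data.frame(subset = "clp", n_speakers = 468,
               condition = c("original", "pitch_shift", "resynth_only",
                             "mcadams", "inverse_original", "inverse_mcadams"),
               eer_pct = c(7.01, 38.73, 23.45, 32.19, 5.86, 12.00)),
    data.frame(subset = c("all", "all", "patients", "patients"),
               n_speakers = c(2742, 2742, 1443, 1443),
               condition = c("original", "mcadams", "original", "mcadams"),
               eer_pct = c(4.02, 32.77, 2.96, 30.24))
  )
}
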