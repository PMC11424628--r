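# Synthetic speaker population. Each speaker is a source-filter voice
# parameterization: a base fundamental frequency inside a gender/age band,
# four (plus optional nasal) vocal-tract resonances, and per-marker disorder
# intensities in [0, 1] for jitter, shimmer, formant blurring and nasality.

DISORDER_LEVELS <- c("control", "dysarthria", "dysglossia", "dysphonia", "clp")
MARKER_NAMES <- c("jitter", "shimmer", "formant_blur", "nasality")

#' Default fundamental-frequency bands (Hz) by gender/age group
#'
#' Bands are configuration, not biology: adult male 85-155 Hz, adult female
#' 155-255 Hz, children (either gender) 200-320 Hz.
#' @return named list of `c(low, high)` pairs with keys `male`, `female`, `child`.
#' @export
default_f0_bands <- function() {
  list(male = c(85, 155), female = c(155, 255), child = c(200, 320))
}

f0_band_for <- function(gender, age_group, bands = default_f0_bands()) {
  if (age_group == "child") bands$child else bands[[gender]]
}

#' Construct a synthetic speaker profile
#'
#' @param speaker_id character id.
#' @param gender `"female"` or `"male"`.
#' @param age_group `"adult"` or `"child"`.
#' @param f0_base base fundamental frequency in Hz; must lie inside the
#'   gender/age band.
#' @param formants matrix or data.frame with columns `center` and `bandwidth`
#'   (Hz), at least 4 rows, strictly increasing centers, all below 8000 Hz.
#' @param disorder one of `r paste(DISORDER_LEVELS, collapse = ", ")`.
#' @param marker_intensity named numeric vector over
#'   `jitter, shimmer, formant_blur, nasality`, each in `[0, 1]`.
#' @param f0_bands band configuration, see [default_f0_bands()].
#' @return object of class `speaker_profile`.
#' @export
speaker_profile <- function(speaker_id, gender, age_group, f0_base, formants,
                            disorder, marker_intensity,
                            f0_bands = default_f0_bands()) {
  gender <- match.arg(gender, c("female", "male"))
  age_group <- match.arg(age_group, c("adult", "child"))
  disorder <- match.arg(disorder, DISORDER_LEVELS)
  band <- f0_band_for(gender, age_group, f0_bands)
  if (f0_base < band[1] || f0_base > band[2]) {
    stop("f0_base ", f0_base, " outside ", gender, "/", age_group,
         " band [", band[1], ", ", band[2], "]")
  }
  formants <- as.matrix(formants)
  colnames(formants) <- c("center", "bandwidth")
  if (nrow(formants) < 4) stop("need at least 4 formants")
  if (any(diff(formants[, "center"]) <= 0)) stop("formant centers must be strictly increasing")
  if (any(formants[, "center"] >= 8000)) stop("formant centers must be below the 8000 Hz Nyquist")
  mi <- marker_intensity[MARKER_NAMES]
  names(mi) <- MARKER_NAMES
  if (anyNA(mi) || any(mi < 0 | mi > 1)) stop("marker intensities must be named and in [0, 1]")
  structure(list(speaker_id = as.character(speaker_id), gender = gender,
                 age_group = age_group, f0_base = f0_base, formants = formants,
                 disorder = disorder, marker_intensity = mi,
                 f0_band = band),
            class = "speaker_profile")
}

#' @export
print.speaker_profile <- function(x, ...) {
  cat(sprintf("<speaker_profile %s: %s %s, %s, F0 %.1f Hz>\n", x$speaker_id,
              x$gender, x$age_group, x$disorder, x$f0_base))
  invisible(x)
}

# Largest-remainder apportionment of n into integer counts matching fractions.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate a seeded population of synthetic speaker profiles
#'
#' Disorder-group counts follow `group_mix` by largest-remainder rounding;
#' gender and age counts follow `gender_mix`/`age_mix` by half-up rounding.
#' Control speakers receive marker intensities at or below
#' `control_baseline`; patient speakers receive their disorder's primary
#' markers centered on `patient_intensity`.
#'
#' @param n_speakers number of speakers (>= 2).
#' @param group_mix named fractions over disorder labels, summing to 1.
#' @param gender_mix fraction of female speakers.
#' @param age_mix fraction of child speakers (CLP is modelled as a childhood
#'   disorder; CLP speakers are always children, controls fill the remainder).
#' @param seed integer seed; identical seeds give identical populations.
#' @param control_baseline upper bound on control marker intensities.
#' @param patient_intensity center of the primary-marker intensity for patients.
#' @param f0_bands see [default_f0_bands()].
#' @return list of [speaker_profile()] objects.
#' @export
make_population <- function(n_speakers,
                            group_mix = c(control = 0.5, dysarthria = 0.125,
                                          dysglossia = 0.125, dysphonia = 0.125,
                                          clp = 0.125),
                            gender_mix = 0.47, age_mix = 0, seed = 1,
                            control_baseline = 0.1, patient_intensity = 0.6,
                            f0_bands = default_f0_bands()) {
  if (n_speakers < 2) stop("n_speakers must be >= 2")
  if (any(group_mix < 0 | group_mix > 1) || gender_mix < 0 || gender_mix > 1 ||
      age_mix < 0 || age_mix > 1) {
    stop("mix fractions must lie in [0, 1]")
  }
  if (abs(sum(group_mix) - 1) > 1e-9) {
    stop("group_mix must sum to 1 (got ", sum(group_mix), ")")
  }
  bad <- setdiff(names(group_mix), DISORDER_LEVELS)
  if (length(bad)) stop("unknown disorder labels: ", paste(bad, collapse = ", "))

  counts <- largest_remainder(n_speakers, group_mix)
  groups <- rep(names(counts), counts)
  n_female <- as.integer(round_half_up(gender_mix * n_speakers))
  n_child <- as.integer(round_half_up(age_mix * n_speakers))

  with_seed(derive_seed(seed, "population"), {
    genders <- rep("male", n_speakers)
    genders[sample.int(n_speakers, n_female)] <- "female"
    # children preferentially cover CLP speakers (a congenital disorder of
    # childhood in the emulated cohort), remainder drawn at random
    ages <- rep("adult", n_speakers)
    clp_idx <- which(groups == "clp")
    n_child <- max(n_child, 0L)
    take <- clp_idx[seq_len(min(length(clp_idx), n_child))]
    ages[take] <- "child"
    left <- n_child - length(take)
    if (left > 0) {
      pool <- setdiff(seq_len(n_speakers), take)
      ages[sample(pool, left)] <- "child"
    }
    profiles <- vector("list", n_speakers)
    for (i in seq_len(n_speakers)) {
      band <- f0_band_for(genders[i], ages[i], f0_bands)
      f0 <- stats::runif(1, band[1] + 0.05 * diff(band), band[2] - 0.05 * diff(band))
      # neutral-vowel resonances with gender/age vocal-tract length scaling
      scale <- if (ages[i] == "child") 1.25 else if (genders[i] == "female") 1.12 else 1.0
      centers <- c(500, 1500, 2500, 3500) * scale *
        exp(stats::rnorm(4, 0, 0.05))
      centers <- sort(pmin(centers, 7500))
      bandwidths <- c(70, 100, 140, 180) * stats::runif(4, 0.9, 1.1)
      mi <- stats::runif(4, 0, control_baseline)
      names(mi) <- MARKER_NAMES
      primary <- switch(groups[i],
                        control = character(0),
                        dysphonia = c("jitter", "shimmer"),
                        dysarthria = c("formant_blur", "jitter"),
                        dysglossia = "formant_blur",
                        clp = c("nasality", "formant_blur"))
      for (m in primary) {
        mi[m] <- min(1, max(0, stats::rnorm(1, patient_intensity, 0.05)))
      }
      profiles[[i]] <- speaker_profile(
        speaker_id = sprintf("spk%03d", i), gender = genders[i],
        age_group = ages[i], f0_base = f0,
        formants = cbind(center = centers, bandwidth = bandwidths),
        disorder = groups[i], marker_intensity = mi, f0_bands = f0_bands)
    }
    profiles
  })
}

#' Tabulate a population as a metadata data frame
#' @param population list of [speaker_profile()] objects.
#' @return data.frame with one row per speaker.
#' @export
population_table <- function(population) {
  do.call(rbind, lapply(population, function(p) {
    data.frame(speaker_id = p$speaker_id, group = p$disorder,
               gender = p$gender, age_group = p$age_group,
               f0_base = p$f0_base, stringsAsFactors = FALSE)
  }))
}
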