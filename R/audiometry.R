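#' Typical metabolic / sensory audiogram profiles
#'
#' A profile basis holds two unit-peak, non-negative shapes over a frequency
#' grid: the typical metabolic (strial) presbyacusis profile, mildly elevated
#' at low frequencies and sloping gently downwards towards high frequencies,
#' and the typical sensory profile, near-normal at low frequencies with a
#' steep high-frequency slope. An individual ear's audiogram is approximated
#' as a non-negative combination of the two; the fitted coefficients are the
#' metabolic and sensory estimates in dB (each shape peaks at 1, so a
#' coefficient is that component's contribution at its worst frequency).
#'
#' The default shapes are stand-ins constructed to match the verbal
#' description of the typical profiles; studies with access to empirically
#' derived profiles should supply them here.
#'
#' @param frequencies_kHz ascending positive frequency grid (kHz).
#' @param metabolic,sensory non-negative weights, same length as the grid,
#'   maximum exactly 1 (unit peak).
#' @return A `profileBasis` list with elements `frequencies_kHz`,
#'   `metabolic`, `sensory`.
#' @examples
#' b <- defaultProfileBasis()
#' fitComponents(30 * b$metabolic, b$frequencies_kHz, b)
#' @export
profileBasis <- function(frequencies_kHz, metabolic, sensory) {
  stopifnot(length(frequencies_kHz) == length(metabolic),
            length(frequencies_kHz) == length(sensory),
            all(frequencies_kHz > 0), all(diff(frequencies_kHz) > 0),
            all(metabolic >= 0), all(sensory >= 0))
  if (abs(max(metabolic) - 1) > 1e-8 || abs(max(sensory) - 1) > 1e-8)
    stop("profile shapes must be unit-peak normalized (max exactly 1)")
  structure(list(frequencies_kHz = as.numeric(frequencies_kHz),
                 metabolic = as.numeric(metabolic),
                 sensory = as.numeric(sensory)),
            class = "profileBasis")
}

#' @rdname profileBasis
#' @export
defaultProfileBasis <- function() {
  profileBasis(
    frequencies_kHz = c(0.25, 0.5, 1, 2, 3, 4, 6, 8),
    metabolic = c(0.70, 0.72, 0.75, 0.80, 0.85, 0.90, 0.95, 1.00),
    sensory   = c(0.00, 0.02, 0.08, 0.25, 0.45, 0.70, 0.90, 1.00))
}

# Interpolate basis shapes onto an audiogram's frequency grid.
# Linear in log2(frequency), the audiometric octave scale.
resampleBasis <- function(basis, frequencies_kHz) {
  if (min(frequencies_kHz) < min(basis$frequencies_kHz) - 1e-9 ||
      max(frequencies_kHz) > max(basis$frequencies_kHz) + 1e-9)
    stop("audiogram frequencies outside the basis frequency range")
  lx <- log2(basis$frequencies_kHz)
  lt <- log2(frequencies_kHz)
  list(frequencies_kHz = frequencies_kHz,
       metabolic = stats::approx(lx, basis$metabolic, lt)$y,
       sensory = stats::approx(lx, basis$sensory, lt)$y)
}

#' Fit metabolic and sensory components to one audiogram
#'
#' Finds non-negative coefficients (m, s) minimising the sum of squared
#' differences between the observed thresholds and
#' `m * metabolic_shape + s * sensory_shape`, with the basis first
#' interpolated onto the audiogram's frequency grid. The line-fit error is
#' the root-mean-square residual in dB; a large value flags an audiogram
#' configuration inconsistent with the two-component presbyacusis model
#' (e.g. a corner audiogram).
#'
#' @param thresholds numeric vector of thresholds (dB HL); `NA` entries are
#'   dropped together with their frequencies.
#' @param frequencies_kHz frequencies matching `thresholds`.
#' @param basis a [profileBasis()].
#' @return list with `metabolic`, `sensory` (fitted estimates, dB) and
#'   `fit_error` (RMS residual, dB).
#' @export
fitComponents <- function(thresholds, frequencies_kHz = NULL, basis = defaultProfileBasis()) {
  if (is.null(frequencies_kHz)) {
    if (is.null(names(thresholds)))
      stop("supply frequencies_kHz or a named threshold vector")
    frequencies_kHz <- as.numeric(sub("^f", "", names(thresholds)))
  }
  keep <- !is.na(thresholds)
  y <- as.numeric(thresholds[keep])
  f <- frequencies_kHz[keep]
  if (length(y) < 2)
    stop("degenerate fit: fewer than 2 usable frequencies")
  b <- resampleBasis(basis, f)
  X <- cbind(metabolic = b$metabolic, sensory = b$sensory)
  # collinearity of the shapes at the available frequencies
  if (rcond(crossprod(X)) < 1e-10)
    stop("ill-conditioned fit: basis shapes collinear at available frequencies")
  fit <- pracma::lsqnonneg(X, y)
  res <- y - X %*% fit$x
  list(metabolic = unname(fit$x[1]), sensory = unname(fit$x[2]),
       fit_error = sqrt(mean(res^2)))
}

#' Sequential phenotype classification rules
#'
#' Thresholds (all in dB) for the five-way audiometric classification.
#' Defaults follow the published rule set: ears with line-fit error >= 15 dB
#' are Unselected; Older-Normal requires summed metabolic + sensory
#' estimates < 20 dB with < 10 dB interaural difference in each estimate;
#' Metabolic requires metabolic estimates >= 20 dB, metabolic asymmetry
#' <= 15 dB, sensory estimates < 20 dB and metabolic > sensory; Sensory
#' requires sensory estimates >= 15 dB, sensory asymmetry <= 20 dB,
#' metabolic estimates < 25 dB and sensory > metabolic. Remaining cases
#' are Unclassified.
#'
#' @param unselected_fit_error_min,on_sum_max,on_interaural_max,met_min,met_asym_max,met_sensory_max,sen_min,sen_asym_max,sen_metabolic_max rule thresholds in dB.
#' @return a named list of rule thresholds.
#' @export
classificationRules <- function(unselected_fit_error_min = 15,
                                on_sum_max = 20, on_interaural_max = 10,
                                met_min = 20, met_asym_max = 15,
                                met_sensory_max = 20,
                                sen_min = 15, sen_asym_max = 20,
                                sen_metabolic_max = 25) {
  r <- list(unselected_fit_error_min = unselected_fit_error_min,
            on_sum_max = on_sum_max, on_interaural_max = on_interaural_max,
            met_min = met_min, met_asym_max = met_asym_max,
            met_sensory_max = met_sensory_max,
            sen_min = sen_min, sen_asym_max = sen_asym_max,
            sen_metabolic_max = sen_metabolic_max)
  stopifnot(all(unlist(r) > 0))
  r
}

#' Classify one participant from both ears' component fits
#'
#' Applies the selection rules strictly sequentially. Magnitude criteria use
#' the across-ear mean of each estimate; asymmetry criteria use the absolute
#' left-right difference of each estimate separately; a participant is
#' Unselected if either ear's line-fit error reaches the exclusion
#' threshold.
#'
#' @param left_fit,right_fit lists as returned by [fitComponents()].
#' @param rules a [classificationRules()] list.
#' @return one of "OlderNormal", "Metabolic", "Sensory", "Unclassified",
#'   "Unselected".
#' @examples
#' f <- function(m, s, e) list(metabolic = m, sensory = s, fit_error = e)
#' classifyCase(f(5, 5, 3), f(5, 5, 3))   # OlderNormal
#' classifyCase(f(25, 10, 5), f(24, 9, 5)) # Metabolic
#' @export
classifyCase <- function(left_fit, right_fit, rules = classificationRules()) {
  eL <- left_fit$fit_error; eR <- right_fit$fit_error
  if (eL >= rules$unselected_fit_error_min || eR >= rules$unselected_fit_error_min)
    return("Unselected")
  mL <- left_fit$metabolic; mR <- right_fit$metabolic
  sL <- left_fit$sensory;   sR <- right_fit$sensory
  m <- mean(c(mL, mR)); s <- mean(c(sL, sR))
  dM <- abs(mL - mR); dS <- abs(sL - sR)
  if (m + s < rules$on_sum_max &&
      dM < rules$on_interaural_max && dS < rules$on_interaural_max)
    return("OlderNormal")
  if (m >= rules$met_min && dM <= rules$met_asym_max &&
      s < rules$met_sensory_max && m > s)
    return("Metabolic")
  if (s >= rules$sen_min && dS <= rules$sen_asym_max &&
      m < rules$sen_metabolic_max && s > m)
    return("Sensory")
  "Unclassified"
}

#' Classify a whole cohort of audiograms
#'
#' Fits both ears of every participant (on the intersection of the two
#' ears' available frequencies), applies [classifyCase()], and summarises
#' mean audiograms per category.
#'
#' @param audiograms an [AudiogramSet-class] with left and right recordings
#'   for each participant.
#' @param basis a [profileBasis()].
#' @param rules a [classificationRules()] list.
#' @return list with `labels` (data.frame: participant_id, label, M_L, M_R,
#'   S_L, S_R, err_L, err_R) and `summary` (data.frame: label,
#'   frequency_kHz, mean_dB, sem_dB, n; only categories with members).
#' @export
classifyCohort <- function(audiograms, basis = defaultProfileBasis(),
                           rules = classificationRules()) {
  stopifnot(is(audiograms, "AudiogramSet"))
  cd <- colData(audiograms)
  freqs <- frequencies(audiograms)
  ids <- unique(cd$participant_id)
  if (!length(ids)) stop("empty cohort")
  X <- thresholds(audiograms)
  rows <- lapply(ids, function(id) {
    iL <- which(cd$participant_id == id & cd$ear == "left")[1]
    iR <- which(cd$participant_id == id & cd$ear == "right")[1]
    if (is.na(iL) || is.na(iR))
      stop("participant ", id, " lacks a left or right recording")
    tL <- X[, iL]; tR <- X[, iR]
    use <- !is.na(tL) & !is.na(tR)
    fL <- fitComponents(tL[use], freqs[use], basis)
    fR <- fitComponents(tR[use], freqs[use], basis)
    data.frame(participant_id = id,
               label = classifyCase(fL, fR, rules),
               M_L = fL$metabolic, M_R = fR$metabolic,
               S_L = fL$sensory, S_R = fR$sensory,
               err_L = fL$fit_error, err_R = fR$fit_error)
  })
  labels <- do.call(rbind, rows)
  # per-category mean audiograms across all recordings of members
  summ <- do.call(rbind, lapply(unique(labels$label), function(lab) {
    member <- labels$participant_id[labels$label == lab]
    sel <- cd$participant_id %in% member
    sub <- X[, sel, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    n <- rowSums(!is.na(sub))
    sem <- apply(sub, 1, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1))
    data.frame(label = lab, frequency_kHz = freqs,
               mean_dB = mu, sem_dB = sem, n = n, row.names = NULL)
  }))
  list(labels = labels, summary = summ)
}
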