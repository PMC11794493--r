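#' Simulate the per-trial behavioral ratings table
#'
#' Draws per-trial 9-point Likert ratings for state nostalgia, pleasure,
#' arousal and dominance in every (subject, channelType, musicType, trial)
#' cell: cell mean + Gaussian noise with the configured cell SD, truncated to
#' [1, 9] and rounded to the integer Likert grid. Reaction times are drawn
#' from a log-normal (median about 1.5 s) purely as plumbing; they are never
#' analyzed. Deterministic given the config seed.
#'
#' @param config a \code{\linkS4class{SimulationConfig}} whose
#'   \code{behaviorMeans} covers all 6 cells x 4 scales.
#' @return data.frame with columns \code{subject}, \code{trial},
#'   \code{channel_type}, \code{music_type}, \code{nostalgia},
#'   \code{pleasure}, \code{arousal}, \code{dominance}, \code{rt_ms}.
#' @export
#' @examples
#' b <- generateBehavior(simConfig(nSubjects = 3, seed = 2))
#' head(b)
generateBehavior <- function(config) {
  validObject(config)
  bm <- config@behaviorMeans
  scales <- c("nostalgia", "pleasure", "arousal", "dominance")
  chTypes <- c("visual", "auditory", "audiovisual")
  mTypes <- c("nostalgic", "non-nostalgic")
  need <- expand.grid(scale = scales, channelType = chTypes,
                      musicType = mTypes, stringsAsFactors = FALSE)
  key <- function(d) paste(d$scale, d$channelType, d$musicType)
  miss <- setdiff(key(need), key(bm))
  if (length(miss))
    stop("behaviorMeans is missing cells: ", paste(miss, collapse = "; "))

  withSeed(deriveSeed(config@seed, 202L), {
    grid <- expand.grid(
      trial = seq_len(config@nTrialsPerCell),
      music_type = mTypes,
      channel_type = chTypes,
      subject = seq_len(config@nSubjects) - 1L,
      stringsAsFactors = FALSE
    )
    out <- grid[, c("subject", "trial", "channel_type", "music_type")]
    for (sc in scales) {
      mu <- sdv <- numeric(nrow(out))
      for (ct in chTypes) for (mt in mTypes) {
        row <- bm[bm$scale == sc & bm$channelType == ct & bm$musicType == mt, ]
        sel <- out$channel_type == ct & out$music_type == mt
        mu[sel] <- row$mean[1]
        sdv[sel] <- row$sd[1]
      }
      v <- mu + rnorm(nrow(out)) * sdv
      out[[sc]] <- pmin(9, pmax(1, round(v)))
    }
    out$rt_ms <- round(exp(rnorm(nrow(out), log(1500), 0.3)))
    rownames(out) <- NULL
    out
  })
}

#' Average trials to one value per subject and design cell
#'
#' Collapses a per-trial ratings table to subject-level cell means for one
#' rating scale — the unit of analysis for every reported test.
#'
#' @param behavior data.frame from \code{\link{generateBehavior}} (or a real
#'   ratings CSV with the same columns).
#' @param scale one of \code{"nostalgia"}, \code{"pleasure"},
#'   \code{"arousal"}, \code{"dominance"}.
#' @return data.frame with columns \code{subject}, \code{channelType},
#'   \code{musicType}, \code{value} (one row per subject x cell).
#' @export
cellMeans <- function(behavior, scale) {
  stopifnot(scale %in% names(behavior))
  agg <- stats::aggregate(
    behavior[[scale]],
    by = list(subject = behavior$subject,
              channelType = behavior$channel_type,
              musicType = behavior$music_type),
    FUN = mean)
  names(agg)[4] <- "value"
  agg[order(agg$subject, agg$channelType, agg$musicType), , drop = FALSE]
}
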